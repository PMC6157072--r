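#' Differential-evolution configuration
#'
#' Controls for the DE/rand/1/bin engine with anti-stagnation measures:
#' the differential weight F is dithered uniformly per generation, the
#' crossover rate cycles through \code{CR_values}, and on a stall (best-scalar
#' improvement below \code{tol} over \code{window} generations) the worst
#' \code{restart_fraction} of the population is re-initialized inside the
#' population's inflated coordinate range, always keeping the best solution.
#'
#' @param pop_size population size; default \code{min(10 * dim, 200)} (at
#'   least 8), resolved when the dimension is known.
#' @param iterations maximum number of generations.
#' @param F_range dither interval for the differential weight.
#' @param CR_values crossover rates cycled per generation.
#' @param tol convergence tolerance on the best scalar.
#' @param window stall window in generations.
#' @param restart_fraction fraction of worst solutions re-initialized on
#'   stall.
#' @param seed integer seed; drawn (and recorded) when \code{NULL}.
#' @return An object of class \code{DEConfig}.
#' @export
de_config <- function(pop_size = NULL, iterations = 10000L,
                      F_range = c(0.1, 0.9), CR_values = c(0.2, 0.9),
                      tol = 1e-9, window = 500L, restart_fraction = 0.25,
                      seed = NULL) {
  stopifnot(length(F_range) == 2L, all(F_range > 0), all(F_range < 2),
            all(CR_values >= 0), all(CR_values <= 1),
            restart_fraction >= 0, restart_fraction < 1)
  structure(list(pop_size = pop_size, iterations = as.integer(iterations),
                 F_range = as.numeric(F_range),
                 CR_values = as.numeric(CR_values),
                 tol = tol, window = as.integer(window),
                 restart_fraction = restart_fraction, seed = seed),
            class = "DEConfig")
}

resolve_pop_size <- function(config, dim) {
  np <- config$pop_size
  if (is.null(np)) np <- max(8L, min(10L * dim, 200L))
  np <- as.integer(np)
  if (np < 4L) stop("pop_size must be at least 4 (DE needs four distinct indices)")
  np
}

#' Run the differential-evolution engine
#'
#' Maximizes \code{objective} over real vectors of length \code{dim} with
#' DE/rand/1/bin: per target i, three distinct other members form the mutant
#' \code{x_r1 + F * (x_r2 - x_r3)} (F dithered per generation), binomial
#' crossover with the generation's CR and one guaranteed mutant coordinate,
#' then greedy replacement. Selection is elitist, so the reported best scalar
#' never decreases. On stall, part of the population is re-initialized; the
#' run terminates at \code{iterations} or after two consecutive
#' stall-restarts without improvement.
#'
#' @param objective function taking a \code{dim x pop} matrix of column
#'   chromosomes and returning one finite scalar per column (larger is
#'   better).
#' @param dim chromosome length.
#' @param config a [de_config()].
#' @param report optional function of the best chromosome returning a named
#'   numeric (e.g. gain/coancestry/inbreeding/penalty) recorded in the log.
#' @return List of class \code{de_result}: \code{best} chromosome,
#'   \code{value}, \code{log} (per-generation data frame with attributes
#'   \code{restarts} and \code{window}), \code{seed}, \code{termination},
#'   \code{generations}.
#' @export
evolve <- function(objective, dim, config = de_config(), report = NULL) {
  stopifnot(dim >= 1L)
  seed <- config$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  NP <- resolve_pop_size(config, dim)
  X <- matrix(stats::runif(dim * NP), dim, NP)
  fit <- objective(X)
  if (length(fit) != NP || !all(is.finite(fit)))
    stop("objective must return one finite value per population member")

  best_j <- which.max(fit)
  best <- X[, best_j]
  best_val <- fit[best_j]
  rep_names <- NULL
  rep_vals <- NULL
  if (!is.null(report)) {
    rep_vals <- report(best)
    rep_names <- names(rep_vals)
  }

  iters <- config$iterations
  best_hist <- numeric(iters + 1L)
  mean_hist <- numeric(iters + 1L)
  best_hist[1L] <- best_val
  mean_hist[1L] <- mean(fit)
  rep_hist <- if (!is.null(report))
    matrix(NA_real_, iters + 1L, length(rep_vals),
           dimnames = list(NULL, rep_names))
  rep_ok <- !is.null(report)
  if (rep_ok) rep_hist[1L, ] <- rep_vals

  ncr <- length(config$CR_values)
  restarts <- integer(0)
  last_event <- 1L           # generation index of last restart (or start)
  stalls_no_improve <- 0L
  best_at_restart <- -Inf
  termination <- "max_iterations"
  gen_done <- 0L

  for (gen in seq_len(iters)) {
    Fg <- stats::runif(1L, config$F_range[1L], config$F_range[2L])
    CR <- config$CR_values[(gen - 1L) %% ncr + 1L]
    r <- vapply(seq_len(NP), function(i) {
      j <- sample.int(NP - 1L, 3L)
      j + (j >= i)
    }, integer(3L))
    V <- X[, r[1L, ], drop = FALSE] +
      Fg * (X[, r[2L, ], drop = FALSE] - X[, r[3L, ], drop = FALSE])
    mask <- matrix(stats::runif(dim * NP) < CR, dim, NP)
    mask[cbind(sample.int(dim, NP, replace = TRUE), seq_len(NP))] <- TRUE
    U <- X
    U[mask] <- V[mask]
    fu <- objective(U)
    better <- fu >= fit
    if (any(better)) {
      X[, better] <- U[, better]
      fit[better] <- fu[better]
    }
    j <- which.max(fit)
    if (fit[j] > best_val) {
      best_val <- fit[j]
      best <- X[, j]
      if (rep_ok) rep_vals <- report(best)
    }
    g1 <- gen + 1L
    best_hist[g1] <- best_val
    mean_hist[g1] <- mean(fit)
    if (rep_ok) rep_hist[g1, ] <- rep_vals
    gen_done <- gen

    # stall detection and partial restart
    if (gen - last_event >= config$window) {
      if (best_val - best_hist[g1 - config$window] < config$tol) {
        if (stalls_no_improve >= 1L && best_val - best_at_restart < config$tol) {
          termination <- "stalled"
          break
        }
        stalls_no_improve <-
          if (best_val - best_at_restart < config$tol) stalls_no_improve + 1L else 1L
        best_at_restart <- best_val
        restarts <- c(restarts, gen)
        m <- min(NP - 1L, max(1L, floor(config$restart_fraction * NP)))
        worst <- order(fit)[seq_len(m)]
        worst <- setdiff(worst, which.max(fit))
        if (length(worst)) {
          lo <- apply(X, 1L, min)
          hi <- apply(X, 1L, max)
          mid <- (lo + hi) / 2
          half <- pmax(hi - lo, 1e-8)
          Xn <- matrix(stats::runif(dim * length(worst)), dim) *
            (2 * half) + (mid - half)
          X[, worst] <- Xn
          fit[worst] <- objective(X[, worst, drop = FALSE])
        }
        last_event <- gen
      }
    }
  }

  n <- gen_done + 1L
  log <- data.frame(generation = seq_len(n) - 1L,
                    best = best_hist[seq_len(n)],
                    mean = mean_hist[seq_len(n)])
  if (rep_ok) log <- cbind(log, as.data.frame(rep_hist[seq_len(n), , drop = FALSE]))
  attr(log, "restarts") <- restarts
  attr(log, "window") <- config$window
  attr(log, "tol") <- config$tol
  structure(list(best = best, value = best_val, log = log, seed = seed,
                 termination = termination, generations = gen_done),
            class = "de_result")
}

#' Has the optimization converged?
#'
#' \code{TRUE} when the best-scalar improvement over the last stall window is
#' strictly below the tolerance \emph{and} at least one stall-restart has
#' already been consumed (the engine only trusts a flat trace after a restart
#' failed to escape it).
#'
#' @param log the optimization log of a [evolve()] result (or the result
#'   itself).
#' @param config the [de_config()] used.
#' @return Logical.
#' @export
has_converged <- function(log, config = de_config()) {
  if (inherits(log, "de_result")) log <- log$log
  n <- nrow(log)
  if (n <= config$window) stop("need at least window + 1 generations")
  restarts <- attr(log, "restarts")
  improvement <- log$best[n] - log$best[n - config$window]
  improvement < config$tol && length(restarts) >= 1L
}

#' @export
print.de_result <- function(x, ...) {
  cat("de_result: best", format(x$value, digits = 8), "after",
      x$generations, "generations (", x$termination, "), seed", x$seed, "\n")
  invisible(x)
}
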
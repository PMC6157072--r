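#' Build the vectorized DE objective for a problem
#'
#' Returns the population evaluator (chromosome matrix to penalized scalars)
#' and a component reporter for one objective mode, backed by the compiled
#' plan decoder.
#'
#' @param problem an [ocs_problem()].
#' @param mode objective mode.
#' @param Cstar,span resolved coancestry bound and normalization span for
#'   target mode.
#' @return List with \code{fn} (population evaluator), \code{report}
#'   (component reporter for one chromosome) and \code{dim}.
#' @export
make_objective <- function(problem, mode = problem$mode, Cstar = NA_real_,
                           span = NA_real_) {
  dat <- problem_data(problem, mode, Cstar, span)
  list(fn = function(X) cpp_eval_population(X, dat),
       report = function(z) {
         p <- cpp_decode_plan(z, dat)
         c(gain = p$gain, coancestry = p$coancestry,
           inbreeding = p$inbreeding, penalty = p$penalty)
       },
       dim = chromosome_length(problem))
}

solve_single <- function(problem, mode, config, Cstar = NA_real_,
                         span = NA_real_) {
  obj <- make_objective(problem, mode, Cstar, span)
  res <- evolve(obj$fn, obj$dim, config, report = obj$report)
  plan <- decode_chromosome(res$best, problem, mode, Cstar, span)
  list(result = res, plan = plan)
}

#' Find the bounds of the gain--coancestry objective space
#'
#' Runs the evolver twice under identical mating constraints -- once
#' maximizing gain, once minimizing group coancestry -- and records both
#' solutions' full objective values. These bounds normalize the objectives and
#' anchor all trade-off targets.
#'
#' @param problem an [ocs_problem()]; a selection criterion is required.
#' @param config a [de_config()]; the min-coancestry solve derives its seed
#'   from \code{config$seed + 1}.
#' @return An object of class \code{ObjectiveBounds}: \code{G_max},
#'   \code{C_at_Gmax}, \code{C_min}, \code{G_at_Cmin}, plus both plans.
#' @export
find_bounds <- function(problem, config = de_config()) {
  if (is.null(config$seed)) config$seed <- sample.int(.Machine$integer.max, 1L)
  cfg_gain <- config
  cfg_div <- config
  cfg_div$seed <- config$seed + 1L
  sg <- solve_single(problem, "max_gain", cfg_gain)
  sc <- solve_single(problem, "min_coancestry", cfg_div)
  og <- sg$plan$objectives
  oc <- sc$plan$objectives
  structure(list(G_max = og$gain, C_at_Gmax = og$coancestry,
                 C_min = oc$coancestry, G_at_Cmin = oc$gain,
                 plan_gain = sg$plan, plan_div = sc$plan,
                 result_gain = sg$result, result_div = sc$result,
                 seed = config$seed),
            class = "ObjectiveBounds")
}

#' @export
print.ObjectiveBounds <- function(x, ...) {
  cat(sprintf("ObjectiveBounds: G_max %.4f (C %.4f)  C_min %.4f (G %.4f)\n",
              x$G_max, x$C_at_Gmax, x$C_min, x$G_at_Cmin))
  invisible(x)
}

frontier_point <- function(degrees, plan, bounds, Cstar, result = NULL) {
  o <- plan$objectives
  gspan <- bounds$G_max - bounds$G_at_Cmin
  cspan <- bounds$C_at_Gmax - bounds$C_min
  structure(list(degrees = degrees, gain = o$gain, coancestry = o$coancestry,
                 inbreeding = o$inbreeding,
                 gain_norm = if (abs(gspan) > 1e-12)
                   (o$gain - bounds$G_at_Cmin) / gspan else 1,
                 coancestry_norm = if (abs(cspan) > 1e-12)
                   (o$coancestry - bounds$C_min) / cspan else 0,
                 Cstar = Cstar,
                 constraint_ok = is.na(Cstar) ||
                   o$coancestry <= Cstar + 1e-6 * max(cspan, 1e-12),
                 plan = plan, result = result),
            class = "FrontierPoint")
}

#' @export
print.FrontierPoint <- function(x, ...) {
  cat(sprintf("FrontierPoint: %s deg  gain %.4f  coancestry %.4f  inbreeding %.4f\n",
              format(x$degrees), x$gain, x$coancestry, x$inbreeding))
  invisible(x)
}

#' Solve for one Pareto-optimal trade-off point
#'
#' Resolves the trade-off target to an absolute coancestry bound C* via
#' [resolve_coancestry_target()] and maximizes the epsilon-constraint
#' penalized gain. When the achieved coancestry exceeds C* beyond solver
#' tolerance the point is flagged (\code{constraint_ok = FALSE}).
#'
#' @param problem an [ocs_problem()].
#' @param target a [target_spec()].
#' @param config a [de_config()].
#' @param bounds precomputed [find_bounds()] result; computed if missing.
#' @return A \code{FrontierPoint}.
#' @export
solve_target <- function(problem, target, config = de_config(), bounds = NULL) {
  if (is.null(bounds)) bounds <- find_bounds(problem, config)
  span <- bounds$C_at_Gmax - bounds$C_min
  C_current <- group_coancestry(rep(1 / problem$candidates$n,
                                    problem$candidates$n), problem$K)
  Cstar <- resolve_coancestry_target(target, bounds, C_current)
  if (span < 1e-12) {
    warning("degenerate gain-diversity span; returning the max-gain bound solution")
    return(frontier_point(degrees_of(target), bounds$plan_gain, bounds, Cstar))
  }
  s <- solve_single(problem, "target", config, Cstar, span)
  frontier_point(degrees_of(target), s$plan, bounds, Cstar, s$result)
}

degrees_of <- function(target) {
  if (target$form == "degrees") target$value else NA_real_
}

#' Sweep the Pareto frontier of gain versus group coancestry
#'
#' Solves targets uniformly spaced in trigonometric degrees from 0 to 90
#' (including both endpoints). The endpoint solutions reuse the bound solves
#' (guaranteeing endpoint consistency); each interior angle gets a seed
#' derived as \code{seed + round(degrees * 1000)} so the sweep is reproducible
#' while points stay independent.
#'
#' @param problem an [ocs_problem()].
#' @param steps number of frontier points, >= 2.
#' @param config a [de_config()].
#' @param bounds optional precomputed [find_bounds()].
#' @return An object of class \code{ocs_frontier}: list of
#'   \code{FrontierPoint}s sorted by degrees, with the bounds attached.
#' @export
sweep_frontier <- function(problem, steps = 9L, config = de_config(),
                           bounds = NULL) {
  stopifnot(steps >= 2L)
  if (is.null(config$seed)) config$seed <- sample.int(.Machine$integer.max, 1L)
  if (is.null(bounds)) bounds <- find_bounds(problem, config)
  span <- bounds$C_at_Gmax - bounds$C_min
  degs <- seq(0, 90, length.out = steps)
  pts <- vector("list", steps)
  for (i in seq_len(steps)) {
    th <- degs[i]
    if (i == 1L) {
      pts[[i]] <- frontier_point(0, bounds$plan_gain, bounds, bounds$C_at_Gmax)
    } else if (i == steps) {
      pts[[i]] <- frontier_point(90, bounds$plan_div, bounds, bounds$C_min)
    } else {
      cfg <- config
      cfg$seed <- config$seed + as.integer(round(th * 1000))
      pts[[i]] <- solve_target(problem, target_spec("degrees", th), cfg, bounds)
    }
    if (span < 1e-12 && i > 1L) {
      warning("degenerate gain-diversity span; frontier collapses to one point")
      pts <- pts[1L]
      break
    }
  }
  structure(pts, class = "ocs_frontier", bounds = bounds)
}

#' Tabulate a frontier
#'
#' @param x an \code{ocs_frontier} (or list of \code{FrontierPoint}s).
#' @param ... unused.
#' @return Data frame with columns Degrees, Gain, Coancestry, GainNorm,
#'   CoancestryNorm, Inbreeding.
#' @export
as.data.frame.ocs_frontier <- function(x, ...) {
  data.frame(Degrees = vapply(x, `[[`, 0, "degrees"),
             Gain = vapply(x, `[[`, 0, "gain"),
             Coancestry = vapply(x, `[[`, 0, "coancestry"),
             GainNorm = vapply(x, `[[`, 0, "gain_norm"),
             CoancestryNorm = vapply(x, `[[`, 0, "coancestry_norm"),
             Inbreeding = vapply(x, `[[`, 0, "inbreeding"))
}

#' @export
print.ocs_frontier <- function(x, ...) {
  cat("ocs_frontier with", length(x), "points\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Remove Pareto-dominated frontier points
#'
#' A point is dominated when another point has gain at least as high and
#' coancestry at least as low (tolerance 1e-9), with at least one strict
#' difference; among duplicates the first (lowest degrees) is kept.
#'
#' @param points an \code{ocs_frontier} or list of \code{FrontierPoint}s.
#' @return The filtered list, same class.
#' @export
pareto_filter <- function(points) {
  n <- length(points)
  if (n <= 1L) return(points)
  gain <- vapply(points, `[[`, 0, "gain")
  coa <- vapply(points, `[[`, 0, "coancestry")
  tol <- 1e-9
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !keep[i]) next
      dominates <- gain[j] >= gain[i] - tol && coa[j] <= coa[i] + tol &&
        (gain[j] > gain[i] + tol || coa[j] < coa[i] - tol)
      duplicate <- abs(gain[j] - gain[i]) <= tol && abs(coa[j] - coa[i]) <= tol
      if (dominates || (duplicate && j < i)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- points[keep]
  attributes(out) <- c(attributes(out),
                       attributes(points)[setdiff(names(attributes(points)),
                                                  names(attributes(out)))])
  class(out) <- class(points)
  out
}
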
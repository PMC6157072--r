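#' Standardize a selection criterion
#'
#' Centers and scales to mean 0 and population standard deviation 1, putting
#' genetic gain on a scale-free footing so penalty weights and degree targets
#' are portable across traits.
#'
#' @param a numeric vector, length >= 2, not all equal.
#' @return Standardized vector.
#' @export
standardize_criterion <- function(a) {
  p <- standardize_params(a)
  (a - p$mean) / p$sd
}

standardize_params <- function(a) {
  if (length(a) < 2L) stop("criterion needs at least two values")
  m <- mean(a)
  s <- sqrt(mean((a - m)^2))
  if (s < .Machine$double.eps * max(1, abs(m)))
    stop("criterion has zero variance")
  list(mean = m, sd = s)
}

#' Genetic gain of a contribution vector
#'
#' The expected mean (standardized) criterion of the next generation,
#' \code{sum(x * a_std)}, for contribution proportions \code{x} summing to 1
#' (each gender role summing to 0.5 in gendered mode).
#'
#' @param x contribution proportions.
#' @param a_std standardized selection criteria.
#' @return Numeric scalar.
#' @export
genetic_gain <- function(x, a_std) {
  stopifnot(length(x) == length(a_std))
  sum(x * a_std)
}

#' Group coancestry of a contribution vector
#'
#' \code{t(x) C x}: the expected mean coancestry (including self-pairs) of the
#' future cohort; its growth measures the loss of genetic diversity.
#'
#' @param x contribution proportions.
#' @param C coancestry matrix.
#' @return Numeric scalar on the 0--1 coancestry scale.
#' @export
group_coancestry <- function(x, C) {
  stopifnot(length(x) == nrow(C))
  drop(crossprod(x, C %*% x))
}

#' Mean expected progeny inbreeding of a mating plan
#'
#' The mean over matings of the parents' coancestry, which equals the expected
#' inbreeding coefficient of their progeny; a selfed mating (i, i) contributes
#' the self-coancestry \code{C[i, i]}.
#'
#' @param plan a \code{MatingPlan} (from [decode_chromosome()]) or an M x 2
#'   matrix of parent indices/IDs.
#' @param C coancestry matrix (ID dimnames required when the plan uses IDs).
#' @return Numeric scalar.
#' @export
mean_progeny_inbreeding <- function(plan, C) {
  m <- if (inherits(plan, "MatingPlan")) plan$matings else plan
  mean(C[cbind(m[, 1L], m[, 2L])])
}

#' Coancestry trade-off target
#'
#' A target for the balance between genetic gain and group coancestry, in one
#' of four equivalent forms: an absolute coancestry value, a rate of coancestry
#' increase, a percentage of the normalized gain--diversity span, or
#' trigonometric degrees on that span (0 degrees = pure gain, 90 degrees =
#' pure diversity).
#'
#' @param form one of \code{"coancestry_value"}, \code{"coancestry_rate"},
#'   \code{"percent_of_min"}, \code{"degrees"}.
#' @param value the target value; degrees in \code{[0, 90]}, percent in
#'   \code{[0, 100]}, rate in \code{(-1, 1)}.
#' @return An object of class \code{TargetSpec}.
#' @export
target_spec <- function(form = c("degrees", "coancestry_value",
                                 "coancestry_rate", "percent_of_min"),
                        value) {
  form <- match.arg(form)
  value <- as.numeric(value)
  if (form == "degrees" && (value < 0 || value > 90))
    stop("degrees target must lie in [0, 90]")
  if (form == "percent_of_min" && (value < 0 || value > 100))
    stop("percent target must lie in [0, 100]")
  if (form == "coancestry_rate" && (value <= -1 || value >= 1))
    stop("coancestry rate target must lie in (-1, 1)")
  structure(list(form = form, value = value), class = "TargetSpec")
}

#' Resolve a trade-off target to a coancestry constraint
#'
#' Converts any [target_spec()] form into the absolute group-coancestry bound
#' C* used by the epsilon-constraint solve:
#' \itemize{
#'   \item value form: C* as given;
#'   \item rate form: \code{C* = C_current + dC * (1 - C_current)};
#'   \item percent form: \code{C* = C_min + (p / 100) * (C_at_Gmax - C_min)};
#'   \item degrees form: \code{C* = C_min + cos(theta) * (C_at_Gmax - C_min)},
#'     so 0 degrees recovers the max-gain bound and 90 degrees the
#'     min-coancestry bound.
#' }
#' Resolved values outside \code{[C_min, C_at_Gmax]} are clamped with a
#' warning.
#'
#' @param target a [target_spec()].
#' @param bounds an \code{ObjectiveBounds} from [find_bounds()] (or a list with
#'   \code{C_min} and \code{C_at_Gmax}).
#' @param C_current current group coancestry, used by the rate form; defaults
#'   to the group coancestry under uniform contributions when a problem is
#'   attached to \code{bounds}.
#' @return The resolved coancestry bound C*.
#' @export
resolve_coancestry_target <- function(target, bounds, C_current = NULL) {
  C_min <- bounds$C_min
  C_hi <- bounds$C_at_Gmax
  if (C_hi < C_min - 1e-9) stop("degenerate bounds: C_at_Gmax < C_min")
  Cstar <- switch(target$form,
    coancestry_value = target$value,
    coancestry_rate = {
      if (is.null(C_current)) stop("rate target needs C_current")
      C_current + target$value * (1 - C_current)
    },
    percent_of_min = C_min + (target$value / 100) * (C_hi - C_min),
    degrees = C_min + cos(target$value * pi / 180) * (C_hi - C_min))
  lo <- min(C_min, C_hi)
  hi <- max(C_min, C_hi)
  if (Cstar < lo - 1e-12 || Cstar > hi + 1e-12) {
    warning("resolved coancestry target ", format(Cstar),
            " clamped into [", format(lo), ", ", format(hi), "]")
    Cstar <- min(max(Cstar, lo), hi)
  }
  Cstar
}

#' Penalized scalar objective
#'
#' Combines the raw objective values into the single maximized scalar the
#' evolver works with. Residual constraint breaches (contribution limits,
#' selfing) are penalized as \code{w * violations / M}; in target mode the
#' coancestry excess over C* is penalized as
#' \code{w * max(0, coancestry - C*) / (C_at_Gmax - C_min)} (exact-penalty
#' epsilon-constraint).
#'
#' @param vals list with \code{gain}, \code{coancestry}, \code{inbreeding} and
#'   \code{violations} (residual breach count).
#' @param mode objective mode.
#' @param n_matings number of matings M.
#' @param Cstar resolved coancestry bound (target mode).
#' @param span normalization span \code{C_at_Gmax - C_min} (target mode).
#' @param penalty_weight penalty weight w.
#' @return List with \code{scalar} (maximized) and \code{penalty}.
#' @export
penalized_objective <- function(vals, mode = c("max_gain", "min_coancestry",
                                               "min_inbreeding", "target"),
                                n_matings, Cstar = NA_real_, span = NA_real_,
                                penalty_weight = 1e4) {
  mode <- match.arg(mode)
  viol <- if (is.null(vals$violations)) 0 else vals$violations
  pen <- penalty_weight * viol / n_matings
  if (mode == "target" && !is.na(span) && span > 0)
    pen <- pen + penalty_weight * max(0, vals$coancestry - Cstar) / span
  base <- switch(mode, max_gain = vals$gain, target = vals$gain,
                 min_coancestry = -vals$coancestry,
                 min_inbreeding = -vals$inbreeding)
  list(scalar = base - pen, penalty = pen)
}
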
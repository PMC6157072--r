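#' Mating constraints
#'
#' Defines what a valid mating plan looks like: the number of matings M, the
#' maximal number of parents used per gender role, minimum/maximum (or equal)
#' contributions per selected parent, and whether selfing is allowed (generic
#' mode only). In gendered mode each role supplies M contributions; in generic
#' mode the single pool supplies 2M (each mating uses two slots).
#'
#' @param n_matings positive integer M, number of matings to plan.
#' @param max_parents maximal number of parents with non-zero contributions
#'   (generic mode, and the default for both roles in gendered mode).
#' @param max_parents_male,max_parents_female per-role overrides.
#' @param min_contrib,max_contrib minimum/maximum contributions (matings
#'   participated in) per selected parent. Equal contributions are expressed as
#'   \code{min_contrib == max_contrib}.
#' @param allow_selfing logical; may a generic candidate be mated to itself?
#' @param gendered logical; male/female roles (codes 1/2) or one generic pool.
#' @return An object of class \code{MatingConstraints}.
#' @export
mating_constraints <- function(n_matings, max_parents = Inf,
                               max_parents_male = max_parents,
                               max_parents_female = max_parents,
                               min_contrib = 0, max_contrib = Inf,
                               allow_selfing = TRUE, gendered = FALSE) {
  n_matings <- as.integer(n_matings)
  if (is.na(n_matings) || n_matings < 1L) stop("n_matings must be a positive integer")
  if (min_contrib < 0) stop("min_contrib must be non-negative")
  if (max_contrib < min_contrib) stop("max_contrib must be >= min_contrib")
  structure(list(n_matings = n_matings,
                 max_parents = max_parents,
                 max_parents_male = max_parents_male,
                 max_parents_female = max_parents_female,
                 min_contrib = as.numeric(min_contrib),
                 max_contrib = as.numeric(max_contrib),
                 allow_selfing = isTRUE(allow_selfing),
                 gendered = isTRUE(gendered)),
            class = "MatingConstraints")
}

role_total <- function(constraints) {
  if (constraints$gendered) constraints$n_matings else 2L * constraints$n_matings
}

# clamp Inf limits to concrete integers for a role of size n_role
role_limits <- function(constraints, n_role, role = c("generic", "male", "female")) {
  role <- match.arg(role)
  T <- role_total(constraints)
  maxp <- switch(role, generic = constraints$max_parents,
                 male = constraints$max_parents_male,
                 female = constraints$max_parents_female)
  list(T = T,
       min = as.integer(min(constraints$min_contrib, T)),
       max = as.integer(min(constraints$max_contrib, T)),
       maxp = as.integer(min(maxp, n_role)))
}

#' Check that a valid mating plan can exist
#'
#' Verifies the feasibility of mating constraints against a candidate set:
#' enough candidates and contribution capacity per role, a contribution count
#' compatible with the min/max (including divisibility for equal
#' contributions), at least one candidate of each gender in gendered mode, and
#' at least two candidates when selfing is disallowed.
#'
#' @param constraints a [mating_constraints()].
#' @param candidates a [candidate_set()].
#' @return Character vector of violated conditions; empty when feasible.
#' @export
validate_constraints <- function(constraints, candidates) {
  errs <- character(0)
  gendered_cands <- any(candidates$gender != 0L)
  if (constraints$gendered != gendered_cands)
    errs <- c(errs, "gendered flag does not match candidate gender codes")
  roles <- if (constraints$gendered)
    list(male = sum(candidates$gender == 1L), female = sum(candidates$gender == 2L))
  else list(generic = candidates$n)
  for (role in names(roles)) {
    n_role <- roles[[role]]
    if (n_role < 1L) {
      errs <- c(errs, paste0("no ", role, " candidates available"))
      next
    }
    lim <- role_limits(constraints, n_role, role)
    if (role == "generic" && !constraints$allow_selfing) {
      # a selfing-free plan never uses one parent in more than M matings
      lim$max <- min(lim$max, constraints$n_matings)
      if (lim$min > lim$max) {
        errs <- c(errs, paste0("min_contrib exceeds the per-parent maximum ",
                               "compatible with no selfing (", lim$max, ")"))
        next
      }
    }
    if (lim$max < 1L) {
      errs <- c(errs, paste0(role, ": max_contrib below 1"))
      next
    }
    if (n_role * lim$max < lim$T)
      errs <- c(errs, paste0(role, ": candidates x max_contrib < required total ",
                             lim$T))
    if (lim$maxp * lim$max < lim$T)
      errs <- c(errs, paste0(role, ": max_parents x max_contrib < required total ",
                             lim$T))
    k <- seq_len(min(lim$maxp, n_role))
    feasible_k <- any(k * max(lim$min, 1L) <= lim$T & k * lim$max >= lim$T &
                        (lim$min == 0L | k * lim$min <= lim$T))
    if (lim$min > 0L) {
      k_ok <- any(k * lim$min <= lim$T & k * lim$max >= lim$T)
      if (!k_ok)
        errs <- c(errs, paste0(role, ": no parent count satisfies the ",
                               "min/max contribution limits (total ", lim$T, ")"))
    } else if (!feasible_k) {
      errs <- c(errs, paste0(role, ": constraints admit no valid parent count"))
    }
  }
  if (!constraints$gendered && !constraints$allow_selfing && candidates$n < 2L)
    errs <- c(errs, "selfing disallowed but only one candidate available")
  errs
}
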
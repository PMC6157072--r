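#' Define a contribution/mate-allocation optimization problem
#'
#' Bundles candidates, their coancestry matrix, the mating constraints and the
#' optimization objective into one problem object that the evolver, frontier
#' and brute-force oracle all consume.
#'
#' The selection criterion is standardized internally (mean 0, population SD 1)
#' so that penalty weights and the degree-based trade-off targets are
#' scale-free; the raw criterion is kept for reporting. When an edited
#' criterion is present it is standardized with the same (non-edited) location
#' and scale so both merits stay on one scale.
#'
#' @param candidates a [candidate_set()].
#' @param coancestry square coancestry matrix aligned (by dimnames, or by
#'   order) with the candidates.
#' @param constraints a [mating_constraints()]; its \code{gendered} flag must
#'   match the candidate gender codes.
#' @param mode one of \code{"max_gain"}, \code{"min_coancestry"},
#'   \code{"min_inbreeding"}, \code{"target"}.
#' @param target for \code{mode = "target"}: a [target_spec()].
#' @param edit_budget integer k >= 0 of candidates that may be genome edited.
#' @param editable candidate IDs eligible for editing; default all males in
#'   gendered mode, all candidates in generic mode.
#' @param penalty_weight weight w of the constraint/target penalty on the
#'   normalized violation scale.
#' @return An object of class \code{ocs_problem}.
#' @export
ocs_problem <- function(candidates, coancestry, constraints,
                        mode = c("max_gain", "min_coancestry",
                                 "min_inbreeding", "target"),
                        target = NULL, edit_budget = 0L, editable = NULL,
                        penalty_weight = 1e4) {
  mode <- match.arg(mode)
  stopifnot(inherits(candidates, "CandidateSet"),
            inherits(constraints, "MatingConstraints"))
  K <- align_coancestry(coancestry, candidates)
  errs <- validate_constraints(constraints, candidates)
  if (length(errs)) stop("infeasible mating constraints:\n  ",
                         paste(errs, collapse = "\n  "))
  needs_criterion <- mode %in% c("max_gain", "target")
  a_std <- rep(0, candidates$n)
  std <- NULL
  if (!is.null(candidates$criterion)) {
    std <- standardize_params(candidates$criterion)
    a_std <- (candidates$criterion - std$mean) / std$sd
  } else if (needs_criterion) {
    stop("mode '", mode, "' requires a selection criterion")
  }
  edit_budget <- as.integer(edit_budget)
  a_std_edit <- a_std
  editable_idx <- integer(0)
  if (edit_budget > 0L) {
    if (is.null(candidates$criterion_edited))
      stop("editing requires criterion_edited for the candidates")
    if (is.null(editable)) {
      editable_idx <- if (constraints$gendered) which(candidates$gender == 1L)
      else seq_len(candidates$n)
    } else {
      editable_idx <- match(as.character(editable), candidates$ids)
      if (anyNA(editable_idx)) stop("unknown editable ID")
    }
    if (edit_budget > length(editable_idx))
      stop("edit budget exceeds the number of editable candidates")
    a_std_edit <- (candidates$criterion_edited - std$mean) / std$sd
  }
  if (mode == "target" && is.null(target))
    stop("mode 'target' requires a target specification")
  structure(list(candidates = candidates, K = K, constraints = constraints,
                 mode = mode, target = target,
                 a_std = a_std, a_std_edit = a_std_edit, std = std,
                 edit_budget = edit_budget, editable = editable_idx,
                 penalty_weight = penalty_weight),
            class = "ocs_problem")
}

#' @export
print.ocs_problem <- function(x, ...) {
  cat("ocs_problem:", x$candidates$n, "candidates,",
      x$constraints$n_matings, "matings, mode", x$mode, "\n")
  if (x$edit_budget > 0L)
    cat("  editing: budget", x$edit_budget, "of", length(x$editable),
        "editable candidates\n")
  invisible(x)
}

role_indices <- function(problem) {
  g <- problem$candidates$gender
  if (problem$constraints$gendered)
    list(male = which(g == 1L), female = which(g == 2L))
  else list(generic = seq_len(problem$candidates$n))
}

#' Chromosome length of a problem
#'
#' Contribution genes (one per candidate per role), mate-permutation keys
#' (M in gendered mode, 2M in generic mode) and, when editing is enabled, one
#' edit-rank gene per editable candidate.
#'
#' @param problem an [ocs_problem()].
#' @return Integer length.
#' @export
chromosome_length <- function(problem) {
  M <- problem$constraints$n_matings
  n_mate <- if (problem$constraints$gendered) M else 2L * M
  n_edit <- if (problem$edit_budget > 0L) length(problem$editable) else 0L
  problem$candidates$n + n_mate + n_edit
}

# list consumed by the compiled evaluator
problem_data <- function(problem, mode = problem$mode, Cstar = NA_real_,
                         span = NA_real_) {
  cn <- problem$constraints
  roles <- role_indices(problem)
  r1 <- roles[[1L]]
  lim1 <- role_limits(cn, length(r1), names(roles)[1L])
  dat <- list(n = problem$candidates$n, M = cn$n_matings,
              gendered = cn$gendered, allow_selfing = cn$allow_selfing,
              role1_idx = as.integer(r1), role1_T = lim1$T,
              role1_min = lim1$min, role1_max = lim1$max, role1_maxp = lim1$maxp,
              K = problem$K, a = problem$a_std, a_edit = problem$a_std_edit,
              mode = match(mode, c("max_gain", "min_coancestry",
                                   "min_inbreeding", "target")) - 1L,
              Cstar = if (is.na(Cstar)) 0 else Cstar,
              span = if (is.na(span)) 0 else span,
              w = problem$penalty_weight,
              edit_budget = problem$edit_budget,
              editable = as.integer(problem$editable))
  if (cn$gendered) {
    r2 <- roles[[2L]]
    lim2 <- role_limits(cn, length(r2), "female")
    dat$role2_idx <- as.integer(r2)
    dat$role2_T <- lim2$T
    dat$role2_min <- lim2$min
    dat$role2_max <- lim2$max
    dat$role2_maxp <- lim2$maxp
  }
  dat
}

#' Decode a chromosome into a mating plan
#'
#' Deterministically maps any real-valued chromosome to a mating plan:
#' contribution genes are ranked and integerized per role
#' ([integerize_contributions()]), mate keys permute the contribution slots
#' ([allocate_mates()]), selfing is repaired in generic mode when disallowed
#' ([repair_selfing()]), and edit-rank genes select which contributors are
#' edited. Residual constraint breaches are counted in \code{violations}, not
#' thrown.
#'
#' @param chrom numeric vector of length [chromosome_length()].
#' @param problem an [ocs_problem()].
#' @param mode objective mode used for the reported scalar (defaults to the
#'   problem's mode).
#' @param Cstar,span resolved coancestry constraint and normalization span for
#'   \code{mode = "target"}.
#' @return A \code{MatingPlan}: list with \code{matings} (M x 2 ID matrix),
#'   \code{matings_idx}, \code{n_contrib}, \code{x} (proportional
#'   contributions), \code{violations}, \code{edited} (IDs) and
#'   \code{objectives} (gain, coancestry, inbreeding, penalty, scalar).
#' @export
decode_chromosome <- function(chrom, problem, mode = problem$mode,
                              Cstar = NA_real_, span = NA_real_) {
  dat <- problem_data(problem, mode, Cstar, span)
  raw <- cpp_decode_plan(as.numeric(chrom), dat)
  ids <- problem$candidates$ids
  matings <- cbind(ids[raw$matings[, 1L]], ids[raw$matings[, 2L]])
  colnames(matings) <- c("Parent1", "Parent2")
  n_contrib <- stats::setNames(raw$n_contrib, ids)
  x <- n_contrib / (2 * problem$constraints$n_matings)
  structure(list(matings = matings, matings_idx = raw$matings,
                 n_contrib = n_contrib, x = x,
                 violations = raw$violations,
                 edited = ids[raw$edited],
                 objectives = list(gain = raw$gain, coancestry = raw$coancestry,
                                   inbreeding = raw$inbreeding,
                                   penalty = raw$penalty, scalar = raw$scalar)),
            class = "MatingPlan")
}

#' @export
print.MatingPlan <- function(x, ...) {
  cat("MatingPlan:", nrow(x$matings), "matings,",
      sum(x$n_contrib > 0), "contributors, violations", x$violations, "\n")
  o <- x$objectives
  cat(sprintf("  gain %.4f  coancestry %.4f  inbreeding %.4f  penalty %.4g\n",
              o$gain, o$coancestry, o$inbreeding, o$penalty))
  if (length(x$edited)) cat("  edited:", paste(x$edited, collapse = ", "), "\n")
  invisible(x)
}
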
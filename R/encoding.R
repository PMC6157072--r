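#' Integerize contribution genes for one gender role
#'
#' Implements the trim-and-round step of the plan decoder: candidates are
#' ranked by gene value (descending, ties by position), a feasible number of
#' top candidates is kept, positive gene parts are normalized to shares, share
#' targets are clamped to the contribution limits, and a largest-remainder
#' apportionment rounds them to integers summing exactly to the role total
#' (M in gendered mode, 2M in generic mode). Increments only go to candidates
#' below the maximum and decrements only to those above the minimum; breaches
#' that the constraints force anyway are counted as violations.
#'
#' @param genes numeric vector, one gene per candidate of the role.
#' @param constraints a [mating_constraints()].
#' @param role \code{"generic"}, \code{"male"} or \code{"female"}.
#' @return Integer vector of contributions per candidate, with attribute
#'   \code{violations}.
#' @export
integerize_contributions <- function(genes, constraints,
                                     role = c("generic", "male", "female")) {
  role <- match.arg(role)
  lim <- role_limits(constraints, length(genes), role)
  res <- cpp_integerize(as.numeric(genes), lim$T, lim$min, lim$max, lim$maxp)
  structure(res$n, violations = res$violations)
}

#' Allocate mates from contribution counts and permutation keys
#'
#' Expands per-candidate contribution counts into slot lists (candidate-file
#' order) and pairs slots according to the stable argsort of the mate keys.
#' Gendered mode: male slot k is paired with female slot \code{pi[k]} where
#' \code{pi} is the argsort of M keys. Generic mode: the 2M keys' argsort
#' orders the single slot list and consecutive ordered slots are paired.
#'
#' @param n_male integer contributions per male (or per candidate in generic
#'   mode).
#' @param n_female integer contributions per female; \code{NULL} for generic
#'   mode.
#' @param mate_genes numeric permutation keys: length M (gendered) or 2M
#'   (generic).
#' @return Integer matrix with M rows and columns Parent1, Parent2 holding
#'   positions within the supplied vectors.
#' @export
allocate_mates <- function(n_male, n_female = NULL, mate_genes) {
  slots_of <- function(n) rep(seq_along(n), times = n)
  if (!is.null(n_female)) {
    ms <- slots_of(n_male)
    fs <- slots_of(n_female)
    if (length(ms) != length(fs)) stop("male and female slot counts differ")
    M <- length(ms)
    if (length(mate_genes) != M) stop("need ", M, " mate keys")
    pi <- order(mate_genes, seq_len(M))
    out <- cbind(Parent1 = ms, Parent2 = fs[pi])
  } else {
    sl <- slots_of(n_male)
    if (length(sl) %% 2L != 0L) stop("generic slot count must be even")
    M <- length(sl) %/% 2L
    if (length(mate_genes) != 2L * M) stop("need ", 2L * M, " mate keys")
    pi <- order(mate_genes, seq_len(2L * M))
    sl <- sl[pi]
    out <- cbind(Parent1 = sl[seq(1L, 2L * M, by = 2L)],
                 Parent2 = sl[seq(2L, 2L * M, by = 2L)])
  }
  out
}

#' Repair selfed matings in a generic-mode plan
#'
#' When selfing is disallowed, each selfed mating (i, i) is repaired by
#' swapping its second parent with that of the next mating (circularly) whose
#' swap removes the selfing without creating a new one. Selfings that no swap
#' can remove are counted as violations.
#'
#' @param matings integer or character matrix with columns Parent1, Parent2.
#' @param allow_selfing logical; when \code{TRUE} the input is returned
#'   unchanged.
#' @return The matings matrix with attribute \code{violations} (number of
#'   irreparable selfings).
#' @export
repair_selfing <- function(matings, allow_selfing = FALSE) {
  if (allow_selfing)
    return(structure(matings, violations = 0))
  M <- nrow(matings)
  viol <- 0
  for (k in seq_len(M)) {
    if (matings[k, 1L] != matings[k, 2L]) next
    i <- matings[k, 1L]
    fixed <- FALSE
    for (shift in seq_len(M - 1L)) {
      j <- (k - 1L + shift) %% M + 1L
      if (matings[j, 1L] != i && matings[j, 2L] != i) {
        tmp <- matings[k, 2L]
        matings[k, 2L] <- matings[j, 2L]
        matings[j, 2L] <- tmp
        fixed <- TRUE
        break
      }
    }
    if (!fixed) viol <- viol + 1
  }
  structure(matings, violations = viol)
}
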
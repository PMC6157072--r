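#' Decide which contributors are genome edited
#'
#' Among editable candidates that are selected in the plan (contribution
#' greater than zero), the \code{budget} with the highest edit-rank genes are
#' edited (ties by candidate order). When fewer editable candidates are
#' selected than the budget allows, all of them are edited -- the budget is
#' never forced onto non-contributors.
#'
#' @param edit_genes numeric edit-rank genes, one per editable candidate.
#' @param n_contrib integer contributions per candidate (full candidate
#'   vector), or a \code{MatingPlan}.
#' @param editable integer indices (into the candidate set) of editable
#'   candidates, aligned with \code{edit_genes}.
#' @param budget integer k >= 0.
#' @return Integer indices of the edited candidates (sorted).
#' @export
decode_edits <- function(edit_genes, n_contrib, editable, budget) {
  if (inherits(n_contrib, "MatingPlan")) n_contrib <- n_contrib$n_contrib
  stopifnot(length(edit_genes) == length(editable))
  if (budget <= 0L) return(integer(0))
  sel <- which(n_contrib[editable] > 0)
  if (!length(sel)) return(integer(0))
  ord <- sel[order(-edit_genes[sel], sel)]
  sort(editable[ord[seq_len(min(budget, length(ord)))]])
}

#' Genetic gain with genome-edited contributors
#'
#' \code{sum(x * m)} where \code{m} equals the edited standardized criterion
#' for edited candidates and the non-edited one otherwise. Both criteria must
#' be standardized with the same (non-edited) location and scale so they stay
#' comparable; [ocs_problem()] does this automatically.
#'
#' @param x contribution proportions.
#' @param a_std standardized non-edited criteria.
#' @param a_std_edited standardized edited criteria (same scale).
#' @param edited integer indices of edited candidates.
#' @return Numeric scalar.
#' @export
gain_with_edits <- function(x, a_std, a_std_edited, edited) {
  stopifnot(length(x) == length(a_std), length(a_std) == length(a_std_edited))
  m <- a_std
  if (length(edited)) m[edited] <- a_std_edited[edited]
  sum(x * m)
}
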
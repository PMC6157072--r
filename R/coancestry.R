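#' Read a coancestry matrix file
#'
#' Reads a square coancestry (kinship) matrix from delimited text with a
#' leading ID column, reorders rows and columns to match \code{ids}, and
#' symmetrizes small numerical asymmetries as \code{(V + t(V)) / 2}.
#'
#' @param path path to the matrix file (whitespace- or comma-delimited; rows
#'   may be in any order).
#' @param ids character vector of candidate identifiers defining the output
#'   order.
#' @return A numeric \code{length(ids)} square matrix with \code{ids} as
#'   dimnames.
#' @export
read_coancestry_matrix <- function(path, ids) {
  ids <- as.character(ids)
  lines <- read_delim_lines(path)
  fields <- lapply(lines, split_fields)
  n <- length(fields)
  if (!n) stop("empty coancestry matrix file: ", path)
  if (any(lengths(fields) != n + 1L))
    stop("coancestry matrix is not square in ", path)
  row_ids <- vapply(fields, `[`, "", 1L)
  unknown <- setdiff(row_ids, ids)
  if (length(unknown)) stop("unknown ID ", unknown[1L])
  missing <- setdiff(ids, row_ids)
  if (length(missing)) stop("missing ID ", missing[1L])
  V <- t(vapply(fields, function(f) as.numeric(f[-1L]), numeric(n)))
  if (anyNA(V)) stop("non-numeric entry in coancestry matrix ", path)
  dimnames(V) <- list(row_ids, row_ids)
  V <- V[ids, ids, drop = FALSE]
  asym <- max(abs(V - t(V)))
  if (asym > 1e-6)
    stop("coancestry matrix asymmetry ", format(asym), " exceeds 1e-6")
  (V + t(V)) / 2
}

#' Write a coancestry matrix file
#'
#' @param K square numeric matrix with ID dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_coancestry_matrix <- function(K, path) {
  ids <- rownames(K)
  if (is.null(ids)) stop("coancestry matrix must carry ID dimnames")
  writeLines(paste(ids, apply(K, 1L, function(r)
    paste(sprintf("%.12g", r), collapse = " "))), path)
  invisible(path)
}

#' Coancestry from a pedigree (tabular method)
#'
#' Builds the numerator relationship matrix A by the tabular method and returns
#' the coancestry (kinship) matrix theta = A / 2, so that
#' \code{theta[i, i] = 0.5 * (1 + F_i)}. Unknown parents (code \code{"0"},
#' \code{""} or \code{NA}) are treated as unrelated, non-inbred founders. The
#' pedigree is topologically sorted internally; a cycle (an individual being
#' its own ancestor) is an error.
#'
#' @param pedigree data frame (or 3-column matrix) with columns individual,
#'   sire, dam.
#' @return Coancestry matrix with individual IDs as dimnames, rows in the
#'   input pedigree order.
#' @export
coancestry_from_pedigree <- function(pedigree) {
  ped <- as.data.frame(pedigree, stringsAsFactors = FALSE)
  if (ncol(ped) < 3L) stop("pedigree needs columns id, sire, dam")
  id <- as.character(ped[[1L]])
  sire <- as.character(ped[[2L]])
  dam <- as.character(ped[[3L]])
  if (anyDuplicated(id)) stop("duplicate ID ", id[duplicated(id)][1L])
  unknown <- function(x) is.na(x) | x == "0" | x == ""
  sire[unknown(sire)] <- NA_character_
  dam[unknown(dam)] <- NA_character_
  for (p in c(sire, dam))
    if (!is.na(p) && !(p %in% id))
      stop("parent ", p, " has no pedigree record")
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)

  # Kahn topological sort: parents before offspring
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  order_idx <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order_idx <- c(order_idx, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order_idx) != n)
    stop("pedigree cycle: an individual is its own ancestor")

  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in order_idx) {
    s <- si[i]; d <- di[i]
    earlier <- order_idx[seq_len(match(i, order_idx) - 1L)]
    if (length(earlier)) {
      as_ <- if (is.na(s)) 0 else A[earlier, s]
      ad_ <- if (is.na(d)) 0 else A[earlier, d]
      A[earlier, i] <- A[i, earlier] <- 0.5 * (as_ + ad_)
    }
    Asd <- if (is.na(s) || is.na(d)) 0 else A[s, d]
    A[i, i] <- 1 + 0.5 * Asd
  }
  A / 2
}

#' Coancestry from marker genotypes (IBS allele sharing)
#'
#' Computes the genomic coancestry of each pair as the proportion of marker
#' alleles in common, averaged over loci: per-locus sharing is
#' \code{s(a, b) = (2 - |a - b|) / 2} for dosages \code{a, b} in
#' \code{{0, 1, 2}}, with the convention \code{s(1, 1) = 0.5} (two
#' heterozygotes share one random allele each in expectation). Values lie in
#' \code{[0, 1]}; the diagonal is 1 for a fully homozygous individual and 0.5
#' at a heterozygous locus.
#'
#' @param genotypes integer matrix, individuals in rows, biallelic loci in
#'   columns, allele dosages 0/1/2; row names taken as candidate IDs. No
#'   missing values are allowed.
#' @return Symmetric coancestry matrix on the 0--1 scale.
#' @export
coancestry_from_markers <- function(genotypes) {
  G <- as.matrix(genotypes)
  storage.mode(G) <- "double"
  if (anyNA(G)) stop("missing genotype values are not supported")
  if (!all(G %in% c(0, 2, 1))) stop("genotype dosages must be 0, 1 or 2")
  L <- ncol(G)
  if (L < 1L) stop("at least one locus is required")
  sq <- rowSums(G^2)
  GG <- tcrossprod(G)
  D2 <- outer(sq, sq, "+") - 2 * GG          # sum over loci of (a - b)^2
  A0 <- G == 0
  A2 <- G == 2
  N4 <- tcrossprod(A0, A2)                   # loci with |a - b| = 2
  N4 <- N4 + t(N4)
  Dabs <- D2 - 2 * N4                        # sum over loci of |a - b|
  BH <- tcrossprod(G == 1)                   # both-heterozygote loci
  K <- 1 - Dabs / (2 * L) - 0.5 * BH / L
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(genotypes), rownames(genotypes))
  K
}

#' Validate and align a coancestry matrix to a candidate set
#'
#' @param K square numeric matrix with ID dimnames (or unnamed, in which case
#'   it is assumed aligned).
#' @param candidates a [candidate_set()].
#' @return The matrix reordered to the candidate order.
#' @keywords internal
align_coancestry <- function(K, candidates) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("coancestry matrix must be square")
  if (!is.null(rownames(K))) {
    missing <- setdiff(candidates$ids, rownames(K))
    if (length(missing)) stop("missing ID ", missing[1L], " in coancestry matrix")
    K <- K[candidates$ids, candidates$ids, drop = FALSE]
  } else {
    if (nrow(K) != candidates$n)
      stop("coancestry matrix dimension does not match candidate count")
    dimnames(K) <- list(candidates$ids, candidates$ids)
  }
  if (max(abs(K - t(K))) > 1e-8) stop("coancestry matrix is not symmetric")
  K
}
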
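#' Construct a set of selection candidates
#'
#' A candidate set holds the individuals available as parents: their
#' identifiers, gender codes, and (optionally) a selection criterion such as an
#' estimated breeding value, plus the criterion the candidate would have after
#' hypothetical genome editing.
#'
#' Gender codes are \code{0} (generic, e.g. a monoecious plant that can act as
#' either parent), \code{1} (male) or \code{2} (female). Generic and gendered
#' codes cannot be mixed within one set.
#'
#' @param ids character vector of unique identifiers.
#' @param gender integer vector of codes in \code{{0}} or \code{{1, 2}};
#'   defaults to all-generic.
#' @param criterion optional numeric selection criterion, one per candidate.
#' @param criterion_edited optional numeric criterion after editing; requires
#'   \code{criterion}.
#' @return An object of class \code{CandidateSet}: a list with elements
#'   \code{ids}, \code{gender}, \code{criterion}, \code{criterion_edited},
#'   \code{n}.
#' @export
candidate_set <- function(ids, gender = NULL, criterion = NULL,
                          criterion_edited = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  if (n < 1L) stop("at least one candidate is required")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate ID ", dup[1L])
  if (is.null(gender)) gender <- rep(0L, n)
  gender <- as.integer(gender)
  if (length(gender) != n) stop("gender must have one code per candidate")
  if (!all(gender %in% c(0L, 1L, 2L)))
    stop("gender codes must be 0 (generic), 1 (male) or 2 (female)")
  if (any(gender == 0L) && any(gender != 0L))
    stop("generic (0) and gendered (1/2) codes cannot be mixed")
  if (!is.null(criterion)) {
    criterion <- as.numeric(criterion)
    if (length(criterion) != n) stop("criterion must have length ", n)
    if (anyNA(criterion)) stop("criterion contains missing values")
  }
  if (!is.null(criterion_edited)) {
    if (is.null(criterion)) stop("criterion_edited requires criterion")
    criterion_edited <- as.numeric(criterion_edited)
    if (length(criterion_edited) != n) stop("criterion_edited must have length ", n)
    if (anyNA(criterion_edited)) stop("criterion_edited contains missing values")
  }
  structure(list(ids = ids, gender = gender, criterion = criterion,
                 criterion_edited = criterion_edited, n = n),
            class = "CandidateSet")
}

#' @export
print.CandidateSet <- function(x, ...) {
  mode <- if (all(x$gender == 0L)) "generic" else "gendered"
  cat("CandidateSet:", x$n, "candidates (", mode, ")\n")
  if (mode == "gendered")
    cat("  males:", sum(x$gender == 1L), " females:", sum(x$gender == 2L), "\n")
  if (!is.null(x$criterion))
    cat("  criterion: mean", format(mean(x$criterion), digits = 4),
        "sd", format(stats::sd(x$criterion), digits = 4), "\n")
  if (!is.null(x$criterion_edited)) cat("  edited criterion present\n")
  invisible(x)
}

#' Read a candidate file
#'
#' Reads a whitespace- or comma-delimited text file with columns
#' \code{Id [Gender] [Criterion] [CriterionEdited]}. A header line is
#' auto-detected (any non-numeric field after the first on line one), or can be
#' forced with \code{header}. A two-column file is read as \code{Id Gender}
#' when every second-column value is an integer in \code{{0, 1, 2}}, and as
#' \code{Id Criterion} otherwise.
#'
#' @param path path to the file.
#' @param header \code{NA} (auto-detect), \code{TRUE} or \code{FALSE}.
#' @return A [candidate_set()].
#' @export
read_candidates <- function(path, header = NA) {
  lines <- read_delim_lines(path)
  if (!length(lines)) stop("empty candidate file: ", path)
  fields <- lapply(lines, split_fields)
  ncol <- length(fields[[1L]])
  if (any(lengths(fields) != ncol))
    stop("inconsistent number of columns in ", path)
  if (is.na(header)) {
    header <- ncol > 1L &&
      any(is.na(suppressWarnings(as.numeric(fields[[1L]][-1L]))))
  }
  if (header) fields <- fields[-1L]
  if (!length(fields)) stop("no candidate rows in ", path)
  tab <- do.call(rbind, fields)
  ids <- tab[, 1L]
  gender <- NULL
  crit_cols <- integer(0)
  if (ncol >= 2L) {
    second <- suppressWarnings(as.numeric(tab[, 2L]))
    bad <- which(is.na(second))
    if (length(bad)) stop("non-numeric value '", tab[bad[1L], 2L],
                          "' on line ", bad[1L] + header)
    is_gender <- all(second %in% c(0, 1, 2)) &&
      (ncol >= 3L || all(second == round(second)))
    if (is_gender) {
      gender <- as.integer(second)
      crit_cols <- seq(3L, ncol)[seq_len(max(0L, ncol - 2L))]
    } else {
      if (ncol > 3L) stop("too many columns for a genderless candidate file")
      crit_cols <- seq(2L, ncol)
    }
  }
  crit <- crit_edit <- NULL
  if (length(crit_cols) >= 1L) crit <- parse_numeric_col(tab, crit_cols[1L], header)
  if (length(crit_cols) >= 2L) crit_edit <- parse_numeric_col(tab, crit_cols[2L], header)
  candidate_set(ids, gender, crit, crit_edit)
}

#' Write a candidate file
#'
#' Inverse of [read_candidates()]: writes \code{Id [Gender] [Criterion]
#' [CriterionEdited]} as whitespace-delimited text without header.
#'
#' @param candidates a [candidate_set()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  cols <- list(candidates$ids)
  if (any(candidates$gender != 0L) || !is.null(candidates$criterion))
    cols <- c(cols, list(candidates$gender))
  if (!is.null(candidates$criterion))
    cols <- c(cols, list(sprintf("%.10g", candidates$criterion)))
  if (!is.null(candidates$criterion_edited))
    cols <- c(cols, list(sprintf("%.10g", candidates$criterion_edited)))
  writeLines(do.call(paste, cols), path)
  invisible(path)
}

# -- shared low-level text helpers ------------------------------------------

read_delim_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

split_fields <- function(line) {
  strsplit(gsub(",", " ", line), "[[:space:]]+")[[1L]]
}

parse_numeric_col <- function(tab, col, header) {
  x <- suppressWarnings(as.numeric(tab[, col]))
  bad <- which(is.na(x))
  if (length(bad)) stop("non-numeric value '", tab[bad[1L], col],
                        "' on line ", bad[1L] + header)
  x
}
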
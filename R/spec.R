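#' Read a pedigree file
#'
#' Three whitespace/comma-delimited columns: individual, sire, dam, with
#' \code{0} (or empty) marking an unknown parent.
#'
#' @param path path to the pedigree file.
#' @return Data frame with columns id, sire, dam.
#' @export
read_pedigree <- function(path) {
  lines <- read_delim_lines(path)
  fields <- lapply(lines, split_fields)
  if (any(lengths(fields) < 3L)) stop("pedigree rows need id, sire, dam")
  if (any(is.na(suppressWarnings(as.numeric(fields[[1L]][2:3])))) &&
      tolower(fields[[1L]][1L]) %in% c("id", "individual"))
    fields <- fields[-1L]
  data.frame(id = vapply(fields, `[`, "", 1L),
             sire = vapply(fields, `[`, "", 2L),
             dam = vapply(fields, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Read a genotype file
#'
#' Each line holds an ID followed by L integer allele dosages (0/1/2).
#'
#' @param path path to the genotype file.
#' @return Integer matrix with individuals in rows (IDs as row names).
#' @export
read_genotypes <- function(path) {
  lines <- read_delim_lines(path)
  fields <- lapply(lines, split_fields)
  L <- length(fields[[1L]]) - 1L
  if (L < 1L) stop("genotype rows need an ID plus at least one locus")
  if (any(lengths(fields) != L + 1L))
    stop("inconsistent number of loci in ", path)
  G <- t(vapply(fields, function(f) as.numeric(f[-1L]), numeric(L)))
  if (anyNA(G)) stop("non-numeric genotype value in ", path)
  rownames(G) <- vapply(fields, `[`, "", 1L)
  G
}

spec_keywords <- c(
  "CandidateFile", "CoancestryMatrixFile", "PedigreeFile", "GenotypeFile",
  "NumberOfMatings", "MaxParentsMale", "MaxParentsFemale", "MaxParents",
  "MinContributions", "MaxContributions", "EqualContributions", "AllowSelfing",
  "Mode", "TargetCoancestry", "TargetCoancestryRate", "TargetPercent",
  "TargetDegrees", "EditBudget", "EvolPopSize", "EvolIterations", "EvolF",
  "EvolCR", "ConvergenceTolerance", "ConvergenceWindow", "PenaltyWeight",
  "Seed", "OutputBasename", "FrontierSteps")

#' Parse a run-specification file
#'
#' One \code{Keyword value} setting per line (case-insensitive keywords,
#' \code{#} comments). Exactly one coancestry source
#' (\code{CoancestryMatrixFile}, \code{PedigreeFile} or \code{GenotypeFile})
#' must be given; \code{Mode Target} requires exactly one target form
#' (\code{TargetCoancestry}, \code{TargetCoancestryRate}, \code{TargetPercent}
#' or \code{TargetDegrees}). Unknown keywords are an error. Relative input
#' paths are resolved against the spec file's directory.
#'
#' @param path path to the specification file.
#' @return An object of class \code{RunSpec}: resolved settings with defaults
#'   filled in, including the verbatim lines for the run log.
#' @export
parse_spec <- function(path) {
  raw <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", raw))
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(gsub(",", " ", ln), "[[:space:]]+")[[1L]]
    key <- spec_keywords[match(tolower(parts[1L]), tolower(spec_keywords))]
    if (is.na(key)) stop("unknown keyword '", parts[1L], "' in ", path)
    kv[[key]] <- parts[-1L]
  }
  dir <- dirname(path)
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(dir, p)
  num1 <- function(key, default = NULL) {
    if (is.null(kv[[key]])) return(default)
    v <- suppressWarnings(as.numeric(kv[[key]][1L]))
    if (is.na(v)) stop("non-numeric value for ", key)
    v
  }

  sources <- intersect(c("CoancestryMatrixFile", "PedigreeFile", "GenotypeFile"),
                       names(kv))
  if (length(sources) > 1L) stop("conflicting coancestry sources: ",
                                 paste(sources, collapse = ", "))
  if (length(sources) < 1L) stop("a coancestry source is required")
  if (is.null(kv$CandidateFile)) stop("CandidateFile is required")
  if (is.null(kv$NumberOfMatings)) stop("NumberOfMatings is required")

  mode_map <- c(maxgain = "max_gain", mincoancestry = "min_coancestry",
                mininbreeding = "min_inbreeding", target = "target",
                frontier = "frontier")
  mode <- "max_gain"
  if (!is.null(kv$Mode)) {
    mode <- unname(mode_map[tolower(kv$Mode[1L])])
    if (is.na(mode)) stop("unknown Mode '", kv$Mode[1L], "'")
  }

  target <- NULL
  tkeys <- intersect(c("TargetCoancestry", "TargetCoancestryRate",
                       "TargetPercent", "TargetDegrees"), names(kv))
  if (mode == "target") {
    if (length(tkeys) != 1L)
      stop("Mode Target requires exactly one target form, got ", length(tkeys))
    form <- c(TargetCoancestry = "coancestry_value",
              TargetCoancestryRate = "coancestry_rate",
              TargetPercent = "percent_of_min",
              TargetDegrees = "degrees")[[tkeys]]
    target <- target_spec(form, num1(tkeys))
  }

  equal <- num1("EqualContributions")
  min_c <- if (!is.null(equal)) equal else num1("MinContributions", 0)
  max_c <- if (!is.null(equal)) equal else num1("MaxContributions", Inf)
  allow_selfing <- TRUE
  if (!is.null(kv$AllowSelfing))
    allow_selfing <- tolower(kv$AllowSelfing[1L]) %in% c("yes", "true", "1")

  constraints_args <- list(n_matings = num1("NumberOfMatings"),
                           max_parents = num1("MaxParents", Inf),
                           min_contrib = min_c, max_contrib = max_c,
                           allow_selfing = allow_selfing)
  if (!is.null(kv$MaxParentsMale))
    constraints_args$max_parents_male <- num1("MaxParentsMale")
  if (!is.null(kv$MaxParentsFemale))
    constraints_args$max_parents_female <- num1("MaxParentsFemale")

  fr <- num1("EvolF")
  F_range <- if (is.null(fr)) c(0.1, 0.9) else {
    v <- as.numeric(kv$EvolF)
    if (length(v) >= 2L) v[1:2] else c(v, v)
  }
  CR_values <- if (is.null(kv$EvolCR)) c(0.2, 0.9) else as.numeric(kv$EvolCR)

  de <- de_config(pop_size = num1("EvolPopSize"),
                  iterations = num1("EvolIterations", 10000),
                  F_range = F_range, CR_values = CR_values,
                  tol = num1("ConvergenceTolerance", 1e-9),
                  window = num1("ConvergenceWindow", 500))

  structure(list(candidate_file = resolve(kv$CandidateFile[1L]),
                 matrix_file = if ("CoancestryMatrixFile" %in% sources)
                   resolve(kv$CoancestryMatrixFile[1L]),
                 pedigree_file = if ("PedigreeFile" %in% sources)
                   resolve(kv$PedigreeFile[1L]),
                 genotype_file = if ("GenotypeFile" %in% sources)
                   resolve(kv$GenotypeFile[1L]),
                 constraints_args = constraints_args,
                 mode = mode, target = target,
                 edit_budget = as.integer(num1("EditBudget", 0)),
                 de = de,
                 penalty_weight = num1("PenaltyWeight", 1e4),
                 seed = if (!is.null(kv$Seed)) as.integer(num1("Seed")),
                 out_basename = if (!is.null(kv$OutputBasename))
                   kv$OutputBasename[1L] else "ocsmate",
                 frontier_steps = as.integer(num1("FrontierSteps", 9)),
                 verbatim = raw),
            class = "RunSpec")
}

#' Run an optimization from a specification file
#'
#' The end-to-end pipeline behind the command-line interface: parses the run
#' specification, reads the candidate file and the coancestry source (matrix,
#' pedigree or genotypes), builds the problem, runs the requested
#' optimization, and (optionally) writes the output files.
#'
#' @param path path to the specification file.
#' @param seed optional integer overriding the spec's seed; when neither is
#'   given a seed is drawn and recorded.
#' @param write write the output files via [write_results()]?
#' @param verbosity 0 (quiet) or 1 (progress messages).
#' @return An object of class \code{ocs_run} with the problem, the optimized
#'   plan(s), the optimization log(s) and the seed used.
#' @export
run_spec <- function(path, seed = NULL, write = TRUE, verbosity = 1L) {
  rs <- parse_spec(path)
  if (!is.null(seed)) rs$seed <- as.integer(seed)
  if (is.null(rs$seed)) rs$seed <- sample.int(1e8, 1L)
  say <- function(...) if (verbosity > 0L) message(...)

  cands <- read_candidates(rs$candidate_file)
  gendered <- any(cands$gender != 0L)
  constraints <- do.call(mating_constraints,
                         c(rs$constraints_args, list(gendered = gendered)))
  K <- if (!is.null(rs$matrix_file)) {
    read_coancestry_matrix(rs$matrix_file, cands$ids)
  } else if (!is.null(rs$pedigree_file)) {
    A2 <- coancestry_from_pedigree(read_pedigree(rs$pedigree_file))
    missing <- setdiff(cands$ids, rownames(A2))
    if (length(missing)) stop("candidate ", missing[1L], " not in pedigree")
    A2[cands$ids, cands$ids]
  } else {
    G <- read_genotypes(rs$genotype_file)
    missing <- setdiff(cands$ids, rownames(G))
    if (length(missing)) stop("candidate ", missing[1L], " not genotyped")
    coancestry_from_markers(G[cands$ids, , drop = FALSE])
  }
  say("read ", cands$n, " candidates; coancestry mean ",
      format(mean(K), digits = 4))

  problem_mode <- if (rs$mode %in% c("frontier")) "max_gain" else rs$mode
  problem <- ocs_problem(cands, K, constraints, mode = problem_mode,
                         target = rs$target, edit_budget = rs$edit_budget,
                         penalty_weight = rs$penalty_weight)
  de <- rs$de
  de$seed <- rs$seed

  run <- list(spec = rs, problem = problem, mode = rs$mode, seed = rs$seed)
  if (rs$mode %in% c("max_gain", "min_coancestry", "min_inbreeding")) {
    s <- solve_single(problem, rs$mode, de)
    run$plan <- s$plan
    run$log <- s$result$log
    run$result <- s$result
  } else if (rs$mode == "target") {
    say("finding objective-space bounds")
    bounds <- find_bounds(problem, de)
    pt <- solve_target(problem, rs$target, de, bounds)
    run$bounds <- bounds
    run$point <- pt
    run$plan <- pt$plan
    run$log <- pt$result$log
  } else {
    say("sweeping the Pareto frontier (", rs$frontier_steps, " points)")
    fr <- sweep_frontier(problem, rs$frontier_steps, de)
    run$bounds <- attr(fr, "bounds")
    run$frontier <- fr
    mid <- which.min(abs(vapply(fr, `[[`, 0, "degrees") - 45))
    run$plan <- fr[[mid]]$plan
    run$log <- run$bounds$result_gain$log
  }
  class(run) <- "ocs_run"
  if (write) write_results(run)
  run
}

#' @export
print.ocs_run <- function(x, ...) {
  cat("ocs_run: mode", x$mode, " seed", x$seed, "\n")
  print(x$plan)
  invisible(x)
}
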
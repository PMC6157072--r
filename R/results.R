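#' Write the output files of a run
#'
#' Writes the five standard outputs next to the configured basename:
#' \itemize{
#'   \item \code{<base>_Summary.txt} -- input data summary;
#'   \item \code{<base>_Contributors.txt} -- \code{Id Gender Criterion
#'     nContributions xContribution Edited};
#'   \item \code{<base>_MatingPlan.txt} -- \code{Mating Parent1 Parent2
#'     ExpectedInbreeding};
#'   \item \code{<base>_OptimisationLog.txt} -- \code{Iteration BestObjective
#'     MeanObjective Gain Coancestry Inbreeding Penalty};
#'   \item \code{<base>_Seed.txt} -- the random seed, enabling byte-identical
#'     reproduction.
#' }
#' Frontier runs additionally write \code{<base>_Frontier.txt}
#' (\code{Degrees Gain Coancestry GainNorm CoancestryNorm Inbreeding}) and one
#' mating-plan file per frontier point.
#'
#' @param run an \code{ocs_run} from [run_spec()].
#' @param basename output basename; defaults to the spec's
#'   \code{OutputBasename}.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(run, basename = run$spec$out_basename) {
  problem <- run$problem
  cands <- problem$candidates
  files <- character(0)
  out <- function(suffix) {
    f <- paste0(basename, "_", suffix, ".txt")
    files <<- c(files, f)
    f
  }

  # (i) input data summary
  su <- c("ocsmate run summary",
          paste0("Mode: ", run$mode),
          paste0("Candidates: ", cands$n,
                 if (any(cands$gender != 0L))
                   sprintf(" (%d male, %d female)", sum(cands$gender == 1L),
                           sum(cands$gender == 2L)) else " (generic)"),
          paste0("Matings: ", problem$constraints$n_matings),
          if (!is.null(cands$criterion))
            sprintf("Criterion: mean %.6f sd %.6f", mean(cands$criterion),
                    stats::sd(cands$criterion)),
          sprintf("Coancestry: mean %.6f diagonal mean %.6f", mean(problem$K),
                  mean(diag(problem$K))),
          "", "Specification file:", run$spec$verbatim)
  writeLines(su, out("Summary"))

  # (ii) contributors
  plan <- run$plan
  raw_crit <- if (!is.null(cands$criterion)) cands$criterion else
    rep(NA_real_, cands$n)
  sel <- which(plan$n_contrib > 0)
  sel <- sel[order(-plan$n_contrib[sel], sel)]
  writeLines(c("Id Gender Criterion nContributions xContribution Edited",
               sprintf("%s %d %s %d %.6f %s", cands$ids[sel],
                       cands$gender[sel],
                       ifelse(is.na(raw_crit[sel]), "NA",
                              sprintf("%.6f", raw_crit[sel])),
                       plan$n_contrib[sel], plan$x[sel],
                       ifelse(cands$ids[sel] %in% plan$edited, "Yes", "No"))),
             out("Contributors"))

  # (iii) mating plan
  writeLines(plan_lines(plan, problem$K), out("MatingPlan"))

  # (iv) optimization log
  log <- run$log
  comp <- function(nm) if (nm %in% names(log)) log[[nm]] else
    rep(NA_real_, nrow(log))
  writeLines(c("Iteration BestObjective MeanObjective Gain Coancestry Inbreeding Penalty",
               sprintf("%d %.8f %.8f %s %s %s %s", log$generation, log$best,
                       log$mean, fmt_na(comp("gain")), fmt_na(comp("coancestry")),
                       fmt_na(comp("inbreeding")), fmt_na(comp("penalty")))),
             out("OptimisationLog"))

  # (v) seed
  writeLines(as.character(run$seed), out("Seed"))

  if (!is.null(run$frontier)) {
    fr <- as.data.frame(run$frontier)
    writeLines(c("Degrees Gain Coancestry GainNorm CoancestryNorm Inbreeding",
                 sprintf("%.2f %.6f %.6f %.6f %.6f %.6f", fr$Degrees, fr$Gain,
                         fr$Coancestry, fr$GainNorm, fr$CoancestryNorm,
                         fr$Inbreeding)),
               out("Frontier"))
    for (pt in run$frontier) {
      f <- paste0(basename, "_MatingPlan_", format(round(pt$degrees)), ".txt")
      files <- c(files, f)
      writeLines(plan_lines(pt$plan, problem$K), f)
    }
  }
  invisible(files)
}

plan_lines <- function(plan, K) {
  M <- nrow(plan$matings)
  inb <- K[cbind(plan$matings_idx[, 1L], plan$matings_idx[, 2L])]
  c("Mating Parent1 Parent2 ExpectedInbreeding",
    sprintf("%d %s %s %.6f", seq_len(M), plan$matings[, 1L],
            plan$matings[, 2L], inb))
}

fmt_na <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
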
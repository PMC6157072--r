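# end-to-end runs from a specification file and the output file contract

make_run_inputs <- function(dir, mode_lines, n = 6L, seed_line = "Seed 123") {
  pop <- simulate_pedigree_population(
    synthetic_config(n_founders = 3L, n_generations = 2L,
                     n_per_generation = 3L, seed = 42L))
  ped <- pop$pedigree
  ids <- tail(ped$id, n)
  K <- coancestry_from_pedigree(ped)[ids, ids]
  cand_file <- file.path(dir, "cand.txt")
  writeLines(paste(ids, 0L, sprintf("%.6f", tail(pop$bv, n))), cand_file)
  mat_file <- file.path(dir, "K.txt")
  write_coancestry_matrix(K, mat_file)
  spec <- file.path(dir, "run.spec")
  writeLines(c("CandidateFile cand.txt",
               "CoancestryMatrixFile K.txt",
               "NumberOfMatings 3",
               "MaxContributions 2",
               "AllowSelfing No",
               "EvolPopSize 25",
               "EvolIterations 120",
               "ConvergenceWindow 40",
               seed_line,
               paste0("OutputBasename ", file.path(dir, "out")),
               mode_lines), spec)
  spec
}

test_that("a max-gain run writes the five output files", {
  dir <- tempfile()
  dir.create(dir)
  spec <- make_run_inputs(dir, "Mode MaxGain")
  run <- run_spec(spec, verbosity = 0L)
  base <- file.path(dir, "out")
  for (suffix in c("Summary", "Contributors", "MatingPlan", "OptimisationLog",
                   "Seed")) {
    expect_true(file.exists(paste0(base, "_", suffix, ".txt")), label = suffix)
  }
  expect_equal(readLines(paste0(base, "_Seed.txt")), "123")
  # contributor counts re-derivable from the mating plan
  mp <- read.table(paste0(base, "_MatingPlan.txt"), header = TRUE)
  cb <- read.table(paste0(base, "_Contributors.txt"), header = TRUE)
  counts <- table(c(mp$Parent1, mp$Parent2))
  expect_equal(unname(cb$nContributions[order(cb$Id)]),
               as.integer(counts[order(names(counts))]))
  expect_equal(sum(cb$nContributions), 6L)
  # the log's best objective never worsens
  ol <- read.table(paste0(base, "_OptimisationLog.txt"), header = TRUE)
  expect_true(all(diff(ol$BestObjective) >= 0))
})

test_that("contributors are listed with their mating counts", {
  cands <- candidate_set(c("A", "B", "C"), criterion = c(3, 1, 2))
  K <- diag(0.5, 3L)
  dimnames(K) <- list(cands$ids, cands$ids)
  prob <- ocs_problem(cands, K,
                      mating_constraints(2L, max_contrib = 2L,
                                         allow_selfing = FALSE),
                      mode = "max_gain")
  # contribution genes (2, 1, 1) and identity mate keys give slots A A B C,
  # selfing repair then yields (A, C), (B, A): A twice, B and C once
  plan <- decode_chromosome(c(2, 1, 1, 0.1, 0.2, 0.3, 0.4), prob)
  expect_equal(unname(plan$n_contrib), c(2L, 1L, 1L))
  expect_equal(sort(plan$matings[plan$matings != "A"]), c("B", "C"))
  dir <- tempfile()
  dir.create(dir)
  run <- structure(list(spec = list(out_basename = file.path(dir, "w"),
                                    verbatim = "synthetic"),
                        problem = prob, mode = "max_gain", seed = 7L,
                        plan = plan,
                        log = data.frame(generation = 0L, best = 0, mean = 0)),
                   class = "ocs_run")
  write_results(run)
  cb <- read.table(file.path(dir, "w_Contributors.txt"), header = TRUE)
  expect_equal(cb$nContributions[cb$Id == "A"], 2L)
  expect_equal(cb$nContributions[cb$Id == "B"], 1L)
  expect_equal(cb$nContributions[cb$Id == "C"], 1L)
  expect_equal(cb$xContribution, cb$nContributions / 4, tolerance = 1e-6)
})

test_that("frontier mode writes the frontier table and per-angle plans", {
  dir <- tempfile()
  dir.create(dir)
  spec <- make_run_inputs(dir, c("Mode Frontier", "FrontierSteps 3"))
  run <- run_spec(spec, verbosity = 0L)
  fr <- read.table(file.path(dir, "out_Frontier.txt"), header = TRUE)
  expect_equal(nrow(fr), 3L)
  expect_equal(fr$Degrees, c(0, 45, 90))
  expect_true(file.exists(file.path(dir, "out_MatingPlan_45.txt")))
  # gain at 0 degrees bounds the sweep from above
  expect_gte(fr$Gain[1L] + 1e-9, max(fr$Gain))
})

test_that("target mode honours the resolved coancestry bound", {
  dir <- tempfile()
  dir.create(dir)
  spec <- make_run_inputs(dir, c("Mode Target", "TargetDegrees 90"))
  run <- run_spec(spec, verbosity = 0L)
  b <- run$bounds
  span <- b$C_at_Gmax - b$C_min
  expect_lte(run$point$coancestry, b$C_min + 1e-6 * max(span, 1e-12))
})
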
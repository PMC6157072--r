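# synthetic populations, genic variance bookkeeping and the enumeration oracle

test_that("marker population matches its additive model", {
  cfg <- synthetic_config(n_individuals = 10000L, n_loci = 5L, edit_q = 2L,
                          seed = 99L)
  pop <- simulate_marker_population(cfg)
  expect_equal(pop$candidates$criterion,
               unname(drop(pop$genotypes %*% pop$effects)))
  # scaled effects give unit base genic variance, so SE(mean) = 1/sqrt(n)
  expect_equal(genic_sd(pop$freqs, pop$effects), 1, tolerance = 1e-12)
  expect_equal(mean(pop$candidates$criterion),
               sum(2 * pop$freqs * pop$effects), tolerance = 4 / sqrt(10000))
})

test_that("edited criterion adds the top achievable locus improvements", {
  cfg <- synthetic_config(n_individuals = 20L, n_loci = 8L, edit_q = 3L,
                          seed = 12L)
  pop <- simulate_marker_population(cfg)
  G <- pop$genotypes
  a <- pop$effects
  for (i in seq_len(nrow(G))) {
    dist <- ifelse(a > 0, 2 - G[i, ], G[i, ])
    bonus <- sum(sort(abs(a) * dist, decreasing = TRUE)[1:3])
    expect_equal(pop$candidates$criterion_edited[i],
                 pop$candidates$criterion[i] + bonus)
  }
  # a candidate already at the favourable homozygote everywhere gains nothing
  Gfix <- matrix(ifelse(a > 0, 2, 0), 1L, 8L, byrow = TRUE)
  dist <- ifelse(a > 0, 2 - Gfix[1L, ], Gfix[1L, ])
  expect_equal(sum(sort(abs(a) * dist, decreasing = TRUE)[1:3]), 0)
})

test_that("genic standard deviation follows the closed form", {
  expect_equal(genic_sd(0.5, 1), sqrt(0.5))
  expect_equal(genic_sd(c(0, 1), c(3, -2)), 0)
  expect_equal(genic_sd(c(0.5, 0.5), c(1, 1)), 1)
})

test_that("pedigree simulation starts from unrelated founders", {
  cfg <- synthetic_config(n_founders = 5L, n_generations = 0L, seed = 3L)
  pop <- simulate_pedigree_population(cfg)
  K <- coancestry_from_pedigree(pop$pedigree)
  expect_equal(unname(K), diag(0.5, 5L))
  # offspring rows only ever reference earlier ids
  cfg <- synthetic_config(n_founders = 4L, n_generations = 3L,
                          n_per_generation = 5L, seed = 8L)
  ped <- simulate_pedigree_population(cfg)$pedigree
  for (i in seq_len(nrow(ped))) {
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (p != "0") expect_lt(match(p, ped$id), i)
    }
  }
})

test_that("founder breeding values are standard normal", {
  cfg <- synthetic_config(n_founders = 5000L, n_generations = 0L, seed = 21L)
  pop <- simulate_pedigree_population(cfg)
  expect_equal(stats::var(pop$bv), 1, tolerance = 0.06)
  expect_equal(mean(pop$bv), 0, tolerance = 0.05)
})

test_that("brute force enumerates the closed-form plan counts", {
  # 2 males x 2 females, one mating: four plans
  cands <- candidate_set(c("M1", "M2", "F1", "F2"), gender = c(1, 1, 2, 2),
                         criterion = c(1, 2, 3, 4))
  K <- diag(0.5, 4L)
  dimnames(K) <- list(cands$ids, cands$ids)
  prob <- ocs_problem(cands, K, mating_constraints(1L, gendered = TRUE),
                      mode = "max_gain")
  bf <- brute_force_optimum(prob, enumerate_plans = TRUE)
  expect_equal(bf$n_plans, 4L)

  # generic, 3 candidates, one mating, no selfing: three plans
  cands <- candidate_set(c("A", "B", "C"), criterion = c(1, 2, 3))
  K <- diag(0.5, 3L)
  dimnames(K) <- list(cands$ids, cands$ids)
  prob <- ocs_problem(cands, K,
                      mating_constraints(1L, allow_selfing = FALSE),
                      mode = "max_gain")
  bf <- brute_force_optimum(prob, enumerate_plans = TRUE)
  expect_equal(bf$n_plans, 3L)

  # min-coancestry over four unrelated parents: optimum 0.5/4 at x = 1/4
  prob <- unrelated_problem(4L, 2L, max_contrib = 1, allow_selfing = FALSE)
  bf <- brute_force_optimum(prob)
  expect_equal(bf$scalar, -0.125)
})

test_that("instances too large for brute force are refused", {
  prob <- unrelated_problem(8L, 2L, max_contrib = 2)
  expect_error(brute_force_optimum(prob), "too large")
})

test_that("gamete sampling conserves allele frequencies in expectation", {
  set.seed(17)
  diffs <- replicate(50L, {
    p <- runif(30L, 0.2, 0.8)
    g1 <- rbinom(30L, 2L, p)
    g2 <- rbinom(30L, 2L, p)
    prog <- mendelian_progeny(g1, g2, 40L)
    mean(colMeans(prog) / 2 - (g1 + g2) / 4)
  })
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-12)
})

test_that("a zero-cycle trajectory reports only the base cohort", {
  cfg <- synthetic_config(n_individuals = 20L, n_loci = 40L, seed = 5L)
  tr <- toy_recurrent_selection(cfg, "truncation-1", cycles = 0L,
                                n_crosses = 4L, progeny_per_cross = 5L)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$cycle, 0L)
  expect_gt(tr$genic_sd, 0)
})

test_that("short trajectories advance the cohort and its bookkeeping", {
  cfg <- synthetic_config(n_individuals = 20L, n_loci = 60L, seed = 6L)
  tr <- toy_recurrent_selection(cfg, "truncation-1", cycles = 2L,
                                n_crosses = 4L, progeny_per_cross = 5L)
  expect_equal(nrow(tr), 3L)
  expect_equal(attr(tr, "scheme"), "truncation-1")
  expect_true(all(is.finite(tr$mean)))
  # selection on true merit should raise the mean at these sizes
  expect_gt(tr$mean[3L], tr$mean[1L])
})
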
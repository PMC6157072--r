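# objective components, target resolution and the penalized scalar

test_that("criterion standardization is exact and idempotent", {
  z <- standardize_criterion(c(1, 2, 3))
  expect_equal(z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(z^2)), 1)
  expect_equal(standardize_criterion(z), z)
  expect_error(standardize_criterion(c(5, 5)), "zero variance")
})

test_that("genetic gain is the contribution-weighted mean criterion", {
  a <- standardize_criterion(c(3, 2, 1))
  expect_equal(genetic_gain(c(1, 0, 0), a), a[1L])
  expect_equal(genetic_gain(rep(1 / 3, 3L), a), 0)
  expect_equal(genetic_gain(c(0.5, 0.5, 0), a), 0.6124, tolerance = 1e-4)
})

test_that("group coancestry follows the quadratic form", {
  expect_equal(group_coancestry(c(0.5, 0.5), diag(0.5, 2L)), 0.25)
  n <- 10L
  expect_equal(group_coancestry(rep(1 / n, n), diag(0.5, n)), 0.05)
  expect_equal(group_coancestry(c(1, 0), diag(0.5, 2L)), 0.5)
  # uniform contributions give the mean of all matrix entries
  set.seed(1)
  V <- matrix(runif(16L), 4L)
  C <- (V + t(V)) / 2
  expect_equal(group_coancestry(rep(0.25, 4L), C), mean(C))
})

test_that("mean progeny inbreeding averages parental coancestries", {
  C <- matrix(c(0.5, 0, 0.25, 0, 0.5, 0, 0.25, 0, 0.5), 3L,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(mean_progeny_inbreeding(rbind(c("A", "B")), C), 0)
  expect_equal(mean_progeny_inbreeding(rbind(c("A", "C")), C), 0.25)
  expect_equal(mean_progeny_inbreeding(rbind(c("A", "B"), c("A", "C")), C),
               0.125)
})

test_that("mate permutation moves inbreeding but not group coancestry", {
  C <- matrix(c(0.5, 0.1, 0.3,
                0.1, 0.5, 0.05,
                0.3, 0.05, 0.5), 3L,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  x <- c(A = 0.5, B = 0.25, C = 0.25)
  m1 <- rbind(c("A", "B"), c("A", "C"))
  m2 <- rbind(c("A", "A"), c("B", "C"))
  expect_equal(group_coancestry(x, C), group_coancestry(x[c(1, 2, 3)], C))
  expect_false(isTRUE(all.equal(mean_progeny_inbreeding(m1, C),
                                mean_progeny_inbreeding(m2, C))))
})

test_that("target forms resolve to coancestry bounds", {
  bounds <- list(C_min = 0.05, C_at_Gmax = 0.25)
  expect_equal(resolve_coancestry_target(target_spec("degrees", 90), bounds),
               0.05)
  expect_equal(resolve_coancestry_target(target_spec("degrees", 0), bounds),
               0.25)
  expect_equal(resolve_coancestry_target(target_spec("coancestry_rate", 0.01),
                                         bounds, C_current = 0.10), 0.109)
  expect_equal(resolve_coancestry_target(target_spec("percent_of_min", 50),
                                         bounds), 0.15)
  expect_warning(resolve_coancestry_target(target_spec("coancestry_value", 0.9),
                                           bounds), "clamped")
})

test_that("target resolution is monotone in degrees and percent", {
  bounds <- list(C_min = 0.05, C_at_Gmax = 0.25)
  degs <- seq(0, 90, by = 5)
  cs <- vapply(degs, function(d)
    resolve_coancestry_target(target_spec("degrees", d), bounds), 0)
  expect_true(all(diff(cs) <= 1e-12))
  ps <- seq(0, 100, by = 10)
  cp <- vapply(ps, function(p)
    resolve_coancestry_target(target_spec("percent_of_min", p), bounds), 0)
  expect_true(all(diff(cp) >= -1e-12))
})

test_that("penalized scalar matches mode orientation and penalty formula", {
  vals <- list(gain = 1, coancestry = 0.2, inbreeding = 0.1, violations = 0)
  expect_equal(penalized_objective(vals, "max_gain", n_matings = 4L)$scalar, 1)
  expect_equal(penalized_objective(vals, "min_coancestry", n_matings = 4L)$scalar,
               -0.2)
  expect_equal(penalized_objective(vals, "min_inbreeding", n_matings = 4L)$scalar,
               -0.1)
  # coancestry exactly at the bound incurs no target penalty
  expect_equal(penalized_objective(vals, "target", n_matings = 4L, Cstar = 0.2,
                                   span = 0.2)$scalar, 1)
  # one residual selfing breach, M = 4, w = 1000 -> 250 subtracted
  vals$violations <- 1
  expect_equal(penalized_objective(vals, "max_gain", n_matings = 4L,
                                   penalty_weight = 1000)$scalar, 1 - 250)
})

test_that("improving one raw objective never lowers the matching scalar", {
  base <- list(gain = 0.5, coancestry = 0.2, inbreeding = 0.1, violations = 0)
  for (mode in c("max_gain", "min_coancestry", "min_inbreeding")) {
    better <- base
    field <- switch(mode, max_gain = "gain", min_coancestry = "coancestry",
                    min_inbreeding = "inbreeding")
    better[[field]] <- base[[field]] + if (mode == "max_gain") 0.1 else -0.05
    expect_gte(penalized_objective(better, mode, n_matings = 4L)$scalar,
               penalized_objective(base, mode, n_matings = 4L)$scalar)
  }
})
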
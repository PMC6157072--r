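# bound finding, epsilon-constraint solves and Pareto-frontier sweeps

fake_point <- function(gain, coa, deg = NA_real_) {
  structure(list(degrees = deg, gain = gain, coancestry = coa),
            class = "FrontierPoint")
}

sib_problem <- function(mode = "max_gain", ...) {
  ids <- c("S1", "S2", "U1", "U2")
  K <- diag(0.5, 4L)
  K[1L, 2L] <- K[2L, 1L] <- 0.25
  dimnames(K) <- list(ids, ids)
  cands <- candidate_set(ids, criterion = c(2, 1.8, 0.5, 0))
  ocs_problem(cands, K, mating_constraints(2L, max_contrib = 2L,
                                           allow_selfing = FALSE),
              mode = mode, ...)
}

de_small <- de_config(pop_size = 30L, iterations = 250L, window = 60L,
                      tol = 1e-12, seed = 11L)

test_that("degenerate instances give identical bounds", {
  # 4 unrelated candidates, one contribution each: every plan has x = 1/4
  prob <- unrelated_problem(4L, 2L, mode = "max_gain", max_contrib = 1,
                            allow_selfing = FALSE)
  b <- find_bounds(prob, de_small)
  expect_equal(b$C_min, 0.125, tolerance = 1e-9)
  expect_equal(b$C_at_Gmax, 0.125, tolerance = 1e-9)
})

test_that("min-coancestry spreads contributions off the sib pair", {
  prob <- sib_problem("min_coancestry")
  bf <- brute_force_optimum(prob)
  # sibs-only plan: x = (1/2, 1/2, 0, 0)
  sib_coa <- group_coancestry(c(0.5, 0.5, 0, 0), prob$K)
  expect_lt(-bf$scalar, sib_coa)
  obj <- make_objective(prob)
  res <- evolve(obj$fn, chromosome_length(prob), de_small)
  expect_equal(res$value, bf$scalar, tolerance = 1e-9)
})

test_that("frontier endpoints recover the single-objective bounds", {
  prob <- sib_problem("target", target = target_spec("degrees", 45))
  b <- find_bounds(prob, de_small)
  span <- b$C_at_Gmax - b$C_min
  expect_gt(span, 0)
  p0 <- solve_target(prob, target_spec("degrees", 0), de_small, b)
  p90 <- solve_target(prob, target_spec("degrees", 90), de_small, b)
  expect_equal(p0$gain, b$G_max, tolerance = 1e-6 * max(1, abs(b$G_max)))
  expect_lte(p90$coancestry, b$C_min + 1e-6 * span)
})

test_that("a 45-degree solve matches the constrained brute-force optimum", {
  prob <- sib_problem("target", target = target_spec("degrees", 45))
  bfg <- brute_force_optimum(prob, mode = "max_gain")
  bfd <- brute_force_optimum(prob, mode = "min_coancestry")
  bounds <- list(C_min = bfd$objectives$coancestry,
                 C_at_Gmax = bfg$objectives$coancestry)
  span <- bounds$C_at_Gmax - bounds$C_min
  Cstar <- resolve_coancestry_target(target_spec("degrees", 45), bounds)
  bf <- brute_force_optimum(prob, mode = "target", Cstar = Cstar, span = span)
  obj <- make_objective(prob, "target", Cstar, span)
  res <- evolve(obj$fn, chromosome_length(prob), de_small)
  expect_equal(res$value, bf$scalar, tolerance = 1e-9)
  plan <- decode_chromosome(res$best, prob, "target", Cstar, span)
  expect_lte(plan$objectives$coancestry, Cstar + 1e-6 * span)
})

test_that("a two-step sweep returns exactly the bound solutions", {
  prob <- sib_problem("target", target = target_spec("degrees", 45))
  b <- find_bounds(prob, de_small)
  fr <- sweep_frontier(prob, steps = 2L, config = de_small, bounds = b)
  expect_length(fr, 2L)
  expect_equal(fr[[1L]]$gain, b$G_max)
  expect_equal(fr[[2L]]$coancestry, b$C_min)
})

test_that("the filtered frontier is monotone", {
  prob <- sib_problem("target", target = target_spec("degrees", 45))
  fr <- sweep_frontier(prob, steps = 5L, config = de_small)
  flt <- pareto_filter(fr)
  df <- as.data.frame(flt)
  ord <- order(df$Coancestry)
  expect_true(all(diff(df$Gain[ord]) >= -1e-9))
  # achieved coancestry is non-increasing in the target angle
  expect_true(all(diff(df$Coancestry[order(df$Degrees)]) <= 1e-9))
})

test_that("pareto filtering removes dominated and duplicate points", {
  pts <- list(fake_point(1, 0.2, 0), fake_point(0.9, 0.25, 45))
  expect_length(pareto_filter(pts), 1L)
  expect_length(pareto_filter(pts[1L]), 1L)
  dup <- list(fake_point(1, 0.2, 0), fake_point(1, 0.2, 45))
  kept <- pareto_filter(dup)
  expect_length(kept, 1L)
  expect_equal(kept[[1L]]$degrees, 0)
  # incomparable points are both kept
  pts <- list(fake_point(1, 0.2, 0), fake_point(0.5, 0.1, 45))
  expect_length(pareto_filter(pts), 2L)
})
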
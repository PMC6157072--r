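# chromosome -> mating-plan decoding: integerization, mate allocation,
# selfing repair and the compiled end-to-end decoder

test_that("largest-remainder integerization follows rank and limits", {
  cons <- mating_constraints(3L, max_contrib = 4L, max_parents = 3L,
                             gendered = TRUE)
  n <- integerize_contributions(c(3, 2, 1), cons, "male")
  expect_equal(as.integer(n), c(2L, 1L, 0L))
  # the result is a feasible vector: enumerate all integer splits of 3
  splits <- expand.grid(0:3, 0:3, 0:3)
  splits <- splits[rowSums(splits) == 3L, ]
  expect_true(any(apply(splits, 1L, function(v) all(v == c(2, 1, 0)))))

  cons <- mating_constraints(3L, min_contrib = 1L, max_contrib = 1L,
                             gendered = TRUE)
  n <- integerize_contributions(c(0.9, 0.5, 0.4, 0.1), cons, "female")
  expect_equal(as.integer(n), c(1L, 1L, 1L, 0L))

  cons <- mating_constraints(2L, max_contrib = 2L, max_parents = 2L,
                             gendered = TRUE)
  n <- integerize_contributions(c(-1, -1, -1, -1), cons, "male")
  expect_equal(as.integer(n), c(1L, 1L, 0L, 0L))
  expect_equal(attr(n, "violations"), 0)
})

test_that("mate allocation permutes female slots by the key argsort", {
  m <- allocate_mates(c(2L, 0L), c(1L, 1L), c(0.1, 0.9))
  expect_equal(unname(m), cbind(c(1L, 1L), c(1L, 2L)))
  m <- allocate_mates(c(2L, 0L), c(1L, 1L), c(0.9, 0.1))
  expect_equal(unname(m), cbind(c(1L, 1L), c(2L, 1L)))
  # generic mode with a single forced mating
  m <- allocate_mates(c(1L, 1L), NULL, c(0.3, 0.8))
  expect_equal(sort(as.integer(m)), c(1L, 2L))
})

test_that("selfing repair swaps mates and counts irreparable selfings", {
  m <- rbind(c("A", "A"), c("B", "C"))
  r <- repair_selfing(m, allow_selfing = FALSE)
  expect_equal(unname(r[1L, ]), c("A", "C"))
  expect_equal(unname(r[2L, ]), c("B", "A"))
  expect_equal(attr(r, "violations"), 0)

  r <- repair_selfing(rbind(c("A", "A")), allow_selfing = FALSE)
  expect_equal(attr(r, "violations"), 1)

  m <- rbind(c("A", "A"), c("B", "C"))
  r <- repair_selfing(m, allow_selfing = TRUE)
  expect_equal(unname(r[1L, ]), c("A", "A"))
  expect_equal(attr(r, "violations"), 0)
})

test_that("the decoder reproduces the worked gendered micro-case", {
  cands <- candidate_set(c("M1", "M2", "F1", "F2"), gender = c(1, 1, 2, 2),
                         criterion = c(1, 0, 0, 1))
  K <- diag(0.5, 4L)
  dimnames(K) <- list(cands$ids, cands$ids)
  prob <- ocs_problem(cands, K,
                      mating_constraints(2L, max_contrib = 2L, gendered = TRUE),
                      mode = "max_gain")
  plan <- decode_chromosome(c(1.0, 0.2, 0.3, 0.7, 0.6, 0.4), prob)
  expect_equal(unname(plan$n_contrib), c(2L, 0L, 1L, 1L))
  expect_equal(unname(plan$matings), rbind(c("M1", "F2"), c("M1", "F1")))
  expect_equal(plan$violations, 0)
})

test_that("decoding is invariant to positive rescaling of contribution genes", {
  inst <- random_tiny_instance(12, gendered = FALSE)
  prob <- ocs_problem(inst$candidates, inst$K, inst$constraints,
                      mode = "min_coancestry")
  set.seed(9)
  for (rep in 1:20) {
    z <- rnorm(chromosome_length(prob))
    p1 <- decode_chromosome(z, prob)
    z2 <- z
    n <- prob$candidates$n
    z2[seq_len(n)] <- 3.7 * z2[seq_len(n)]   # positive scaling of contrib block
    p2 <- decode_chromosome(z2, prob)
    expect_identical(p1$n_contrib, p2$n_contrib)
    expect_identical(p1$matings, p2$matings)
  }
})

test_that("compiled decoder agrees with the composed R-level operations", {
  set.seed(31)
  for (s in c(3, 8, 21)) {
    for (gendered in c(TRUE, FALSE)) {
      inst <- random_tiny_instance(s, gendered = gendered)
      prob <- ocs_problem(inst$candidates, inst$K, inst$constraints,
                          mode = "min_coancestry")
      for (rep in 1:40) {
        z <- rnorm(chromosome_length(prob))
        a <- decode_chromosome(z, prob)
        b <- r_decode(z, prob)
        expect_equal(as.integer(unname(a$n_contrib)), b$n_contrib)
        expect_equal(unname(a$matings), unname(b$matings))
        expect_equal(a$violations, b$violations)
      }
    }
  }
})

test_that("every chromosome decodes to a plan with exact contribution sums", {
  for (s in c(2, 14)) {
    for (gendered in c(TRUE, FALSE)) {
      inst <- random_tiny_instance(s, gendered = gendered)
      prob <- ocs_problem(inst$candidates, inst$K, inst$constraints,
                          mode = "min_coancestry")
      M <- inst$constraints$n_matings
      set.seed(100 + s)
      for (rep in 1:250) {
        z <- rnorm(chromosome_length(prob), sd = 5)
        plan <- decode_chromosome(z, prob)
        expect_equal(sum(plan$n_contrib), 2L * M)
        ok <- check_plan(plan, inst$constraints, inst$candidates)
        expect_equal(plan$violations == 0, ok)
      }
    }
  }
})

test_that("decoded plans lie inside the brute-force plan enumeration", {
  for (s in c(4, 9)) {
    inst <- random_tiny_instance(s)
    M <- min(inst$constraints$n_matings, 3L)
    cons <- inst$constraints
    cons$n_matings <- M
    cands <- inst$candidates
    if (length(validate_constraints(cons, cands))) next
    prob <- ocs_problem(cands, inst$K, cons, mode = "min_coancestry")
    bf <- brute_force_optimum(prob, enumerate_plans = TRUE)
    set.seed(200 + s)
    for (rep in 1:500) {
      z <- rnorm(chromosome_length(prob))
      plan <- decode_chromosome(z, prob)
      if (plan$violations > 0) next
      key <- ocsmate:::canonical_plan(plan$matings_idx, cons$gendered)
      expect_true(key %in% bf$plans)
    }
  }
})

test_that("infeasible constraint sets are reported, feasible ones pass", {
  # gendered pool: 8 males can carry 16 matings at up to 4 contributions
  cands <- candidate_set(sprintf("C%02d", 1:16),
                         gender = rep(c(1L, 2L), each = 8L))
  cons <- mating_constraints(16L, max_contrib = 4L, max_parents = 8L,
                             gendered = TRUE)
  expect_length(validate_constraints(cons, cands), 0L)

  # equal contributions must divide the role total
  cons <- mating_constraints(5L, min_contrib = 2L, max_contrib = 2L,
                             gendered = TRUE)
  expect_gt(length(validate_constraints(cons, cands)), 0L)

  # gendered mode with no females
  males <- candidate_set(c("A", "B"), gender = c(1L, 1L))
  cons <- mating_constraints(2L, gendered = TRUE)
  expect_true(any(grepl("female", validate_constraints(cons, males))))
})
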
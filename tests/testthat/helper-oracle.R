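# Independent oracles and checkers used across the test files. These
# deliberately share no code with the package's decoding/evaluation paths.

# naive recursive kinship (double recursion over parents)
naive_kinship <- function(pedigree) {
  id <- as.character(pedigree[[1L]])
  sire <- as.character(pedigree[[2L]])
  dam <- as.character(pedigree[[3L]])
  sire[sire %in% c("0", "")] <- NA
  dam[dam %in% c("0", "")] <- NA
  si <- match(sire, id)
  di <- match(dam, id)
  n <- length(id)
  memo <- new.env()
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      0.5 * (1 + f(si[i], di[i]))   # F_i equals the parents' kinship
    } else {
      # recurse on the younger individual (larger index: rows are ordered
      # parents-first in all generated pedigrees)
      if (i < j) { tmp <- i; i <- j; j <- tmp }
      0.5 * (f(si[i], j) + f(di[i], j))
    }
    memo[[key]] <- val
    val
  }
  K <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) for (j in seq_len(i)) K[i, j] <- K[j, i] <- f(i, j)
  K
}

# random pedigree with parents-first ordering, unknown parents and selfing
random_pedigree <- function(n, seed) {
  set.seed(seed)
  id <- sprintf("P%02d", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in seq_len(n)) {
    if (i >= 3L && runif(1) < 0.8) {
      sire[i] <- id[sample.int(i - 1L, 1L)]
      dam[i] <- if (runif(1) < 0.1) sire[i] else id[sample.int(i - 1L, 1L)]
    }
  }
  data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
}

# independent mating-plan checker: TRUE iff every constraint is satisfied
check_plan <- function(plan, constraints, candidates) {
  M <- constraints$n_matings
  gendered <- constraints$gendered
  # recount contributions from the mating list itself
  counts <- table(factor(c(plan$matings[, 1L], plan$matings[, 2L]),
                         levels = candidates$ids))
  nc <- as.integer(counts)
  if (!identical(nc, as.integer(unname(plan$n_contrib)))) return(FALSE)
  roles <- if (gendered) {
    list(male = which(candidates$gender == 1L),
         female = which(candidates$gender == 2L))
  } else list(generic = seq_len(candidates$n))
  for (rn in names(roles)) {
    v <- nc[roles[[rn]]]
    Tt <- if (gendered) M else 2L * M
    if (sum(v) != Tt) return(FALSE)
    maxp <- switch(rn, male = constraints$max_parents_male,
                   female = constraints$max_parents_female,
                   generic = constraints$max_parents)
    if (sum(v > 0L) > maxp) return(FALSE)
    if (any(v > constraints$max_contrib)) return(FALSE)
    if (constraints$min_contrib > 0 && any(v[v > 0L] < constraints$min_contrib))
      return(FALSE)
  }
  if (gendered) {
    male_ids <- candidates$ids[candidates$gender == 1L]
    if (!all(plan$matings[, 1L] %in% male_ids)) return(FALSE)
    if (any(plan$matings[, 2L] %in% male_ids)) return(FALSE)
  } else if (!constraints$allow_selfing &&
             any(plan$matings[, 1L] == plan$matings[, 2L])) {
    return(FALSE)
  }
  TRUE
}

# decode via the R-level module operations (cross-check for the compiled path)
r_decode <- function(chrom, problem) {
  cn <- problem$constraints
  M <- cn$n_matings
  cands <- problem$candidates
  if (cn$gendered) {
    mi <- which(cands$gender == 1L)
    fi <- which(cands$gender == 2L)
    gm <- chrom[seq_along(mi)]
    gf <- chrom[length(mi) + seq_along(fi)]
    nm <- integerize_contributions(gm, cn, "male")
    nf <- integerize_contributions(gf, cn, "female")
    mate <- chrom[length(mi) + length(fi) + seq_len(M)]
    m <- allocate_mates(nm, nf, mate)
    viol <- attr(nm, "violations") + attr(nf, "violations")
    nc <- integer(cands$n)
    nc[mi] <- nm
    nc[fi] <- nf
    matings <- cbind(cands$ids[mi[m[, 1L]]], cands$ids[fi[m[, 2L]]])
  } else {
    n <- cands$n
    ng <- integerize_contributions(chrom[seq_len(n)], cn, "generic")
    mate <- chrom[n + seq_len(2L * M)]
    m <- allocate_mates(ng, NULL, mate)
    m <- repair_selfing(m, cn$allow_selfing)
    viol <- attr(ng, "violations") + attr(m, "violations")
    nc <- as.integer(ng)
    matings <- cbind(cands$ids[m[, 1L]], cands$ids[m[, 2L]])
  }
  list(n_contrib = nc, matings = matings, violations = viol)
}

# small gendered marker instance with an elementwise-superior edited criterion
edit_instance <- function(seed, n = 8L, n_loci = 60L, M = 4L) {
  pop <- simulate_marker_population(synthetic_config(
    n_individuals = n, n_loci = n_loci, edit_q = 5L, seed = seed))
  cs <- pop$candidates
  cands <- candidate_set(cs$ids, gender = rep(c(1L, 2L), n / 2L),
                         criterion = cs$criterion,
                         criterion_edited = cs$criterion_edited)
  K <- coancestry_from_markers(pop$genotypes)
  cons <- mating_constraints(M, max_contrib = 2L, gendered = TRUE)
  list(candidates = cands, K = K, constraints = cons)
}

# DE solve of one tiny instance against the brute-force oracle; returns the
# absolute scalar difference
oracle_gap <- function(inst, mode, seed,
                       de = de_config(pop_size = 30, iterations = 250,
                                      window = 60, tol = 1e-12)) {
  de$seed <- seed
  if (mode != "target") {
    prob <- ocs_problem(inst$candidates, inst$K, inst$constraints, mode = mode)
    bf <- brute_force_optimum(prob)
    obj <- make_objective(prob)
    res <- evolve(obj$fn, chromosome_length(prob), de)
    return(abs(bf$scalar - res$value))
  }
  prob <- ocs_problem(inst$candidates, inst$K, inst$constraints,
                      mode = "target", target = target_spec("degrees", 45))
  bfg <- brute_force_optimum(prob, mode = "max_gain")
  bfd <- brute_force_optimum(prob, mode = "min_coancestry")
  bounds <- list(C_min = bfd$objectives$coancestry,
                 C_at_Gmax = bfg$objectives$coancestry)
  span <- bounds$C_at_Gmax - bounds$C_min
  if (span < 1e-12) return(0)
  Cstar <- resolve_coancestry_target(target_spec("degrees", 45), bounds)
  bf <- brute_force_optimum(prob, mode = "target", Cstar = Cstar, span = span)
  obj <- make_objective(prob, "target", Cstar, span)
  res <- evolve(obj$fn, chromosome_length(prob), de)
  abs(bf$scalar - res$value)
}

# unrelated non-inbred candidates with evenly spread criteria
unrelated_problem <- function(n, M, mode = "min_coancestry", ...) {
  ids <- sprintf("U%02d", seq_len(n))
  K <- diag(0.5, n)
  dimnames(K) <- list(ids, ids)
  cands <- candidate_set(ids, criterion = seq_len(n))
  ocs_problem(cands, K, mating_constraints(M, ...), mode = mode)
}
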
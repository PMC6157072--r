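#' Configuration for the synthetic population generators
#'
#' Describes the simulated populations used for testing and demonstration:
#' pedigree sizes for the pedigree simulator, marker-panel sizes and allele
#' frequency range for the marker simulator, and the editing rule (the
#' \code{edit_q} loci with the largest achievable merit improvement are set to
#' the favourable homozygote).
#'
#' @param n_founders,n_generations,n_per_generation pedigree simulation sizes.
#' @param n_individuals number of genotyped individuals (marker simulation).
#' @param n_loci number of unlinked biallelic loci L.
#' @param freq_range allele-frequency range, drawn uniformly per locus.
#' @param edit_q number of top causal loci editable per individual.
#' @param seed integer seed.
#' @return An object of class \code{SyntheticConfig}.
#' @export
synthetic_config <- function(n_founders = 4L, n_generations = 2L,
                             n_per_generation = 6L, n_individuals = 160L,
                             n_loci = 200L, freq_range = c(0.1, 0.9),
                             edit_q = 5L, seed = 1L) {
  stopifnot(n_founders >= 1L, n_generations >= 0L, n_per_generation >= 1L,
            n_individuals >= 1L, n_loci >= 1L,
            all(freq_range > 0), all(freq_range < 1))
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 n_per_generation = as.integer(n_per_generation),
                 n_individuals = as.integer(n_individuals),
                 n_loci = as.integer(n_loci),
                 freq_range = as.numeric(freq_range),
                 edit_q = as.integer(edit_q),
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Simulate a marker-genotyped population with additive merit
#'
#' Genotypes are independent per-locus binomial(2, p) draws with allele
#' frequencies uniform in the configured range; per-locus additive effects are
#' standard normal, scaled so the base-population genic variance is 1. The
#' criterion is the true additive merit \code{G alpha}; the edited criterion
#' is the merit after setting the \code{edit_q} loci with the largest
#' achievable improvement (effect size times distance from the favourable
#' homozygote) to the favourable homozygote for that individual.
#'
#' @param cfg a [synthetic_config()].
#' @return List with \code{candidates} (a [candidate_set()] with criterion and
#'   edited criterion), \code{genotypes}, \code{effects}, \code{freqs}.
#' @export
simulate_marker_population <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  L <- cfg$n_loci
  p <- stats::runif(L, cfg$freq_range[1L], cfg$freq_range[2L])
  G <- matrix(stats::rbinom(n * L, 2L, rep(p, each = n)), n, L)
  alpha <- stats::rnorm(L)
  gv <- sum(2 * p * (1 - p) * alpha^2)
  alpha <- alpha / sqrt(gv)
  crit <- drop(G %*% alpha)
  # achievable improvement per individual x locus:
  # |effect| times the dosage distance from the favourable homozygote
  dist <- matrix(0, n, L)
  pos <- alpha > 0
  dist[, pos] <- 2 - G[, pos]
  dist[, !pos] <- G[, !pos]
  improv <- sweep(dist, 2, abs(alpha), "*")
  q <- min(cfg$edit_q, L)
  bonus <- apply(improv, 1L, function(r) sum(sort(r, decreasing = TRUE)[seq_len(q)]))
  ids <- sprintf("I%03d", seq_len(n))
  rownames(G) <- ids
  cands <- candidate_set(ids, criterion = crit, criterion_edited = crit + bonus)
  list(candidates = cands, genotypes = G, effects = alpha, freqs = p)
}

#' Simulate a pedigreed population under the infinitesimal model
#'
#' Founders are unrelated and non-inbred with breeding values N(0, 1); each
#' later generation is produced from random parent pairs drawn from the
#' previous generation, with child breeding value
#' \code{mean(parents) + N(0, 0.5)} (Mendelian-sampling variance without
#' inbreeding adjustment).
#'
#' @param cfg a [synthetic_config()].
#' @return List with \code{candidates} (criterion = breeding value, whole
#'   pedigree), \code{pedigree} (data frame id/sire/dam, parents before
#'   offspring) and \code{bv}.
#' @export
simulate_pedigree_population <- function(cfg) {
  set.seed(cfg$seed)
  ids <- sprintf("F%02d", seq_len(cfg$n_founders))
  sire <- dam <- rep("0", cfg$n_founders)
  bv <- stats::rnorm(cfg$n_founders)
  prev <- ids
  prev_bv <- bv
  for (g in seq_len(cfg$n_generations)) {
    new_ids <- sprintf("G%dI%02d", g, seq_len(cfg$n_per_generation))
    s <- d <- character(cfg$n_per_generation)
    nb <- numeric(cfg$n_per_generation)
    for (i in seq_len(cfg$n_per_generation)) {
      pr <- if (length(prev) >= 2L) sample(prev, 2L) else rep(prev, 2L)
      s[i] <- pr[1L]
      d[i] <- pr[2L]
      pbv <- prev_bv[match(pr, prev)]
      nb[i] <- mean(pbv) + stats::rnorm(1L, 0, sqrt(0.5))
    }
    ids <- c(ids, new_ids)
    sire <- c(sire, s)
    dam <- c(dam, d)
    bv <- c(bv, nb)
    prev <- new_ids
    prev_bv <- nb
  }
  ped <- data.frame(id = ids, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  list(candidates = candidate_set(ids, criterion = bv), pedigree = ped, bv = bv)
}

#' Genic standard deviation of an additive trait
#'
#' \code{sqrt(sum(2 p (1 - p) alpha^2))}: the square root of the additive
#' variance under linkage equilibrium. Its decline over cycles tracks the
#' genetic diversity still usable for future gain.
#'
#' @param freqs allele frequencies.
#' @param effects per-locus additive effects.
#' @return Numeric scalar.
#' @export
genic_sd <- function(freqs, effects) {
  stopifnot(length(freqs) == length(effects))
  sqrt(sum(2 * freqs * (1 - freqs) * effects^2))
}

# ---------------------------------------------------------------------------
# brute-force global optimizer (test oracle for tiny instances)
# ---------------------------------------------------------------------------

# integer contribution vectors: sum Tt, each 0 or in [minc, maxc], <= maxp positive
enumerate_contributions <- function(ncand, Tt, minc, maxc, maxp) {
  out <- list()
  rec <- function(i, left, used, acc) {
    if (i > ncand) {
      if (left == 0L) out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    remaining <- ncand - i            # candidates after this one
    vals <- 0L
    if (used < maxp) {
      lo <- max(minc, 1L)
      hi <- min(maxc, left)
      if (hi >= lo) vals <- c(0L, seq.int(lo, hi))
    }
    for (v in vals) {
      nl <- left - v
      if (nl < 0L) next
      # prune: remaining slots cannot absorb nl
      cap <- (min(maxp, used + (v > 0L) + remaining) - used - (v > 0L)) * maxc
      if (nl > cap) next
      rec(i + 1L, nl, used + (v > 0L), c(acc, v))
    }
  }
  rec(1L, Tt, 0L, integer(0))
  out
}

# distinct perfect matchings of a generic slot multiset (counts per candidate)
enumerate_matchings_generic <- function(counts, allow_selfing) {
  out <- list()
  rec <- function(cnt, acc) {
    i <- which(cnt > 0L)[1L]
    if (is.na(i)) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    cnt[i] <- cnt[i] - 1L
    js <- setdiff(which(cnt > 0L), i)
    if (allow_selfing && cnt[i] > 0L) js <- c(i, js)
    for (j in js) {
      c2 <- cnt
      c2[j] <- c2[j] - 1L
      rec(c2, rbind(acc, c(min(i, j), max(i, j))))
    }
  }
  rec(as.integer(counts), NULL)
  dedupe_matchings(out)
}

enumerate_matchings_gendered <- function(cm, cf) {
  out <- list()
  rec <- function(m, f, acc) {
    i <- which(m > 0L)[1L]
    if (is.na(i)) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    m[i] <- m[i] - 1L
    for (j in which(f > 0L)) {
      f2 <- f
      f2[j] <- f2[j] - 1L
      rec(m, f2, rbind(acc, c(i, j)))
    }
  }
  rec(as.integer(cm), as.integer(cf), NULL)
  dedupe_matchings(out)
}

dedupe_matchings <- function(ms) {
  if (!length(ms)) return(ms)
  key <- vapply(ms, function(m) {
    m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
    paste(m[, 1L], m[, 2L], sep = "x", collapse = "|")
  }, "")
  ms[!duplicated(key)]
}

canonical_plan <- function(matings_idx, gendered) {
  m <- matings_idx
  if (!gendered) {
    m <- cbind(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
  }
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  paste(m[, 1L], m[, 2L], sep = "x", collapse = "|")
}

# best edit set reachable by the decoder for a given contribution vector:
# exactly min(budget, selected editable) edits, chosen to maximize the gain
best_edit_gain <- function(problem, nc, x) {
  base <- sum(x * problem$a_std)
  if (problem$edit_budget <= 0L) return(list(gain = base, edited = integer(0)))
  sel <- problem$editable[nc[problem$editable] > 0L]
  if (!length(sel)) return(list(gain = base, edited = integer(0)))
  k <- min(problem$edit_budget, length(sel))
  delta <- x[sel] * (problem$a_std_edit[sel] - problem$a_std[sel])
  ord <- sel[order(-delta, sel)]
  ed <- sort(ord[seq_len(k)])
  list(gain = base + sum(x[ed] * (problem$a_std_edit[ed] - problem$a_std[ed])),
       edited = ed)
}

#' Brute-force global optimum of a tiny mating problem
#'
#' Exhaustively enumerates every valid mating plan (all integer contribution
#' vectors satisfying the constraints and, where the objective or the selfing
#' rule depends on the pairing, all distinct mate pairings) and returns the
#' global optimum of the same penalized scalar the evolver maximizes. This is
#' the independent test oracle; it shares none of the decoder's machinery.
#'
#' @param problem an [ocs_problem()].
#' @param mode objective mode (defaults to the problem's).
#' @param Cstar,span resolved coancestry bound and span for target mode.
#' @param enumerate_plans also return the canonical form of every valid plan
#'   (used by the decoder-image test) and the plan count.
#' @param max_candidates,max_matings instance-size guard rails.
#' @return List with \code{scalar}, \code{objectives} at one optimum,
#'   \code{best} (canonical arg-optima), and with
#'   \code{enumerate_plans = TRUE} also \code{n_plans} and \code{plans}.
#' @export
brute_force_optimum <- function(problem, mode = problem$mode,
                                Cstar = NA_real_, span = NA_real_,
                                enumerate_plans = FALSE,
                                max_candidates = 6L, max_matings = 4L) {
  cn <- problem$constraints
  if (problem$candidates$n > max_candidates || cn$n_matings > max_matings)
    stop("instance too large for brute force")
  M <- cn$n_matings
  roles <- role_indices(problem)
  need_pairings <- mode == "min_inbreeding" ||
    (!cn$gendered && !cn$allow_selfing) || enumerate_plans

  role_vectors <- lapply(names(roles), function(rn) {
    lim <- role_limits(cn, length(roles[[rn]]), rn)
    enumerate_contributions(length(roles[[rn]]), lim$T, lim$min, lim$max,
                            lim$maxp)
  })

  combos <- if (cn$gendered)
    expand.grid(a = seq_along(role_vectors[[1L]]),
                b = seq_along(role_vectors[[2L]]))
  else data.frame(a = seq_along(role_vectors[[1L]]))

  best_scalar <- -Inf
  best_keys <- character(0)
  best_obj <- NULL
  n_plans <- 0L
  all_plans <- character(0)

  for (ci in seq_len(nrow(combos))) {
    nc <- integer(problem$candidates$n)
    v1 <- role_vectors[[1L]][[combos$a[ci]]]
    nc[roles[[1L]]] <- v1
    if (cn$gendered) {
      v2 <- role_vectors[[2L]][[combos$b[ci]]]
      nc[roles[[2L]]] <- v2
    }
    x <- nc / (2 * M)
    coa <- group_coancestry(x, problem$K)
    eg <- best_edit_gain(problem, nc, x)

    matchings <- NULL
    if (need_pairings) {
      matchings <- if (cn$gendered)
        enumerate_matchings_gendered(v1, v2)
      else enumerate_matchings_generic(nc, cn$allow_selfing)
      if (!length(matchings)) next   # no valid pairing (e.g. selfing forced)
    }

    scalars <- if (mode == "min_inbreeding") {
      vapply(matchings, function(m) {
        mglob <- if (cn$gendered)
          cbind(roles[[1L]][m[, 1L]], roles[[2L]][m[, 2L]])
        else m
        -mean(problem$K[mglob])
      }, 0)
    } else {
      base <- switch(mode,
                     max_gain = eg$gain,
                     min_coancestry = -coa,
                     target = eg$gain - problem$penalty_weight *
                       max(0, coa - Cstar) / span)
      rep(base, max(1L, length(matchings)))
    }

    if (enumerate_plans) {
      keys <- vapply(matchings, function(m) {
        mglob <- if (cn$gendered)
          cbind(roles[[1L]][m[, 1L]], roles[[2L]][m[, 2L]])
        else m
        canonical_plan(mglob, cn$gendered)
      }, "")
      n_plans <- n_plans + length(keys)
      all_plans <- c(all_plans, keys)
    }

    mbest <- max(scalars)
    if (mbest > best_scalar + 1e-12) {
      best_scalar <- mbest
      best_keys <- character(0)
      inb_best <- if (mode == "min_inbreeding") -mbest else NA_real_
      best_obj <- list(gain = eg$gain, coancestry = coa,
                       inbreeding = inb_best, edited = eg$edited,
                       n_contrib = nc)
    }
    if (mbest > best_scalar - 1e-12 && need_pairings) {
      hit <- which(scalars > best_scalar - 1e-12)
      best_keys <- unique(c(best_keys, vapply(matchings[hit], function(m) {
        mglob <- if (cn$gendered)
          cbind(roles[[1L]][m[, 1L]], roles[[2L]][m[, 2L]])
        else m
        canonical_plan(mglob, cn$gendered)
      }, "")))
    }
  }
  if (!is.finite(best_scalar)) stop("no valid plan exists for this instance")
  out <- list(scalar = best_scalar, objectives = best_obj, best = best_keys)
  if (enumerate_plans) {
    out$n_plans <- n_plans
    out$plans <- unique(all_plans)
  }
  out
}

#' Random tiny mating instance
#'
#' Draws a small, feasible instance for oracle-equivalence testing: 4--6
#' candidates with coancestry from a small simulated pedigree and breeding
#' values as criterion, a random gendered or generic structure, 2--4 matings
#' and random contribution limits including equal-contribution and no-selfing
#' cases.
#'
#' @param seed integer seed.
#' @param gendered force gendered (\code{TRUE}) or generic (\code{FALSE});
#'   random when \code{NULL}.
#' @return List with \code{candidates}, \code{K}, \code{constraints}.
#' @export
random_tiny_instance <- function(seed, gendered = NULL) {
  set.seed(seed)
  if (is.null(gendered)) gendered <- stats::runif(1L) < 0.5
  n <- sample(4:6, 1L)
  pop <- simulate_pedigree_population(
    synthetic_config(n_founders = 3L, n_generations = 2L,
                     n_per_generation = max(3L, ceiling(n / 2)),
                     seed = sample.int(1e6, 1L)))
  total <- nrow(pop$pedigree)
  take <- seq(total - n + 1L, total)
  Kfull <- coancestry_from_pedigree(pop$pedigree)
  ids <- pop$pedigree$id[take]
  K <- Kfull[ids, ids]
  gender <- NULL
  if (gendered) {
    gender <- rep(c(1L, 2L), length.out = n)
  }
  cands <- candidate_set(ids, gender = gender, criterion = pop$bv[take])

  n_role <- if (gendered) min(sum(gender == 1L), sum(gender == 2L)) else n
  for (attempt in seq_len(50L)) {
    M <- sample(2:4, 1L)
    Tt <- if (gendered) M else 2L * M
    allow_selfing <- gendered || stats::runif(1L) < 0.5
    if (stats::runif(1L) < 0.3) {
      divs <- which(Tt %% seq_len(Tt) == 0L)
      divs <- divs[Tt %/% divs <= n_role]
      cc <- sample(rep(divs, 2L), 1L)
      cons <- mating_constraints(M, min_contrib = cc, max_contrib = cc,
                                 allow_selfing = allow_selfing,
                                 gendered = gendered)
    } else {
      maxc <- sample(seq(ceiling(Tt / n_role), Tt), 1L)
      if (!gendered && !allow_selfing) maxc <- min(maxc, M)
      maxp <- sample(seq(ceiling(Tt / maxc), n_role), 1L)
      cons <- mating_constraints(M, max_parents = maxp, max_contrib = maxc,
                                 allow_selfing = allow_selfing,
                                 gendered = gendered)
    }
    if (!length(validate_constraints(cons, cands)))
      return(list(candidates = cands, K = K, constraints = cons))
  }
  stop("could not draw a feasible instance")   # nocov
}

# ---------------------------------------------------------------------------
# toy recurrent-selection demonstration
# ---------------------------------------------------------------------------

#' Mendelian progeny of two parents
#'
#' Samples progeny dosages locus by locus: each parent transmits one allele,
#' heterozygous loci transmitting the favourable allele with probability 0.5.
#' Loci are unlinked.
#'
#' @param g1,g2 parental dosage vectors (0/1/2).
#' @param n number of progeny.
#' @return \code{n x L} dosage matrix.
#' @export
mendelian_progeny <- function(g1, g2, n) {
  L <- length(g1)
  gam <- function(g) {
    het <- g == 1L
    base <- matrix(as.integer(g == 2L), n, L, byrow = TRUE)
    if (any(het))
      base[, het] <- matrix(stats::rbinom(n * sum(het), 1L, 0.5), n)
    base
  }
  gam(g1) + gam(g2)
}

#' Toy recurrent-selection demonstration
#'
#' Runs a miniature recurrent selection program on unlinked markers: each
#' cycle the current progeny cohort is genotyped, candidates are selected and
#' mated according to the scheme, and crosses produce the next cohort by
#' Mendelian sampling. Schemes: \code{"truncation-1"} (top 2M candidates by
#' merit, one cross each, random pairing), \code{"truncation-4"} (top M/2,
#' four crosses each) or \code{"degrees"} (contribution/mate-allocation
#' optimization with the given trade-off angle and at most
#' \code{max_contrib} crosses per parent).
#'
#' @param cfg a [synthetic_config()] (marker part is used).
#' @param scheme selection scheme.
#' @param degrees trade-off angle for \code{scheme = "degrees"}.
#' @param cycles number of selection cycles.
#' @param n_crosses number of crosses M per cycle.
#' @param progeny_per_cross progeny per cross.
#' @param max_contrib maximum crosses per parent in the degrees scheme.
#' @param config a [de_config()] for the optimization scheme.
#' @return Data frame of class \code{Trajectory} with columns \code{cycle},
#'   \code{mean} (cohort genetic mean) and \code{genic_sd}, rows for the base
#'   cohort and every cycle.
#' @export
toy_recurrent_selection <- function(cfg,
                                    scheme = c("degrees", "truncation-1",
                                               "truncation-4"),
                                    degrees = 35, cycles = 12L,
                                    n_crosses = 16L, progeny_per_cross = 10L,
                                    max_contrib = 4L,
                                    config = de_config(pop_size = 48L,
                                                       iterations = 150L,
                                                       window = 50L)) {
  scheme <- match.arg(scheme)
  pop <- simulate_marker_population(cfg)
  G <- pop$genotypes
  alpha <- pop$effects
  set.seed(cfg$seed + 7L)
  cohort_stats <- function(G) {
    p <- colMeans(G) / 2
    c(mean = mean(drop(G %*% alpha)), genic_sd = genic_sd(p, alpha))
  }
  stats_mat <- matrix(NA_real_, cycles + 1L, 2L,
                      dimnames = list(NULL, c("mean", "genic_sd")))
  stats_mat[1L, ] <- cohort_stats(G)
  M <- n_crosses

  random_pairing <- function(parent_idx, per_parent) {
    slots <- sample(rep(parent_idx, each = per_parent))
    m <- cbind(slots[seq(1L, 2L * M, 2L)], slots[seq(2L, 2L * M, 2L)])
    repair_selfing(m, allow_selfing = FALSE)
  }

  for (cyc in seq_len(cycles)) {
    bv <- drop(G %*% alpha)
    merit_sd <- stats::sd(bv)
    if (scheme == "truncation-1" ||
        (scheme == "degrees" && merit_sd < 1e-9)) {
      top <- order(-bv)[seq_len(2L * M)]
      matings <- random_pairing(top, 1L)
    } else if (scheme == "truncation-4") {
      top <- order(-bv)[seq_len(M / 2L)]
      matings <- random_pairing(top, 4L)
    } else {
      ids <- sprintf("C%03d", seq_len(nrow(G)))
      rownames(G) <- ids
      cands <- candidate_set(ids, criterion = bv)
      K <- coancestry_from_markers(G)
      cons <- mating_constraints(M, max_contrib = max_contrib,
                                 allow_selfing = FALSE)
      prob <- ocs_problem(cands, K, cons, mode = "target",
                          target = target_spec("degrees", degrees))
      cfg_de <- config
      if (is.null(cfg_de$seed)) cfg_de$seed <- cfg$seed
      cfg_de$seed <- cfg_de$seed + 131L * cyc
      pt <- solve_target(prob, target_spec("degrees", degrees), cfg_de)
      matings <- pt$plan$matings_idx
    }
    Gnew <- matrix(0L, M * progeny_per_cross, ncol(G))
    for (k in seq_len(M)) {
      rows <- (k - 1L) * progeny_per_cross + seq_len(progeny_per_cross)
      Gnew[rows, ] <- mendelian_progeny(G[matings[k, 1L], ],
                                        G[matings[k, 2L], ],
                                        progeny_per_cross)
    }
    G <- Gnew
    stats_mat[cyc + 1L, ] <- cohort_stats(G)
  }
  out <- data.frame(cycle = 0:cycles, mean = stats_mat[, 1L],
                    genic_sd = stats_mat[, 2L])
  attr(out, "scheme") <- if (scheme == "degrees")
    paste0("degrees-", degrees) else scheme
  class(out) <- c("Trajectory", class(out))
  out
}

#' Efficiency of converting genetic diversity into genetic gain
#'
#' Fits a linear regression of the cohort genetic mean on the cohort genic
#' standard deviation across cycles of one trajectory and returns the negated
#' slope: the gain obtained per unit of genic standard deviation lost.
#'
#' @param trajectory a \code{Trajectory} from [toy_recurrent_selection()].
#' @return Numeric scalar (higher = more efficient conversion).
#' @export
conversion_efficiency <- function(trajectory) {
  fit <- stats::lm(mean ~ genic_sd, data = trajectory)
  -unname(stats::coef(fit)[2L])
}
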
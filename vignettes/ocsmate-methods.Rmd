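---
title: "Methods: joint optimization of contributions and mate allocation"
author: "ocsmate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint optimization of contributions and mate allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocsmate)
```

## The problem

A breeding or conservation program must decide, every cycle, how strongly
each candidate contributes to the next generation and who is mated to whom.
Concentrating contributions on the best candidates maximizes short-term
genetic gain but erodes the genetic diversity that future gain is made from;
spreading contributions preserves diversity at the cost of immediate gain.
`ocsmate` formulates this as optimization of a *mating plan* — the full list
of M parent pairs — under user constraints, and solves it with a
differential-evolution (DE) engine.

For contribution proportions $x$ (summing to 1; each gender role summing to
0.5 in gendered mode), a standardized selection criterion $a$ and a
coancestry matrix $C$, the raw objectives are

* genetic gain $G(x) = x^\top a$,
* group coancestry $\mathcal{C}(x) = x^\top C x$, whose growth measures the
  loss of genetic diversity,
* mean expected progeny inbreeding
  $\bar F = \tfrac{1}{M}\sum_k C_{s_k d_k}$ over the planned matings — unlike
  group coancestry this depends on *which* pairs are formed, which is why
  contributions and mate allocation are optimized jointly.

The criterion is standardized internally to mean 0 and population SD 1, so
penalty weights and trade-off targets transfer across traits; raw-scale
values are reported in the outputs.

## Mating constraints and plan encoding

A valid plan satisfies: the number of matings M; a maximal number of parents
per role; minimal/equal/maximal contributions per selected parent; and the
selfing allowance (generic mode). In gendered mode each role supplies M
contributions; in generic mode the single pool supplies 2M, since each mating
consumes two slots.

A plan is encoded as a real vector: one *contribution gene* per candidate per
role, M *mate keys* (gendered) or 2M (generic), and one *edit-rank gene* per
editable candidate when editing is enabled. Decoding is deterministic and
total — every real vector yields a plan — which keeps the DE search space
unconstrained:

1. Candidates are ranked by contribution gene (descending, ties by candidate
   file order). The top `min(max_parents, n)` are kept, further capped by
   `floor(T / min_contrib)` when a minimum is set (keeping more parents would
   force the contribution total above T).
2. Positive gene parts are normalized to shares; an all-nonpositive block
   falls back to uniform shares. Share targets `share * T` are clamped to the
   contribution limits.
3. A largest-remainder apportionment rounds targets to integers summing
   exactly to T, incrementing only below the maximum and decrementing only
   above the minimum, with ties resolved in rank order. Largest-remainder is
   used because it is deterministic, sum-exact and order-stable. Breaches
   that gene patterns force anyway are *counted*, not thrown, and penalized.
4. Contribution slots are laid out in candidate order. In gendered mode the
   argsorted M mate keys permute the female slots against the fixed male
   slots; any pairing of the two slot lists is reachable. In generic mode the
   2M keys' argsort orders the single slot list and consecutive slots are
   paired. Two keys per mating are used deliberately: with only M keys
   permuting half the slots, some perfect matchings of the slot multiset are
   unreachable, and mate allocation (which drives progeny inbreeding) would
   be artificially restricted.
5. When selfing is disallowed, each selfed pair is repaired by a single
   deterministic swap pass; irreparable selfings are counted. Repair first,
   penalize what remains.

The scalar the engine maximizes is the mode's objective minus
`w * violations / M`, with `w = 1e4` by default on this normalized scale —
large enough that any valid plan beats any invalid one, while still grading
*how* invalid a plan is so the search can travel through mildly invalid
regions.

## The evolutionary engine

Classic DE/rand/1/bin with three measures against premature convergence:

* the differential weight F is dithered uniformly in `[0.1, 0.9]` each
  generation;
* the crossover rate alternates between 0.2 and 0.9 per generation, mixing
  coordinate-wise and block moves;
* when the best scalar improves by less than `tol` over a `window` of
  generations, the worst quarter of the population is re-initialized inside
  the population's coordinate range inflated twofold (the best member is
  always kept). Two consecutive stall-restarts without improvement terminate
  the run.

Selection is elitist, so the reported best never worsens. All randomness
flows from one seed, recorded in the outputs; identical seed and inputs
reproduce the output files byte for byte. Population defaults to
`min(10 * dimension, 200)`; chromosomes are initialized uniformly in
`[0, 1]`, which only sets initial diversity since decoding depends on ranks
and positive parts, not scale.

## Trade-off targets and the Pareto frontier

Multi-objective runs use two steps. First, two single-objective solves find
the bounds of the objective space: the max-gain solution (gain $G_{max}$,
coancestry $C_{@Gmax}$) and the min-coancestry solution ($C_{min}$,
$G_{@Cmin}$). Second, an $\varepsilon$-constraint solve maximizes gain
subject to coancestry at most $C^*$, realized as an exact penalty
`w * max(0, coancestry - C*) / (C_at_Gmax - C_min)` rather than hard
rejection, which keeps the search informative near the constraint boundary.

$C^*$ can be given in four forms:

| form | resolution |
|---|---|
| absolute value | $C^*$ as given |
| rate $\Delta C$ | $C^* = C_{now} + \Delta C\,(1 - C_{now})$ |
| percent $p$ | $C^* = C_{min} + (p/100)(C_{@Gmax} - C_{min})$ |
| degrees $\theta$ | $C^* = C_{min} + \cos\theta\,(C_{@Gmax} - C_{min})$ |

The degree convention is a documented design choice: $\theta$ is measured
from the gain axis, so $0^\circ$ recovers the max-gain solution and
$90^\circ$ the min-coancestry solution; an angle like $35^\circ$ is
gain-leaning. $C_{now}$ for the rate form defaults to the group coancestry
under uniform contributions across all candidates. Resolved targets outside
the bound interval are clamped with a warning; a degenerate span below
1e-12 collapses the frontier to a single point with a warning.

`sweep_frontier()` solves a uniform grid of angles. The endpoints reuse the
bound solutions (two DE runs saved, endpoint consistency guaranteed); each
interior angle derives its seed as `seed + round(degrees * 1000)` so a sweep
is reproducible while points stay independent. `pareto_filter()` removes
dominated points at tolerance 1e-9.

## Genome editing

When an edit budget $k$ and edited criteria are supplied, edit-rank genes are
appended to the chromosome. Among editable candidates *selected in the plan*,
the $k$ with the highest edit ranks use their edited merit in the gain;
non-contributors never consume budget, and when fewer than $k$ editable
candidates are selected the budget is simply under-used rather than forcing
selection. Both merit vectors are standardized with the non-edited location
and scale so they stay on one scale. Which loci are edited, and with what
effect, is upstream of this package: users (or the synthetic generator)
supply the edited criterion per candidate.

## The synthetic generator and what the tests show

The generator emulates two population types. The marker simulator draws
allele frequencies uniformly (default 0.1–0.9), genotypes as independent
binomial(2, p) dosages over unlinked biallelic loci, and per-locus additive
effects scaled to unit base genic variance; the criterion is the true merit
$G\alpha$ and the edited criterion flips the `edit_q` loci with the largest
achievable improvement to the favourable homozygote. The pedigree simulator
produces unrelated founders and random matings under the infinitesimal model
(child = parent mean + N(0, 0.5); the inbreeding adjustment of the Mendelian
sampling variance is deliberately omitted at these shallow depths).

Real data differ in ways the generator does not model: linkage and maps,
genotyping error and missingness, estimated (not true) breeding values, and
selection histories that structure allele frequencies. Passing tests
therefore demonstrate the *optimizer's* correctness and the *direction* of
the gain–diversity trade-off, not quantitative predictions for any real
program.

The toy recurrent-selection demonstration uses a cohort of 160 candidates,
16 crosses of 10 progeny each per cycle, at most 4 crosses per parent, 200
unlinked loci and 12 cycles — a deliberately small design that a single DE
run per cycle handles in seconds while still separating selection schemes.
Conversion efficiency is the negated slope of a per-replicate linear
regression of cohort genetic mean on cohort genic SD
($\sqrt{\sum 2p(1-p)\alpha^2}$), averaged over replicates; fitting per
replicate (rather than pooled) keeps replicates exchangeable. Across 20
replicates, a 35° scheme consistently converts diversity into gain more
efficiently than four-cross truncation, mirroring the qualitative behaviour
expected of optimal-contribution selection.

## Numerical choices

* Coancestry matrices: read-time asymmetry up to 1e-6 is averaged away,
  beyond that it is an error; alignment to candidates requires exact ID
  matches (silent dropping hides data errors).
* Pedigrees are topologically sorted internally; cycles are an error. The
  pedigree coancestry is reported as kinship ($A/2$), so pedigree- and
  marker-derived matrices share semantics. Marker coancestry is plain IBS
  allele sharing with $s(1,1) = 0.5$; the diagonal is *not* rescaled to the
  $0.5(1+F)$ pedigree convention, so gain/coancestry trade-offs are
  scale-dependent across sources (documented, not hidden).
* Brute-force verification is limited to 6 candidates and 4 matings; beyond
  that the enumeration explodes and the DE engine is the only solver.
* All tie-breaks (ranking, remainders, edit ranks, Pareto duplicates) resolve
  by candidate file order or lowest angle, making every decoding path
  deterministic.
* Test problem sizes (tiny oracle instances, 5-point editing frontiers,
  20-replicate toy demos) are the package's chosen study conditions: small
  enough to verify exhaustively or replicate many times, large enough to
  exercise every constraint type.

## Known limitations

* Matings have exactly two parents; generic and gendered candidates cannot
  be mixed in one pool.
* No missing-genotype imputation and no centered genomic relationship
  matrices — only IBS sharing.
* The $\varepsilon$-machinery constrains group coancestry; a separate
  inbreeding-rate constraint is not implemented.
* No linkage, GEBV estimation or editing-failure modelling in the synthetic
  module; those belong to upstream genetic-evaluation tools.
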
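---
title: "Group testing for cooperative compound discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group testing for cooperative compound discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooppool)
```

## The screening problem

Some chemical reactivity only appears when two compounds act together: an
acid activates a substrate, a donor and an acceptor form a charge-transfer
complex, a nucleophile unmasks an electrophile. Testing every pair of an
n-compound library for such cooperativity needs $\binom{n}{2}$ experiments
-- 4,950 for n = 100 -- which is why pairwise screens are rarely run
exhaustively. `cooppool` implements the statistics-based alternative: pool
the library into groups built from a *covering design*, screen the pools
with a cheap readout (here, luminescence quenching of an excited
photosensitizer), and resolve each positive pool down to its active pair(s)
with a few adaptive follow-up experiments.

The package has five working parts: covering-design construction
(`greedy_design()`, `swap_design()`), adaptive iterative-sectioning
deconvolution (`run_iterative()`), non-adaptive one-step signature
deconvolution (`onestep_design()`, `onestep_decode()`), a phenomenological
quenching model used to pick pool size and threshold (`quench_model()`,
`tradeoff_table()`), and an end-to-end campaign simulator
(`sample_truth()`, `run_campaign()`). A peak-table differ for reaction
follow-up screening (`match_peaks()`, `batch_compare()`) rounds out the
workflow.

## Covering designs

A covering design $C(n, k, t)$ is a family of $k$-member blocks of an
$n$-set such that every $t$-subset lies in at least $\lambda$ blocks. With
$t = 2$ and $\lambda = 1$, screening one pool per block guarantees every
pair is co-tested at least once. Optimal coverings (Steiner systems) rarely
exist and no general construction is known, so the package reports the
recursive Schönheim lower bound
$C(n,k,t) \ge \lceil \tfrac{n}{k} C(n-1,k-1,t-1) \rceil$
(`schonheim_bound()`) next to whatever a constructor achieves.

`greedy_design()` fills each block position by a three-stage rule:

1. keep the candidates that would newly cover the most uncovered
   $t$-subsets;
2. among those, keep the candidates occurring in the most uncovered
   $t$-subsets;
3. pick one uniformly at random.

Blocks are appended until coverage is complete, the whole construction is
restarted (default 1000 times), and the smallest design wins. Two
implementation points matter:

* **Blocks are filled to `k` even when a position covers nothing new.** The
  stage-2 filler is not wasted: it enables covered pairs at *later*
  positions of the same block. Closing blocks early as soon as no candidate
  adds coverage costs 5-7 extra blocks at (n = 100, k = 10); filled blocks
  reach 157-158, below the 159 that the swap search achieves.
* **Stage 2 is a heuristic with a known failure mode.** At (n = 6, k = 3)
  and (n = 7, k = 3) the incidence tie-break deterministically steers the
  construction away from the optimal coverings (6 and 7 blocks) no matter
  how many restarts are used, while a stage-1-only variant finds them. The
  rule stays because it is part of the published algorithm and it clearly
  helps at realistic sizes (dropping it costs ~10 blocks at n = 100); the
  toy-size suboptimality is documented in the acceptance suite rather than
  patched around.

`swap_design()` is the local-search alternative: start from `n_blocks`
random blocks and repeatedly apply the single-element swap that most
increases total coverage (random tie-break), restarting from a fresh random
family when stuck. Plain strictly-improving hill climbing plateaus well
short of record coverings -- it is retained as the reference the greedy is
compared against and for searching designs of a *prescribed* size (with
`n_blocks = NULL` it bisects between the Schönheim bound and a greedy
witness).

For $\lambda > 1$ the greedy may locally want to rebuild an existing block
(its pairs still need more coverage); since designs must consist of
distinct blocks, the constructor snapshots its coverage state, rejects the
duplicate, and retries with fresh tie-breaks.

## Iterative-sectioning deconvolution

A positive pool of size $k_0$ is resolved by a tree of subsets with sizes
$k_i = \lceil \tfrac{2}{3} k_{i-1} \rceil$, stopping at pairs: for
$k_0 = 10$ the cascade is 7, 5, 4, 3, 2 (`schedule()`). Children of a node
are built from a tripartition of its members into near-equal parts $A, B,
C$ as the unions $A \cup B$, $B \cup C$, $A \cup C$ (`make_children()`):
any two members share at least one child, so no pair can escape the
descent.

`run_iterative()` walks this tree depth-first, but only queries the oracle
when the answer is not already implied:

* a negative set excludes every pair (and singleton/triple) inside it;
* a set containing a confirmed entity must be positive, so it is never
  queried;
* a set whose candidate entities are all excluded must be negative;
* if every remaining candidate entity of a positive parent sits inside one
  child, that child is forced positive (its own test would carry no
  information).

**Confirmation requires a positive test of exactly the entity.** A leaf
pair implied positive by elimination is still queried once before being
reported (a memoized earlier query of the same set, e.g. the initial screen
of a pool that happens to be a pair, counts). This keeps reported hits
anchored to experiments rather than to model assumptions, at the price of
one query per entity.

**Continuation after a hit is a masked sweep.** Once a pair $\{a, b\}$ is
confirmed, every superset is positive and uninformative, and pairs
involving $a$ or $b$ can only be excluded by sets that avoid the partner.
The tripartition tree produces such sets poorly, degenerating into
one-pair-at-a-time leaf tests. Instead, on each new confirmation the walk
unwinds to the root, and a set $S$ containing a confirmed entity continues
through the *masked children* $S \setminus \{a\}$ and $S \setminus \{b\}$:
they jointly cover every pair of $S$ except the confirmed one, and a single
negative masked test excludes all remaining partner pairs wholesale. This
is the step a chemist would take -- re-pool without one member of the found
pair -- and it cut the mean per-pool deconvolution cost from ~8.7 to ~6
queries in campaign simulations.

Optional protocols, both off by default in `run_iterative()` and
controllable per campaign:

* `detect_singletons`: a positive leaf pair is disambiguated by testing its
  members alone (at most 2 extra queries; members already excluded by
  negative sets are not re-tested, so inside a campaign this usually costs
  nothing because the initial screen exonerates almost every compound).
* `detect_triples`: a positive node whose three children are all negative
  can only be explained by a three-way interaction spanning the
  tripartition; candidate triples whose internal pairs are all excluded are
  then tested directly. The published protocol for triples is not
  specified; direct testing of the few surviving candidates is the simplest
  protocol that is conclusive under a noiseless oracle.

With `prune = FALSE` every traversed set is queried; the reported entities
are provably unchanged under a noiseless oracle (the paired property test
checks this), only `tests_used` grows. All internal randomness (partition
order, exploration order) is derived from the session seed *and the node
members*, so pruned and unpruned runs traverse the same tree and replicate
runs are reproducible.

## One-step signature deconvolution

The non-adaptive alternative divides a positive pool of 10 into eight
subsets of seven such that every pair lights up a distinct, non-empty
subset pattern (`onestep_design()`, random restart search with a counting
feasibility pre-check: $2^{m} - 1 \ge \binom{k}{2}$ is necessary for $m$
subsets). All eight subsets are measured in one parallel round;
`onestep_decode()` inverts the pattern. Decoding is guaranteed only when
the pool holds exactly one active pair: any other pattern is returned as
*ambiguous* together with its consistent explanations (all small sets of
pairs whose signature union matches, and all single compounds whose
membership pattern matches). In campaign simulations ambiguous pools fall
back to iterative sectioning that reuses the recorded subset outcomes.

## The quenching model

The readout is the quenching percentage
$Q = 100\,(1 - I/I_0)$ (`quench_percent()`), with a pool called positive at
$Q \ge 60$ by default. Inactive compounds still quench slightly;
channels add on the Stern-Volmer scale, so a pool with per-compound
products $s_i$ ($K_{sv}[Q_i]$, dimensionless at working concentration)
retains $I/I_0 = 1/(1 + \sum_i s_i)$ (`combined_background()`). Per-compound
backgrounds are modelled log-normal. Defaults
(`meanlog = log(0.055)`, `sdlog = 0.9`, readout noise 2 percentage points)
are calibrated so a pool of ten inactive compounds crosses the 60%
threshold with probability ~3% -- inside the 1-5% band that motivates the
threshold choice -- and a single compound sits near 5% quenching. The
actual background distribution behind the published design is not public;
all parameters are exposed in `quench_model()` and accepted via the YAML
campaign config.

An active entity removes a fraction of the *remaining* emission (default
1.0, full extinction, matching reported total extinction for strong pairs);
multiple entities compose multiplicatively. `false_positive_prob()` gives
the Monte-Carlo probability that background alone triggers a hit,
`positive_group_prob()` the closed form $1 - (1 - p)^{\binom{k}{2}}$ under
independent per-pair activation with hit rate $p$ (default 0.5%).

**Pool-size trade-off.** `tradeoff_table()` tabulates, per pool size $k$:
the greedy design size; the probability a pool is positive (genuine hits
plus background false positives); and the simulated deconvolution cost of a
positive pool, with the number of planted pairs drawn
$\mathrm{Binomial}(\binom{k}{2}, p)$ conditioned on $\ge 1$, so multi-hit
complexity is priced in. The expected total
$\mathrm{blocks} \times (1 + p_+ \times \mathrm{cost})$ is U-shaped at
$p = 0.005$ over $k \in 4..20$ with its minimum at $k = 10$: small pools
waste screens, large pools drown in background false positives and
multi-hit deconvolution. The independence assumption behind
`positive_group_prob()` is violated by privileged "hub" compounds that
appear in many pairs; `sample_truth(hub_bias = ...)` exists precisely to
probe that violation.

## The campaign simulator

`sample_truth()` plants the stated world: a library of ~100 compounds that
are individually (near-)inactive, a small number of cooperative pairs
(default scenario: 15 pairs, per-pair hit probability ~0.5%), optionally
single quenchers, three-way interactions, and hub structure in which a few
privileged compounds anchor many pairs. Entity roles are disjoint by
construction -- a pair containing an active singleton is experimentally
unidentifiable (every set containing the pair is positive through the
singleton alone), so such truths are never generated.

`run_campaign()` executes design, screen, and deconvolution, counting every
oracle call: `total_tests = design_tests + deconv_tests`. Screen outcomes
and deconvolution queries feed one shared knowledge base (toggle with
`share_knowledge`), so negative pools exclude their 45 pairs wholesale and
a pool whose positivity is already explained by a known pair is not
re-resolved from scratch. The `parallel` strategy is the $k = 2$ covering:
all $\binom{n}{2}$ pairs tested directly, always exactly 4,950 experiments
at n = 100. Under a noiseless model, iterative campaigns recover planted
truths exactly (sensitivity 1.0, no false pairs), and the strategy ordering
iterative < one-step < parallel holds in far more than 95% of seeded
replicates. A positive pool whose deconvolution finds nothing (a
false-positive root under a noisy model) is reported in `unresolved` and
not retried.

What the generator does **not** emulate: real photophysics (energy vs.
electron transfer), correlated backgrounds or solvent effects, plate-level
artifacts, concentration dependence, and chemically structured hit
probabilities. A green simulation therefore establishes the combinatorial
and statistical machinery -- coverage, deconvolution logic, experiment
accounting -- not the chemistry.

## GC-MS reaction outcome analysis

Reactivity follow-up compares each reaction run's peak table against its
controls (`match_peaks()`): greedy nearest-retention-time assignment within
a tolerance (default 0.05 min), each control peak used at most once, an
optional spectral-cosine gate when unit-m/z spectra are present, and a
prominence floor (default 5% of the strongest reaction peak) separating
`new_peaks` from `low_unmatched`. Controls are matched independently, so
reports are invariant to control order; matching against a solvent blank
listed first realizes background subtraction. `batch_compare()` maps the
procedure over a (pair x acceptor) grid and ranks cells by new-peak
evidence, recording missing-control errors per run without aborting the
batch. Peak *picking* from raw chromatograms and vendor formats are out of
scope; published matching tolerances are not available, so the defaults are
config-exposed placeholders.

## Numerical and interface choices

* Candidate indices are 1-based in R objects; the JSON interchange format
  (designs, deconvolution logs, CLI) uses 0-based indices.
* All stochastic entry points take an integer `seed`; identical inputs and
  seed give byte-identical results. Deconvolution derives per-node seeds by
  hashing node members with the session seed, making the tree shape
  independent of pruning.
* `count_combinations()` and `schonheim_bound()` are exact integer
  computations; closed-form identities (background additivity, group
  positivity) hold to 1e-12 in the tests.
* Degenerate inputs: pools of size 2 are leaves (one query, or three with
  singleton disambiguation); `schedule(2)` is empty; empty peak tables
  produce empty reports; an oracle error aborts deconvolution with the
  partial query log attached to the condition.

## Known limitations

* The stage-2 greedy tie-break is provably suboptimal at two toy sizes (see
  above); the acceptance suite keeps the failing assertion visible.
* The swap search implements plain strictly-improving hill climbing; the
  published variant's acceptance rule is not public and record-size designs
  (159 blocks at n = 100) are out of its reach here.
* Noise is handled by thresholding and honest `unresolved` reporting only;
  there is no error-correcting (noise-tolerant) decoding.
* One-step decoding trusts an exact signature match; with multiple active
  pairs whose union mimics another signature it can mis-identify, which the
  campaign fallback mitigates but cannot eliminate.
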
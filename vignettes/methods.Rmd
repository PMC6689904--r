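---
title: "Methods: timing-rule sequence coding and permutation network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: timing-rule sequence coding and permutation network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestnet)
```

`gestnet` links two kinds of observational data on a fission–fusion primate
group — scan-sampled focal follows and a continuous gesture event log — and
asks whether dyads that spend more time together communicate differently.
This vignette documents the models, the timing rules, the tunable
parameters, and the design decisions behind the package, in that order.

## The coding model

A **gesture event** is one intentional, mechanically ineffective movement
directed at a recipient, time-stamped in seconds. Events form a **sequence**
when they share signaller, recipient and context and each consecutive pair
is at most 30 s apart (inclusive); any change of stream or a longer gap
starts a new sequence. Sequences are then classified purely from their
inter-gesture gap vector:

* no gaps (one gesture) → **single**;
* all gaps < 1 s → **rapid sequence**: the gestures follow too quickly for
  the signaller to have monitored the recipient;
* any gap ≥ 1 s → **persistence sequence**: at least one response-waiting
  pause occurred.

Three boundary conventions are fixed and tested: a gap of exactly 1 s
counts as response waiting; a gap of exactly 30 s still joins a sequence;
and the response-waiting window is read as the inclusive interval [1 s,
5 s]. Gaps in (5 s, 30 s] are a genuine ambiguity: the waiting window ends
at 5 s but the independence window ends at 30 s. By default any within-
sequence gap ≥ 1 s counts as persistence, which maximizes consistency with
the 30-s rule; setting `strict_wait_window = TRUE` in
`segment_sequences()` instead splits sequences at gaps above 5 s, for
sensitivity analysis. Classification uses timestamp-to-timestamp gaps
(event logs carry no durations), and context equality is exact string
match, since context is observer-coded upstream. Multi-recipient
(broadcast) events are expanded to one event per recipient before
segmentation because all downstream quantities are per directed dyad.

Whether persistence additionally requires the *failure* of the previous
gesture (no response before the pause) is not part of the timing
definition used here; the coder is deliberately a pure function of the gap
vector, and a rapid burst followed by a waiting pause and another burst is
one persistence sequence, not a hybrid.

## Dyadic measures

Each 2-min scan records the focal's party members and the subset within
10 m. For an ordered dyad (A, B), with C_AB communication counts while B
was within 10 m, P10_AB within-10 m scan counts and party_AB party scan
counts:

* communication rate: CA_AB = (C_AB × 60) / (P10_AB × 2) events per hour
  of co-proximity. The denominator is proximity time in *minutes* (each
  scan represents a 2-min window), which dimensional analysis forces; the
  same formula is applied per sequence class and per response grouping
  (response present/absent and the three response types), one matrix each,
  since the hypothesis models treat them as separate networks.
* proximity: PROX_AB = 60 × P10_AB / party_AB minutes within 10 m per
  party-hour, bounded in [0, 60].

A sequence is attributed to the scan interval containing its first
gesture; if the recipient was not within 10 m at that scan the sequence is
excluded from the counts but reported (`excluded_sequences`), since the
rate's denominator is proximity time. Dyads with zero exposure (never
within 10 m, or never in the same party) get rate 0 and are flagged rather
than dropped, because the permutation regressions need complete matrices;
`drop_zero_exposure = TRUE` in `build_networks()` instead builds a mask
used for listwise deletion of those dyads in every model.

Attribute similarity matrices are binary and symmetric: same sex; same age
class (absolute age difference ≤ 5 years, computed from ages at study
time, not birth-year bins); reproductively active pairing (male ×
cycling female — in the attribute vocabulary only cycling females can be
in oestrus); and maternal kinship (mother–offspring links from the
`mother_id` column). The packaged 12-adult attribute table reproduces the
published similarity margins for age (30 same-age vs 102 different-age
ordered dyads) and reproductive pairing (36 active dyads); its mother
links are unknown and left empty, so kinship tests use synthetic
pedigrees. The published sex-similarity margin (60/60) is arithmetically
inconsistent with a 6-male/6-female group (which forces 60 same-sex and 72
different-sex ordered dyads); the package codes sex similarity by
definition and makes no attempt to reproduce that margin.

## Permutation inference

Dyadic observations sharing a row or column are not independent, so all
inference relabels *nodes*: a permutation is applied simultaneously to
rows and columns, preserving the dyadic dependence structure under the
null.

**QAP correlation** compares the observed Pearson correlation of the
off-diagonal vectors against correlations under relabelings of one
matrix. **MRQAP with Double-Dekker semi-partialling** fits OLS of the
outcome dyad vector on the predictor vectors (with an intercept, never
permuted or reported), then builds each predictor's null by (i) regressing
that predictor's vector on the remaining predictors, (ii) re-forming the
residuals as a matrix, (iii) relabeling it, (iv) substituting it for the
predictor and refitting. Permuting the residual rather than the raw
predictor is what makes the test robust to autocorrelation carried by the
other predictors and the outcome. Implementation notes:

* Residualization happens on **raw** vectors; standardized coefficients
  (from z-scored vectors) are reported separately, so p-values cannot
  depend on an arbitrary scaling step. Classical OLS standard errors are
  emitted for reference and labeled as such — they are not
  permutation-valid.
* Tests are two-sided: p = proportion of relabelings with |β*| ≥ |β|.
  In sampled mode the (+1)/(+1) estimator is used, so p ∈ (0, 1]. Ties
  count toward rejection (conservative); a relative tolerance of 1e-8
  protects exact ties (e.g. the identity relabeling) from floating-point
  round-off, since the observed and permuted statistics are computed by
  different numerical routes (full QR fit vs the
  Frisch–Waugh–Lovell shortcut used in the permutation loop, which gives
  the same coefficient analytically).
* When n! ≤ 5040 (n ≤ 7) the engine automatically enumerates **all**
  relabelings and reports the exact proportion (identity included, so
  p ≥ 1/n!); this exhaustive mode is the primary correctness oracle in the
  test suite, which checks it against an independent brute-force
  implementation.
* One independent permutation stream is derived per predictor from the
  single user seed, so results are reproducible and independent of
  evaluation order.
* With a single predictor, semi-partialling reduces to permuting the
  centered predictor itself; because relabeling permutes the off-diagonal
  cells among themselves, its variance is invariant and the DSP p-value
  coincides exactly with the QAP-correlation p-value in exhaustive mode —
  another identity the tests assert.

**Node-level regression** permutes the outcome vector across nodes
(exchangeability of node labels under the null); covariate permutation is
a documented alternative, not implemented. Degree centralities are plain
row/column sums with the diagonal excluded. The centrality model uses
proximity outdegree as the outcome and, as controls, proximity directed
at cycling females, proximity directed at maternal kin, and the focal's
sex and age. The published model prints a single combined "sex/age" row
without defining the composite; the package defaults to two separate
columns and offers `sex_age = "combined"` (z-scored age plus z-scored male
indicator) as the alternative encoding, flagged in the documentation
because neither reading is canonical.

**Reliability** uses unweighted Cohen's kappa (codes are nominal), with
the per-response-type report computed on presence/absence binarizations of
each category, one kappa per category. The degenerate case p_e = 1 can
only arise with perfect agreement and is defined as kappa = 1.

## The synthetic generator

The generator emulates the study design the pipeline assumes: 12 adults
(6 males; 3 cycling among 6 females), 18-min follows of nine 2-min scans,
25 follows per focal (about 7.5 h of focal observation each, the order of
magnitude of published field efforts), and planted structure:

* **Latent sociality** s_AB is i.i.d. log-normal per unordered dyad
  (meanlog 0, sdlog 1), symmetrized — positive and right-skewed, like
  observed proximity durations. All planted effects act on the
  standardized log scale z_AB = (log s_AB − meanlog)/sdlog, so effect
  sizes are per-SD and independent of the distribution's parameters.
* **Association**: at each scan a non-focal joins the party with
  probability plogis(qlogis(0.5) + 0.5 z) and, if in the party, is within
  10 m with probability plogis(qlogis(0.365) + z). The 0.365 baseline was
  solved numerically so the expected proximity measure matches the
  published group mean of 23.26 min per party-hour; the generated grand
  mean averages ≈ 23.2 across replicates.
* **Gesture initiation** is Poisson per dyad × 2-min co-proximity
  interval — the simplest rate model consistent with per-hour outcome
  measures — with per-hour intercepts equal to the published
  per-proximity-hour means (single 1.27, rapid 0.45, persistence 0.11).
  Only the persistence rate is modulated: λ_pers ∝ exp(0.66 z). The 0.66
  default was calibrated once by simulation so that the standardized
  persistence coefficient in the proximity model averages ≈ 0.3 under the
  default design, and is not revisited.
* **Timing signatures** are drawn away from the classification
  boundaries: rapid gaps in [0.1, 0.8] s, persistence gaps in
  [1.5, 4.5] s, and consecutive sequences of the same dyad separated by at
  least 40 s (> the 30-s window), so re-coding the synthetic log recovers
  every planted class exactly — a round-trip the tests assert at 100%.
  A sequence that cannot be placed inside its 2-min interval with full
  separation (which requires an improbable 3+ initiations in one
  dyad-interval) is dropped and counted; the resulting bias is orders of
  magnitude below the Poisson sampling noise any test resolves.
* **Responses** are annotations on the sequence, not simulated behaviour
  streams, drawn from class-conditional category probabilities. The
  default table was derived by fixing the planted signs (vocalisation
  dominates responses to rapid sequences at 0.68; activity change
  dominates responses to persistence at 0.70) and solving the single-
  gesture row so the *marginal* response-type rates match the published
  per-proximity-hour means (activity change 0.58, vocalisation 0.47,
  visual/tactile 0.08 of a 1.83 total).

What the generator does **not** emulate: party composition is drawn
independently per scan (no within-follow autocorrelation beyond the shared
dyad probabilities); no demography, no activity or attention streams, no
acoustics; effort is even across focals unless `effort_multiplier` is set
(real sampling was uneven). Passing tests therefore show that the
*pipeline* recovers what it is supposed to recover under the stated
stochastic model — not that field data satisfy that model.

## Problem sizes and numerical choices

The statistical guarantees are checked at these sizes: exhaustive
enumeration at n = 4–5 (24–120 relabelings) against brute force; type-I
calibration at n = 12 with 500 replicates of 999 permutations per test
(binomial 99% CI around 0.05); planted-effect recovery and the matched
null with 200 replicates of the full generate–code–build–fit chain at 999
permutations. Default inference uses 2000 sampled permutations.
Zero-variance vectors, rank-deficient designs (reported by predictor
name), constant outcomes and unknown node labels are all hard errors, not
silent fixes; a nonzero matrix diagonal on file read warns and zeroes by
default.

## Known limitations

* **Rate matrices are not exactly exchangeable under the null.** The
  communication measure divides a count by the dyad's within-10 m exposure
  time, so dyads with little co-proximity have much noisier rates — and
  exposure itself determines the proximity outcome. Even with no planted
  effect, the persistence coefficient in the proximity model rejects at
  about 0.10 rather than the nominal 0.05 (the acceptance script measures
  this as `h1_persistence_null_rejection_pct`). This is a property of
  exposure-normalized rates, not of the permutation engine: the same
  engine holds its size exactly under a row/column-autocorrelated Gaussian
  null, and the inflation disappears when the generator decouples
  sociality from exposure. Substituting a pivotal t-statistic for the raw
  coefficient does not remove it. Users should read borderline p-values on
  rate predictors (0.01–0.10) with this in mind; the planted-effect power
  and effect-size checks are unaffected.
* The published regression coefficients themselves are not reproducible —
  they depend on unavailable raw field data; the package reproduces the
  printed *inputs* (attribute similarity margins, dyad counts, the rate
  formulas) and validates the machinery on synthetic data instead.
* MRQAP p-values at n = 12 are Monte-Carlo estimates; with 2000
  permutations their resolution is ≈ 0.0005 and rates near 0.05 carry
  binomial noise.
* The semi-partialling null permutes residual matrices; with structurally
  masked dyads the masked cells are held at zero during relabeling, an
  approximation that matters only when many dyads are masked.
* Exhaustive mode is capped at n! ≤ 5040; larger groups always use
  sampling.
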
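---
title: "Dynamic networks and hypergraphs for two-compartment inflammation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic networks and hypergraphs for two-compartment inflammation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inflamnet)
```

## The data and the question

`inflamnet` analyzes longitudinal multiplex immunoassay panels measured in
two tissue compartments. The canonical design it targets: trauma patients
sampled at up to five surgical debridements (visits n1–n5, roughly every 3
days), with a 23-mediator cytokine/chemokine panel (pg/mL) quantified in
both peripheral serum (the systemic compartment) and wound effluent (the
local compartment), and patients grouped by a clinical factor such as the
presence of traumatic brain injury (TBI vs. non-TBI). The scientific
question is not just which mediators differ between groups, but how the
*coordination* of mediators — within a compartment, across compartments,
and over time — differs.

All functions operate on a `cohort_table`: a validated long-format
data.frame (one measurement per row) carrying the mediator panel as an
attribute. Duplicate observation keys, unknown mediators, out-of-range
debridement indices and inconsistent group labels are rejected at
construction, so downstream stages can assume a coherent table.

## Interval correlation networks

For one group, one compartment (or both), and one consecutive-debridement
interval (k, k+1), `build_network()` draws an edge between mediators whose
trajectories move together across the interval: the Pearson correlation of
their interval samples satisfies r ≥ threshold (parallel) or
r ≤ −threshold (antiparallel). The default threshold is 0.95 and the
comparison is inclusive on both sides.

Two sample constructions are exposed because "trajectories moving in
parallel" admits more than one formalization with per-patient data:

* **stacked** (default): each patient contributes its values at both
  endpoints as two separate sample columns, so an interval with P complete
  patients yields 2P samples per mediator;
* **delta**: each patient contributes one column holding
  level(k+1) − level(k).

Both are first-class and tested; figures-facing defaults use stacked.

Missingness is handled pairwise-complete: a patient enters an interval
only if it has measured values at both endpoints, remaining holes are NA,
and each mediator pair is tested on its complete sample pairs, requiring
at least 3. Listwise deletion was rejected because a sparse cohort would
lose most of its patients. Mediators with zero variance in the interval
remain nodes but are never tested for edges (their correlation is
undefined); this is the only tie-break the edge rule needs. No
multiple-testing correction is applied: the method is a threshold on r by
definition, not a p-value procedure.

Two summary scores are attached to each network with n mediators and
connection counts N₁…N_n:

* **complexity** (N₁ + … + N_n)/(n − 1), algebraically 2|E|/(n − 1),
  ranging from 0 (empty) to n (complete graph);
* **Shannon entropy** of the connection-probability distribution. The
  per-mediator connection probability admits two readings, and the
  package exposes both: `"paper"` mode divides each N_i by the number of
  possible partners per mediator (n − 1 nodes it could attach to, counting
  across compartments in cross-compartment mode), so the p_i need not sum
  to one and the complete graph has entropy 0; `"normalized"` mode divides
  by Σ N_j, giving a genuine distribution bounded by log₂ n and assigning
  the single-edge network exactly 1 bit. `"paper"` is the default; which
  normalization produced any given published entropy curve is generally
  not recoverable from figures, so both are reported in exports.

Cross-compartment mode pools both compartments into one node set with
`s`/`e` prefixes (`sIL-17A`, `eTNF-a`). With a single compartment the
prefix is dropped and the mode reduces exactly to the single-compartment
network. Entropy's per-mediator possible-connection count is the node-set
size minus one in both modes (n − 1 single-compartment, 2n − 1
cross-compartment).

## Dynamic hypergraphs

Interval networks see coordination *within* a time step;
the hypergraph stage sees monotone *trends across* time steps and where
they co-occur spatially. Over each sliding three-debridement window
(n1–n3, n2–n4, n3–n5), `trend_correlation()` computes the group mean of a
mediator at the window's three debridements and correlates those three
centers with time coded (0, 3, 6) days. The fixed 3-day coding is used
even though real inter-debridement gaps vary around 3 days; with only
three support points the correlation is insensitive to modest spacing
perturbations, and the fixed design keeps windows comparable. The mean is
the default center (matching the mean-quantification convention of
multiplex readouts); a median option is provided for robustness studies
only. The gate is **strict**: a trend passes iff |r| > threshold (default
0.95) — deliberately different from the interval-network rule, which is
inclusive. Centers that are constant to within a 10⁻¹⁰ relative tolerance
are flagged degenerate and never pass; the tolerance matters because
synthetic flat trends are constant only to machine precision.

In the hypergraph, nodes are compartments and edges are mediators: each
passing mediator attaches to exactly the subset of compartments in which
it passes with the given sign, and all mediators sharing a subset share
one hyperedge labeled with their names. Increasing and decreasing trends
build separate hypergraphs; a mediator rising in one compartment and
falling in the other therefore appears in the increasing-{A} and
decreasing-{B} structures separately, never in a joint hyperedge. This
keeps the partition property exact: per (window, sign), every passing
mediator lies in exactly one compartment subset.

The **edge distribution** counts hyperedge mediators per (window, subset,
sign), including explicit zeros. Group differences for one subset are
tested by `compare_distributions()`, which forms the 2 × windows count
table and applies an exact conditional test with both margins fixed:
every margin-compatible table is enumerated, weighted by its multivariate
hypergeometric probability, and the two-sided p is the total probability
of tables no more probable than the observed one (the standard
convention). The published analysis this reconstructs did not print its
table layout; the group × window homogeneity framing used here is one
reconstruction and is labeled as such in outputs. Above an enumeration
budget (2×10⁵ tables) the test switches to a fixed-seed Monte Carlo
estimate over margin-conditioned tables; edge-distribution counts are
small, so the fallback exists for robustness, not for routine use.

## Th17 subset inference

IL-17A can be produced by several cell populations with distinct
co-expression signatures: pathogenic Th17 cells co-express GM-CSF,
non-pathogenic Th17 cells co-express IL-10, and memory/effector T cells
co-express TNF-a. `infer_subsets()` therefore rank-correlates IL-17A with
each partner within one group and compartment, pooling all
(patient, debridement) observations as pairs; pooling is the default
because the published convention does not state a pooling level, and a
per-debridement stratified variant is exposed for sensitivity analysis.
Spearman's rho uses average ranks for ties; the 95% interval is a
percentile bootstrap over pair resamples (B = 1000 default) — the
simplest method consistent with a "bootstrapped confidence interval" —
and verdicts rest on the CI: *inferred-present* above zero,
*inferred-reduced* below, otherwise *indeterminate*. The labels are an
interpretive convention, not a cell measurement. With several hundred
pooled pairs the CI is narrow, so small incidental correlations can
occasionally produce a non-indeterminate call for an uncoupled pair;
calibration under independence is exercised in the test suite.

## Screening statistics

`anova_screen()` fits, per mediator and compartment,
`value ~ group * factor(debridement)` and reports Type II sums-of-squares
p-values (via `car::Anova`), the appropriate choice for the unbalanced
group sizes; the headline flag uses the group main effect. When a
(group × debridement) cell is empty the interaction is dropped; with a
single debridement level the time factor is dropped entirely and the test
reduces to the two-sample comparison (F = t²). Debridement is treated as
an independent factor, not a repeated measure — the cost is some
within-patient correlation ignored; a mixed-model treatment is out of
scope and the limitation is deliberate. No multiplicity correction is
applied across the 23 mediators by default (matching per-mediator
reporting conventions); a Benjamini–Hochberg option exists.
`chi_square_2x2()` applies the Yates continuity correction by default,
which is what reproduces the printed p ≈ 0.001 for the worked
wound-number table ([[26, 51], [4, 49]]); the uncorrected statistic
(≈ 12.16) is available with `yates = FALSE`.

## The synthetic-cohort generator

Raw cohorts of this design are not publicly deposited, so the generator
is a first-class module: it produces cohorts with exactly the statistical
structure the stages detect, making every pipeline claim testable.

* **Baselines** are lognormal — exp(μ + σz), z standard normal — because
  concentrations are strictly positive and biological effects are
  multiplicative. Defaults: μ = log 50 pg/mL, σ = 0.5 for every mediator,
  chosen once as order-of-magnitude realism for a Luminex panel; no
  attempt is made to match unpublished per-mediator distributions.
* **Group effects** are multiplicative shifts per
  (mediator, compartment, group).
* **Planted pair correlations** are specified on the *raw* scale and
  implanted through a Gaussian copula on the log scale, with the copula
  correlation obtained by inverting the exact bivariate-lognormal
  correlation formula — so the empirical stacked-interval Pearson matches
  the target without attenuation bias. Lognormal margins bound the
  attainable negative correlation (about −0.78 at σ = 0.5); targets below
  the bound are clamped with a warning. When several planted pairs share
  a debridement the assembled correlation matrix is repaired to the
  nearest positive-definite matrix only if needed.
* **Planted trends** fix the per-debridement group-mean schedule
  base + slope·(0, 1, 2) (one step per debridement), optionally perturbed
  by Gaussian noise on each timepoint mean, by multiplicatively
  recentering that cell's values — preserving positivity and making the
  zero-noise case exactly arithmetic. Chained windows anchor on the level
  a previous window left behind, so multi-window trajectories stay
  continuous.
* **Missing visits** are dropped completely at random at a configurable
  rate (both compartments at once); the real missingness mechanism is
  unknown, and MCAR is the neutral choice.

`paper_like_config()` packages the study conditions: 59 TBI / 81 non-TBI
patients; IL-17A shifted 2.5× upward in both compartments of the TBI
group only; a denser planted serum correlation structure in TBI
(IL-17A–GM-CSF and IL-17A–TNF-a at 0.97, GM-CSF–TNF-a at 0.9, IL-2–IL-7
at 0.99, at every interval) versus one non-TBI pair; rising TBI trends
(effluent TNF-a over n1–n3, serum TNF-a over n2–n4, serum IL-6 and
IL-17A over n3–n5) and falling non-TBI IFN-g trends in both compartments
over n2–n4; IL-10 left uncoupled from IL-17A; 10% missing visits. TBI
patients are all blast-injured; the non-TBI arm mixes blast and gunshot
mechanisms at the observed frequency.

What the generator does **not** emulate: within-patient autocorrelation
across debridements (each visit is drawn independently given the planted
structure), informative missingness, detection-limit censoring, and
inter-mediator correlation beyond the planted pairs. Passing tests
therefore demonstrate that the stages recover known structure under
clean conditions — not that real cohorts satisfy those conditions.

One interaction deserves note: with only three time points, the trend
correlation of an *unconstrained* mediator's random centers exceeds 0.95
in roughly a fifth of draws (the three-point correlation under
independence is arcsine-distributed, regardless of sample size). Exact
edge-distribution recovery is therefore only a meaningful contract when
every non-planted (mediator, compartment) is pinned flat (slope 0, zero
noise), and that is how the recovery tests are constructed. On realistic
noisy cohorts, three-point trend gating is permissive by nature — a
property of the method, not of this implementation.

## Numerical choices and problem sizes

Determinism: every stochastic routine (`generate_cohort`,
`spearman_bootstrap`, the Monte Carlo fallback of `fisher_exact`,
`run_pipeline`) takes a seed, uses it locally, and restores the caller's
RNG state, so pipeline reruns are byte-identical.

The validation suite sizes its simulations to be decisive yet quick: the
brute-force network oracle runs on 100 random 6-mediator, 10-patient
cohorts; planted-edge recovery and null spurious-edge rates use 100 seeds
at 60 patients with the full 23-mediator panel; bootstrap CI calibration
uses 200 simulations at n = 100 with B = 1000; the ANOVA null uses 200
cohorts of 15 + 15 patients with a 6-mediator panel. The 2×2 exact test
is checked against the closed-form hypergeometric rule on all tables with
N ≤ 20, and the 2×3 enumeration against an independent brute-force loop.

## Known limitations

* The two-way ANOVA ignores repeated measures within patient.
* Three-point trend correlations have essentially no multiplicity
  control; the hypergraph stage is exploratory by construction.
* The exact-test layout for comparing edge distributions is a
  reconstruction (group × window within one compartment subset).
* The entropy normalization actually used in published curves is
  ambiguous; both modes are computed.
* Concentrations at or below detection limits are taken at face value;
  no imputation or censoring model is applied.
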
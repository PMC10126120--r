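# inflamnet

Dynamic network and hypergraph analysis of multi-compartment inflammation.

Severe tissue injury triggers inflammation both locally (in the wound) and
systemically (in the circulation), and the two compartments talk to each
other. `inflamnet` is an R toolkit for studying that crosstalk from
longitudinal multiplex cytokine panels: concentrations of a fixed mediator
panel (23 cytokines/chemokines, pg/mL) measured in **serum** and **wound
effluent** at successive surgical debridements (visits n1–n5, roughly every
3 days), in patient groups such as trauma with vs. without traumatic brain
injury (TBI vs. non-TBI). Because patient-level datasets of this kind are
rarely deposited, the package ships a synthetic-cohort generator with
plantable correlation and trend structure, so every stage of the pipeline
is testable end to end.

## Methods at a glance

**Interval correlation networks (DyNA).** For each consecutive debridement
interval (n1–n2, …, n4–n5) and patient group, mediators become nodes and an
undirected edge joins mediators *i, j* when the Pearson correlation of
their trajectories over the interval satisfies |r| ≥ 0.95 — positive r is a
*parallel* (black) edge, negative an *antiparallel* (red) edge. Two sample
constructions are provided: *stacked* (each patient contributes its values
at both endpoints as separate samples; the default) and *delta* (per-patient
endpoint differences). Networks are summarized by

- **network complexity** = (N₁ + N₂ + … + N_n) / (n − 1), where N_i is
  mediator i's connection count and n the panel size (equals 2|E|/(n−1);
  the complete graph on 23 mediators scores 23), and
- **Shannon entropy** H = −Σ p_i log₂ p_i of the connection-probability
  distribution, with p_i = N_i / (possible connections per mediator)
  ("paper" mode) or p_i = N_i / Σ N_j ("normalized" mode).

Cross-compartment networks pool both compartments with `s`/`e`-prefixed
nodes (e.g. `sIL-17A`, `eTNF-a`).

**Dynamic hypergraphs (DyHyp).** Over each sliding three-debridement window
(n1–n3, n2–n4, n3–n5), a mediator's per-debridement group mean is
correlated with time coded (0, 3, 6) days. Mediators with |r| > 0.95 are
significantly increasing (r > 0) or decreasing (r < 0). In the hypergraph
the *nodes are tissue compartments* and the *edges are mediators*: a
passing mediator attaches to exactly the compartment subset in which it
passes with that sign, and mediators sharing a subset share one hyperedge.
The **edge distribution** (hyperedge counts per compartment subset ×
window) traces spatial shifts of inflammation; group differences are tested
with an exact conditional (Fisher-type) test on the group × window count
table, implemented by full enumeration of margin-fixed tables with a
fixed-seed Monte Carlo fallback.

**Th17 subset inference.** Spearman rank correlation of IL-17A with GM-CSF
(pathogenic Th17), IL-10 (non-pathogenic Th17) and TNF-a (memory/effector
T cells), with 95% percentile-bootstrap confidence intervals; a subset is
called *inferred-present* when the CI lies above zero and
*inferred-reduced* when below.

**Screening statistics.** Per-mediator two-way ANOVA (group × debridement,
Type II sums of squares), Yates-corrected 2×2 chi-square tests, and a
clinical characteristics table with counts, percentages and per-descriptor
chi-square p-values.

## Worked example

```r
library(inflamnet)

co <- generate_cohort(paper_like_config(seed = 17))
co
#> Cohort table: 28842 observations, 140 patients, 23 mediators, 5 debridements
#> group
#> nonTBI    TBI
#>     81     59

net <- build_network(co, group = "TBI", compartments = "serum",
                     interval = "n4-n5")
net$edges
#>   node_a node_b     sign         r
#> 1   IL-2   IL-7 parallel 0.9859901
network_complexity(net)
#> [1] 0.09090909
shannon_entropy(net)
#> [1] 0.4054029

trend_correlation(co, group = "TBI", compartment = "serum",
                  mediator = "TNF-a", window = "n2-n4")
#> Trend TNF-a [serum, TBI, n2-n4]: r = 0.9999, passes (increasing)

infer_subsets(co, group = "TBI", compartment = "serum", seed = 17)
#>   partner          population   rho   n  ci_low ci_high          verdict
#> 1  GM-CSF     pathogenic Th17 0.935 263  0.9146   0.948 inferred-present
#> 2   IL-10 non-pathogenic Th17 0.053 263 -0.0691   0.174    indeterminate
#> 3   TNF-a   memory/effector T 0.786 263  0.7364   0.824 inferred-present
```

The generated cohort carries a planted IL-2/IL-7 serum correlation in the
TBI group at n4–n5 — recovered here as the network's edge (r ≈ 0.986, one
edge → complexity 2/22 ≈ 0.091, entropy 2·(1/22)·log₂22 ≈ 0.405 bits) — a
planted rising serum TNF-a trend over n2–n4 (r ≈ 1, passes the |r| > 0.95
gate), and IL-17A coupled to GM-CSF and TNF-a but not IL-10, so only the
pathogenic-Th17 and memory/effector signatures are inferred present.

`run_pipeline()` drives all stages at once and writes
CSV/JSON/GraphML artifacts plus a manifest:

```r
run_pipeline(list(input = paper_like_config(seed = 17), out_dir = "out"))
```

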
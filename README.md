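# chainreg

Chain-graph (graphical Markov) analysis of how a lifestyle intervention
and genetic predisposition jointly drive changes in glycaemic traits —
built for epidemiologists and biostatisticians analysing two-arm trials
with a small SNP panel, and for methodologists who want a tested,
fully reproducible implementation of *sequences of regressions* with a
ground-truth simulator.

The scientific question the package addresses: after twelve months of a
weight-management programme, how much of the change in insulin
sensitivity (HOMA-IR), insulin secretion (HOMA-B), fasting glucose and
HbA1c flows through weight loss, diet and physical activity, and how
much through a type 2 diabetes genetic predisposition score (GPS)?

## The model

Variables are arranged in ordered boxes by order of exposure, responses
leftmost:

```
[Δ outcomes] ← [Δ weight] ← [Δ satfat %E, Δ steps] ← [arm] ← [GPS, age, sex, country]
```

For each response *y* with right-hand variables *x₁…xₚ*, an ordinary
least-squares model is fitted and reduced by backward elimination using
partial F-tests,

  F = [(RSSᵣ − RSS_f)/(df_r − df_f)] / [RSS_f/df_f],

at selection level α = 0.05; prespecified, clinically motivated product
terms (e.g. Δweight × Δsatfat, arm × Δweight, GPS × Δweight) are
screened by the same nested comparison with main effects forced in. The
chain graph is read off the selected models: directed edges (partial
regression coefficient, SE, p) for retained terms with p < 0.10, dashed
interaction edges for product terms, undirected edges among intrinsic
variables, and missing edges as conditional-independence statements.
Outcomes are log ratios ln(month12/baseline), so a fitted linear
predictor exponentiates to a final/baseline ratio and percent change.

Around this core the package provides SNP-panel QC (call rate,
Hardy–Weinberg likelihood-ratio G-test on 1 df with Bonferroni cutoff,
composite LD r²), unweighted risk-allele scoring with mean imputation,
HOMA-index and dietary trait derivation, a participant exclusion
cascade, DOT/JSON graph export, and a synthetic-cohort generator with
queryable ground truth for structure- and parameter-recovery
benchmarking.

## Worked example

```r
library(chainreg)

sim <- generate_cohort(synthetic_config(seed = 42, n_enrolled = 772))
nrow(sim$cohort)                       # 363 retained of 772 enrolled
g <- fit_chain_graph(sim$cohort,
                     interactions = default_pipeline_config()$interactions)
g
#> chain_graph: 12 nodes, 19 edge(s) at alpha = 0.1
#>                   source       target        type coefficient        se   p_value
#> 1               d_weight   lr_homa_ir    directed   0.0227156 0.0033356 4.136e-11
#> 2                    gps   lr_homa_ir    directed  -0.0195202 0.0057523 7.674e-04
#> 3           d_satfat_pct   lr_homa_ir    directed   0.0366308 0.0105827 6.024e-04
#> 4  d_satfat_pct:d_weight   lr_homa_ir interaction   0.0058432 0.0012358 3.260e-06
#> ...
#> 17                   arm     d_weight    directed  -3.5647384 0.5686867 1.044e-09
#> 18                   arm d_satfat_pct    directed  -1.2554843 0.2475101 6.302e-07
```

Reading the common paths: the intervention arm lowered dietary
saturated fat by 1.26 percentage points of energy and weight by an
additional 3.56 kg (close to the planted −1.13 and −3.53), and weight
change carries through to every outcome — e.g. each kilogram lost
multiplies HOMA-IR by exp(0.0227) ≈ 0.978 per kg in reverse. Path-based
predictions sweep the genetic score at fixed mean lifestyle change:

```r
fit <- g$fits$lr_homa_ir
variance_explained(fit)                # 0.156
at <- list(d_weight = mean(sim$cohort$d_weight),
           d_satfat_pct = mean(sim$cohort$d_satfat_pct))
predict_outcome_ratio(fit, c(at, gps = 20))$pct_change   # -10.6 %
predict_outcome_ratio(fit, c(at, gps = 24))$pct_change   # -17.4 %
```

so at this cohort's mean weight and diet change, a participant at the
lower GPS quartile is predicted to improve HOMA-IR by ~11%, one at the
upper quartile by ~17%. `export_graph_dot(g, "graph.dot")` writes the
Graphviz figure; `run_pipeline()` orchestrates the full path from raw
panel/genotype/phenotype files to artefacts.

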
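---
title: "Chain-graph modelling of lifestyle and genetic effects: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chain-graph modelling of lifestyle and genetic effects: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chainreg` implements a graphical Markov (chain-graph) analysis for
two-arm lifestyle-intervention cohorts: how does a randomised treatment,
acting through changes in diet, physical activity and body weight, alter
glycaemic traits over twelve months, once intrinsic characteristics —
age, sex, study centre and a genetic predisposition score — are taken
into account? This vignette documents the model, its tunable parameters,
the synthetic-cohort generator used for validation, and the numerical
and design choices a maintainer would want to know about.

## The model: sequences of regressions over ordered boxes

Variables are partitioned into ordered boxes by order of exposure,
responses leftmost:

1. outcome changes — log ratios `ln(month12 / baseline)` of HOMA-IR,
   HOMA-B, fasting glucose, HbA1c (stacked: analysed separately);
2. weight change (kg);
3. lifestyle changes (stacked): dietary saturated fat as percent of
   total energy, and mean daily steps in thousands;
4. treatment arm (standard care `SC` vs commercial programme `CP`);
5. intrinsic characteristics: genetic predisposition score (GPS), age,
   sex, country.

Every continuous variable outside the rightmost box is a response to
everything strictly to its right. For each response we fit ordinary
least squares on all right-hand variables (`fit_full_model()`), then
reduce the model by backward elimination (`select_model()`): at each
step every droppable term is tested with a partial F-test

$$F = \frac{(RSS_r - RSS_f)/(df_r - df_f)}{RSS_f / df_f},$$

and the term with the largest p-value above `selection_alpha` (default
0.05) is removed; categorical variables move as whole dummy blocks. Ties
are broken by the smaller absolute t-statistic and then term name, so
selection is deterministic. Prespecified, clinically motivated product
terms are then screened (`screen_interactions()`) by the same nested
comparison; a retained interaction forces its main effects into the
model (hierarchy principle). The graph is read off the selected models
(`build_chain_graph()`): a directed edge for every retained term with
p below `edge_alpha` (default 0.10, deliberately looser than the
selection threshold so moderate associations remain visible), dashed
interaction edges for product terms, and undirected edges among
rightmost-box variables from marginal association tests (correlation t,
one-way F, or chi-square, depending on types). A missing edge states
that the pair is conditionally independent given the selected
explanatory sets. Because outcomes are interpreted singly, and each
displayed association is of standalone interest, no multiplicity
adjustment is applied across models.

Treatment arm is not itself modelled by default: under randomisation its
independence of the intrinsic box holds by design, and a regression of
arm on age, sex and genotype would only resample that known null.

### Log-ratio outcomes and path predictions

Outcome changes are analysed on the log scale, where the 12-month change
equals the ratio final/baseline (0 on the log scale means no change) and
residuals are closer to symmetric. `predict_outcome_ratio()` evaluates a
selected model's linear predictor at a query point and exponentiates,
returning the predicted ratio and percent change — e.g. fixing mean
weight and saturated-fat changes while sweeping the GPS between its
quartiles. Unsupplied covariates sit at "no change" (change scores), the
sample mean (centred intrinsic covariates), or the reference level.

### Mean-centring of intrinsic covariates

The ordering declares the GPS and age for mean-centring
(`chain_ordering(center = ...)`). These covariates have no natural zero:
if an interaction such as GPS × weight change is retained, an uncentred
parameterisation turns the weight-change main effect into "the slope at
GPS = 0", a point far outside any cohort, and its p-value becomes
meaningless. Centring keeps main effects interpretable as slopes at
covariate means, leaves all slopes and nested-comparison tests
unchanged, and is undone transparently in prediction queries. Change
scores are *not* centred: their zero ("no change") is the natural
reference for treatment-contrast terms.

## Genotype quality control and the predisposition score

The genotyping module mirrors standard panel practice: SNPs with call
rate below 0.95 are excluded; individuals with 3 or more failed
genotypes are excluded; Hardy-Weinberg equilibrium is tested per SNP
with the likelihood-ratio (G) statistic
$2\sum O \ln(O/E)$ on 1 df, with expectations at the maximum-likelihood
allele frequency, against a Bonferroni-corrected cutoff (0.05/25 =
0.002 for a 25-SNP panel). The HWE scan flags, it does not auto-exclude:
monomorphic SNPs are degenerate (statistic 0) and reported, and
exclusion decisions stay with the analyst. Linkage disequilibrium
between same-locus SNPs uses the composite estimator — squared Pearson
correlation of allele counts — because genotype data carry no haplotype
phase. All four thresholds (call rate, individual failures, HWE alpha,
test count) are configuration values.

The GPS is the unweighted sum of risk-allele counts, coded 0/1/2 per
SNP with the risk allele defined by the panel file; unweighted scores
track weighted versions closely in practice while staying interpretable
as an allele count. Sporadic missing genotypes are mean-imputed from the
analysis set so each person is scored over the same panel; imputation
preserves each SNP's observed mean exactly, and a per-SNP weight column
is accepted for users who want a weighted score. File readers orient
PLINK-style dosages and VCF genotypes to the panel's risk allele and
refuse strand-ambiguous (A/T, C/G) SNPs outright rather than guess.

## Trait derivation

HOMA indices use the closed forms HOMA-IR $= G \cdot I/22.5$ and
HOMA-B $= 20 I/(G-3.5)$ % (glucose in mmol/L, insulin in uU/mL; pmol/L
input divided by 6). The computer-model HOMA2 variant has no published
closed form, so the module exposes multiplicative calibration factors
(default 1) that users with paired HOMA2 output can set; this is a
documented deviation, not an approximation claim. HOMA-B is undefined
at glucose ≤ 3.5 mmol/L and returns `NA` with the record retained.
Saturated fat is expressed as percent of energy using a fat energy
density of 37 kJ/g (9 kcal/g; kcal input accepted with an explicit unit
flag), NSP is 0.75 × AOAC fibre, pedometer weeks are averaged over
non-missing days with at least 4 of 7 required (full weeks are the
ideal; real diaries have gaps), and HbA1c travels in mmol/mol with an
IFCC/NGSP linear converter for ingestion of percent-denominated data.
Weight change is month-12 minus baseline, so negative means loss. All
change scores and log ratios are complete-case: no derived value is
produced when either timepoint is missing.

## The synthetic-cohort generator

`generate_cohort()` simulates the data-generating process the analysis
assumes, in causal order: genotypes under Hardy-Weinberg equilibrium
(independent SNPs, risk-allele frequencies drawn once per configuration
uniformly in \[0.2, 0.8\], missingness completely at random at 1%);
demographics (age 49.3 ± 12.6 years, 86.8% female, three equal country
strata); baseline traits with per-allele genetic effects (+0.04 mmol/L
glucose, +0.21 mmol/mol HbA1c, −1.30 % HOMA-B per risk allele) and
marginal moments matching a typical overweight cohort (glucose
4.98 ± 0.57 mmol/L, HbA1c 37.8 ± 4.1 mmol/mol, HOMA-B 99 ± 35 %,
weight 87 ± 13 kg); a 50/50 randomised arm; and then the structural
chain: the intervention lowers dietary saturated fat (−1.13 percentage
points, with sex and country shifts), activity change has no parents,
weight change responds to arm (−3.53 kg), diet (0.20 kg per point) and
activity (−0.18 kg per 1000 steps), and each outcome log-ratio is a
linear function of its planted parents — including weight × diet and
arm × weight / arm × diet product terms — plus Gaussian noise on the
log scale. Outcome-equation coefficients have no published point
values; the defaults are chosen so each outcome model's true variance
explained lands in a realistic 7–18% band, and the GPS slope for
HOMA-IR (−0.0225 per allele) reproduces a 7% vs 15% reduction between
GPS quartiles of 20 and 24. Residual SDs and every coefficient live in
the configuration and are recorded, with the noise draws themselves, in
a `synthetic_truth` object, so each generated value decomposes exactly
into parent contributions plus recorded noise, and `true_graph()` gives
the generating edge set for recovery scoring.

Raw 12-month measurement columns are back-calculated so the emitted
phenotype CSV round-trips through `derive_changes()`: glucose and HbA1c
from their log-ratios, insulin from the glucose and HOMA-IR ratios
jointly. One consequence is structural: HOMA-IR and HOMA-B are both
functions of the same two measurements, so their changes cannot be
specified independently in one raw file; the structurally generated
HOMA-B column in the analysis table is the ground truth for that
outcome, and the raw file's implied HOMA-B change differs. Baseline
diet and steps are lifted, never the change scores, when a 12-month
value would otherwise go non-positive.

What the generator does *not* emulate: linkage disequilibrium and
population structure, informative missingness or differential dropout
(retention is completely at random), assay batch effects, diet-diary
under-reporting, and anything beyond two timepoints. Passing recovery
tests therefore demonstrate that the estimator recovers the model it
assumes at realistic effect sizes — not robustness to those
violations on real data.

## Validation design and problem sizes

Three layers of tests validate the engine:

- **Oracle equivalence.** Coefficients, standard errors and partial-F
  p-values are compared with a brute-force normal-equations and explicit
  RSS-ratio oracle on 100 random small instances (agreement to 1e-8),
  and the HWE statistic with a grid-search maximum-likelihood oracle on
  50 random genotype-count triples (1e-6).
- **Structure recovery.** 200 synthetic cohorts of n = 2000 at the
  default effect sizes: every planted edge must be recovered in at least
  90% of replicates and the spurious-edge rate must stay below twice the
  display threshold. These sizes keep a full run in a few minutes on one
  core while leaving per-edge recovery estimates with standard errors
  near 1.5 percentage points.
- **Parameter recovery.** The planted weight-model coefficients must lie
  inside the fitted ±2 SE interval in at least 90% of replicates.
  Coverage is evaluated on the *full* (pre-selection) weight model: a
  coefficient's confidence interval is only calibrated before the data
  have voted on which terms survive, so mixing selection into the
  coverage check would conflate two properties. Structure metrics, by
  contrast, use the post-selection graph — selection is exactly what is
  being scored there. Recovery tests always compare against the planted
  values, never against coefficients estimated on any real cohort,
  which carry their own sampling error.

## Numerical choices and degenerate inputs

- Partial F with a zero full-model RSS (exact fit) is defined as 0 when
  the reduced model also fits exactly and infinite otherwise.
- Monomorphic SNPs: HWE statistic 0, p 1, `degenerate` flag; constant
  genotype vectors make LD undefined and error.
- Elimination ties (identical p-values to 1e-12) fall back to the
  smaller |t|, then lexicographic term name.
- Rank-deficient designs error immediately, naming the aliased columns.
- All TSV/DOT/JSON writers format numbers explicitly (`%.15g`), so
  identical inputs give byte-identical artefacts.
- Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; regeneration from a stored configuration is
  bit-identical.

## Known limitations

- Backward elimination is one defensible search among several; the
  selection criterion and thresholds are configuration, not claims of
  optimality, and the selected graph inherits all the usual caveats of
  data-driven model selection.
- Symmetric associations in the intrinsic box are tested marginally,
  not conditionally on the other box members.
- The closed-form HOMA indices are systematically larger than HOMA2
  computer-model output (roughly twofold for HOMA-IR at typical
  values); the calibration hook rescales levels but not the model's
  nonlinearity.
- The exclusion-cascade fixture reproduces printed marginal counts by
  construction; overlap between late filters in the original cohort is
  unknowable from marginals alone.
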
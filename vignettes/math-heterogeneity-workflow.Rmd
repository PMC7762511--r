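---
title: "Quantifying intra-tumoral heterogeneity with MATH and relating it to survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra-tumoral heterogeneity with MATH and relating it to survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mathsurv)
```

## The problem and the statistic

A tumor is rarely one clone. Subclonal populations carry different somatic
mutations, and that genetic diversity — intra-tumoral heterogeneity (ITH) —
shapes how the tumor responds to therapy: a heterogeneous tumor is more
likely to harbor a resistant subclone. MATH (mutant-allele tumor
heterogeneity) is a deliberately simple summary of ITH that needs nothing
beyond the variant allele fractions (VAFs) already produced by exome
sequencing. For one tumor with VAFs $x_1, \dots, x_n$,

$$\mathrm{MATH} = 100 \times \frac{1.4826 \cdot
\mathrm{median}(|x_i - \mathrm{median}(x)|)}{\mathrm{median}(x)}.$$

The numerator is the median absolute deviation scaled by 1.4826 so that its
expectation under a normal sample equals the standard deviation; the ratio
is a robust coefficient of variation of the mutant-allele fractions. A
clonally pure tumor concentrates its VAFs near purity/2 and scores low;
subclones spread the VAF distribution and push MATH up. The score is
invariant to rescaling of the VAF vector and to the order of variants, and
`math_score()` is checked against a brute-force sorting-based oracle.

This package implements the full analysis built around that statistic:
MAF input handling, MATH scoring, tertile stratification of a cohort,
survival analysis (Kaplan–Meier, k-group log-rank, Cox proportional
hazards), gene-set enrichment between heterogeneity groups, single-sample
immune-cell scoring, and somatic-mutation summaries — plus a synthetic
cohort generator so every stage is testable with known ground truth.
The numbered scripts under `analysis/` run these stages as a narrative
workflow; `run_all()` executes the same flow as one reproducible, manifest
hashed bundle. Those scripts and the exported functions are the interface;
there is no separate shell CLI.

## Variant filtering ahead of MATH

Two filters sit between a MAF file and the MATH input, both configurable:

* **Classification include-list** (`include`, default all classifications
  with read counts). MATH operates on mutant-allele fractions regardless of
  coding consequence, and the source analyses state no restriction, so the
  default keeps everything; passing
  `include = nonsilent_classes` restricts to protein-altering calls.
  Both modes are supported; neither is asserted as "the" convention.
* **Upper VAF trim** (`vaf_max`, default 0.75). Allele fractions far above
  0.5 usually reflect copy-number gain or loss of heterozygosity rather
  than clonal structure, and they inflate the MAD. The 0.75 cutoff damps
  those alleles while leaving high-purity clonal peaks intact. Established
  MATH tooling applies a clustering-based outlier control whose algorithm
  is unspecified; we deliberately do not guess at it — the trim is the sole
  outlier control here, and it is a documented, adjustable choice.

`math_score()` never silently drops a sample: fewer than `min_variants`
VAFs (default 5 — the MAD of fewer points is too unstable to rank tumors
by) yields `qc_flag = "too_few_variants"`, a zero median yields
`"zero_median"`, and only `"ok"` rows enter stratification. Medians use the
mean-of-central-pair convention for even lengths.

## Tertile stratification

Cohorts are split into low / intermediate / high MATH thirds by rank:
samples are sorted ascending (ties broken by sample id so results are
platform-independent), with cuts at $\lfloor n/3 \rfloor$ and
$\lfloor 2n/3 \rfloor$. When $n \bmod 3 \neq 0$ the extra sample(s) fall in
the *high* group; this convention reproduces a 385-patient cohort splitting
as 128/128/129. The chemotherapy subset is stratified twice in the
workflow: once as part of the full cohort and once with its own re-derived
tertiles, because a subset's tertile boundaries are not the full cohort's.

The baseline table reports each characteristic level as `count(percent)`
with percentages rounded half-up to one decimal, a univariate k-group
log-rank p across the levels (records with a missing level are counted in
the table but excluded from the test), and a one-way ANOVA F-test across
MATH groups for continuous covariates.

## Survival models

`km_estimate()`, `logrank_test()` and `cox_fit()` are implemented directly
on their defining quantities; `survival::survfit/survdiff/coxph` serve as
independent cross-checks in the test suite, never as the implementation.

The Cox model is maximized by Newton–Raphson on the partial likelihood with
step-halving, convergence when the largest score component falls below
1e-8 (cap 50 iterations), standard errors from the inverse observed
information, normal-approximation 95% intervals
$\exp(\beta \pm 1.96\,\mathrm{SE})$ and Wald p-values. Tied event times use
the Efron correction by default — it is the more accurate of the two
standard corrections — with Breslow available because some common software
defaults to it; both paths are tested against `coxph`. Diverging
coefficients (monotone likelihood from perfect separation) and
non-convergence are flagged in the returned object rather than silently
reported. Covariates are centered internally and the linear predictor is
shifted by its maximum before exponentiation, so large coefficients do not
overflow.

MATH enters multivariate models as a single ordinal covariate
(low/intermediate/high coded 0/1/2): published analyses of this design
report one hazard ratio for "MATH", which implies a per-step trend coding
rather than two dummies. Clinical covariates are likewise coded ordinally
(stage I–IV as 1–4, grade G1–G3 as 1–3 with Gx unranked, binary codes for
age group, sex, radiation) and rows with any missing model covariate are
dropped listwise.

## Gene-set enrichment

`gsea_significance()` is a two-phenotype GSEA with phenotype-label
permutation:

* **Ranking metric**: signal-to-noise $(\mu_A-\mu_B)/(\sigma_A+\sigma_B)$
  with each class SD floored at $0.2\,|\mu|$ (0.2 when $\mu = 0$) — the
  two-class default of the reference GSEA tool, chosen because the source
  analyses name the tool but not the metric. Ties break by gene symbol.
* **Enrichment score**: weighted Kolmogorov–Smirnov running sum (hits add
  $|m|^p$ normalized over the set, default $p = 1$; misses subtract
  $1/(N-N_{hit})$); the ES is the extremum of the running sum, which starts
  and ends at zero. $p = 0$ reduces to the classical KS statistic, and the
  test suite verifies that equivalence against a direct evaluation.
* **Null and calibration**: label permutations (default `n_perm = 1000`,
  seeded; requests beyond the number of distinct assignments are enumerated
  exhaustively with a warning). NES divides the observed ES by the mean
  |null ES| of matching sign; nominal p uses the $(b+1)/(B+1)$ convention
  over same-sign nulls so it is never exactly zero; FDR q is the standard
  positive/negative null-pool ratio.
* **Significance rule**: nominal p < 0.05, $|\mathrm{NES}| \ge 1$ and
  q < 0.25. The magnitude reading of the NES threshold is an interpretation
  (the rule is ambiguous for negative scores); direction is reported
  separately as which phenotype the set is enriched in.

## Immune-cell scoring

`ssgsea_matrix()` scores each sample against 28 immune cell-type sets with
a single-sample rank statistic: genes are ranked descending within the
sample and the score is the summed gap between the weighted in-set rank
ECDF (weight $r^\alpha$ on the descending rank, default $\alpha = 0.25$)
and the out-of-set ECDF. The engine is deliberately ssGSEA-style rank
arithmetic rather than full GSVA kernel-CDF machinery: the downstream
group tests are rank-based Mann–Whitney comparisons, which are insensitive
to the choice, and the simpler statistic has an exact closed form that is
testable against hand evaluation (monotone-transform invariance and
complement antisymmetry at $\alpha = 0$ are asserted properties).

The packaged GMT (`immune_cell_sets()`) carries the 28 cell-type *names*
with **synthetic placeholder memberships** — the published 28-signature
gene lists are not reproduced here — so real analyses should supply their
own signature GMT. Group differences therefore validate on synthetic data
only, which is exactly what the generator's planted shifts provide.

Mann–Whitney comparisons report a z from the tie-corrected normal
approximation (continuity correction off by default; it is immaterial at
cohort sizes where z is the readout) while the two-sided p is computed
exactly from the null U distribution whenever the samples are untied and
small (`max(n1, n2) <= 25`), the same policy as `wilcox.test`. The exact
branch exists because at very small n the normal approximation can miss the
enumerated p by far more than any reasonable tolerance (up to ~0.24 plain
and ~0.09 with continuity correction at $n_1, n_2 \le 7$); exactness there
costs nothing and removes the discrepancy entirely. Raw p-values are the
primary readout (mirroring how such tables are published); Benjamini–
Hochberg adjustment is available by flag.

## Mutation summaries

Fisher's exact test computes the two-sided p by the probability-mass
method — summing hypergeometric probabilities of all same-margin tables no
more probable than the observed one — matching the classical test, and is
verified against full enumeration for every table with total up to 20. The
displayed odds ratio is the sample OR with a 0.5 cell correction when any
cell is zero (display only). The gene-by-sample matrix counts a gene once
per sample and qualifies non-silent classifications by default
(configurable); the co-occurrence scan tests all pairs among the top 25
most frequently mutated genes and calls co-occurrence/exclusivity at
p < 0.05 with OR above/below 1.

## The synthetic cohort generator

`synthetic_config()` defaults define the study conditions the pipeline
emulates, and they are fixed, not tuning knobs:

| parameter | default | what it emulates |
|---|---|---|
| `n_samples` | 385 | surgically treated cohort size |
| `chemo_fraction` | 0.444 | 171/385 with adjuvant-chemotherapy data |
| `variant_mean`, `variant_size` | 63, 10 | negative-binomial somatic load, median ~63 |
| `depth_mean` | 150 | Poisson exome coverage |
| `purity_range` | 0.4–0.9 | uniform tumor purity |
| `subclone_range`, `theta` | 1–3, 0.1 | subclone count; CCF spread `1 - Exp(mean θ)` truncated to [0.05, 1] |
| `clonal_fraction` | 0.6 | share of clonal variants |
| `weibull_shape`, `weibull_scale` | 1.2, 36 | baseline event times (months) |
| `group_hr` | 1.433 | hazard ratio per MATH-tertile step (the full-cohort adjusted estimate of the motivating study) |
| `censoring` | 0.5 | target censored fraction, calibrated by root-finding on a uniform censoring scale |
| `n_genes`, `delta` | 1000, 1 | expression matrix size; planted shift in pooled SDs |
| `shifted_sets` | 20 of 28 cell types | sets raised in the low/intermediate group |

True VAF is `purity × CCF / 2` — diploid heterozygous variants with no
copy-number simulation, so MATH's ground truth is not confounded.
Read-level noise is Binomial(depth, true VAF) with zero-depth draws redrawn
and counted. Censoring is independent of covariates to keep Cox recovery
assumptions clean. All randomness flows from the single mandatory seed
through per-component sub-streams, so each `simulate_*` call is
independently reproducible and a rerun of `run_all()` with the same seed is
byte-identical (asserted via MD5 in the manifest).

What the generator does *not* emulate — and hence what passing tests do not
show about real data: trinucleotide mutational signatures, copy-number/LOH
distortion of allele fractions, germline contamination, correlated
gene–gene expression structure, covariate-dependent censoring, and real
immune-signature gene memberships. A rank-compensation effect is visible
and expected in the synthetic expression: planting shifts in 300 of 1000
genes depresses the relative ranks of everything else, so unshifted sets
can drift significant in the opposite direction in both GSEA and the
single-sample scores — calibration tests therefore use a fully null
configuration.

One generator property worth recording: with `theta = 0` and purity 1
(clonal variants only), noise-only MATH at 150× depth and ~63 variants
sits near 8 with roughly a one-point spread across samples, so ~92% — not
all — of samples fall below 10. The regression test asserts that
simulation-derived fraction, not a wished-for one.

## Problem sizes in the tests

The suite exercises the stochastic claims at sizes chosen to balance power
against a single-CPU run: hazard-ratio recovery uses 100 replicates of
n = 400; log-rank null calibration 200 replicates of n = 150; GSEA null and
power 50 runs each at 40 samples × 500 genes with 500 permutations; immune
detection 50 runs at the 171-sample design; Fisher enumeration covers all
~10,600 tables with total ≤ 20. `scripts/acceptance.R` recomputes the same
quantities at reduced replicate counts and writes them as JSON.

## Known limitations

* MATH has no purity/ploidy correction and no subclone reconstruction;
  it is a dispersion summary, not a clonal-architecture estimate.
* The unspecified clustering step of other MATH implementations is not
  reproduced, so scores can differ from tools that apply it.
* Cox fits assume proportional hazards; no diagnostics, time-varying
  effects, stratification or frailty terms are provided.
* The packaged immune GMT is a synthetic scaffold; published z-values for
  real cohorts are not reproducible from it by design.
* GSEA offers phenotype permutation only (no gene-permutation mode) and no
  leading-edge export.
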
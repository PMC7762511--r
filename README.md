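# mathsurv

Tumors are mosaics of subclones, and that intra-tumoral heterogeneity (ITH)
predicts how patients fare under surgery and chemotherapy: a genetically
diverse tumor is more likely to hide a treatment-resistant subclone.
`mathsurv` is an R implementation of the MATH-based prognosis workflow for
cancer cohorts — aimed at biostatisticians and cancer genomics analysts who
have somatic mutation calls (MAF), clinical follow-up, and optionally
RNA-seq for a cohort, and want a tested, reproducible path from variant
allele fractions to survival and immune characterization.

## The statistic at the core

MATH (mutant-allele tumor heterogeneity) summarizes the dispersion of a
tumor's variant allele fractions x₁…xₙ:

    MATH = 100 × 1.4826 · median(|xᵢ − median(x)|) / median(x)

i.e. a robust coefficient of variation of the VAF distribution: scaled
median absolute deviation over median. Homogeneous (clonal) tumors score
low; subclonal structure spreads the VAFs and raises the score. Around it
the package implements:

- **MAF/GMT IO and VAF profiles** — `read_maf()`, `vaf_profiles()`
  (classification filter + configurable VAF trim at 0.75), `read_gmt()`.
- **MATH scoring and stratification** — `math_score()`, `cohort_math()`,
  rank-based tertiles via `assign_tertiles()` (extras to the high group:
  385 → 128/128/129), `baseline_table()` with log-rank / ANOVA univariate
  tests.
- **Survival** — `km_estimate()`, k-group `logrank_test()`, and `cox_fit()`
  by Newton–Raphson on the partial likelihood (Efron/Breslow ties, Wald
  CIs, separation flagged), with MATH as an ordinal 0/1/2 covariate in
  multivariate models.
- **Enrichment** — two-phenotype GSEA (`gsea_significance()`):
  signal-to-noise ranking, weighted-KS enrichment score, seeded phenotype
  permutations, NES, FDR q, and the p < 0.05 & |NES| ≥ 1 & q < 0.25 rule.
- **Immune scoring** — single-sample (ssGSEA-style) scores for 28 immune
  cell types (`ssgsea_matrix()`), Mann–Whitney group comparison
  (`immune_diff_table()`), per-cell-type Cox (`per_celltype_cox()`).
- **Mutation summaries** — `summarize_maf()`, exact 2×2 Fisher tests, and a
  pairwise co-occurrence / mutual-exclusivity scan.
- **Synthetic cohorts** — `simulate_cohort()` generates MAF, clinical and
  expression data with recorded ground truth (subclone CCFs, true hazard
  ratios, planted expression shifts) so the entire pipeline is testable
  offline.

The numbered scripts under `analysis/` run the workflow end to end on a
generated cohort; `run_all()` does the same as a single call and writes a
manifest with MD5 hashes so reruns can be verified byte-for-byte.

Note: the packaged immune GMT ships the 28 cell-type names with *synthetic*
gene memberships (the published signature gene lists are not bundled);
supply your own signature GMT for real analyses.

## Worked example

```r
library(mathsurv)

cfg    <- synthetic_config(seed = 42, n_samples = 171, chemo_fraction = 1)
cohort <- simulate_cohort(cfg)

smry <- attr(cohort$math_table, "summary")
sprintf("MATH median %.1f (range %.1f-%.1f), tertiles %s",
        smry$median, smry$range[1], smry$range[2],
        paste(attr(cohort$math_table, "group_sizes"), collapse = "/"))
#> "MATH median 13.2 (range 6.2-33.6), tertiles 57/57/57"

cc <- merge(cohort$clinical,
            cohort$math_table[, c("sample_id", "math_group")],
            by = "sample_id")
lr <- logrank_test(cc$os_time, cc$os_event, cc$math_group)
sprintf("log-rank chi2 = %.2f (df %d), p = %.4f",
        lr$chi_square, lr$df, lr$p_value)
#> "log-rank chi2 = 6.23 (df 2), p = 0.0444"

fit <- cox_fit(cc$os_time, cc$os_event, encode_clinical(cc))
fit$table[fit$table$term == "MATH", ]
#>  term  beta    se   hr ci_lower ci_upper     p
#>  MATH 0.392 0.377 1.48    0.707      3.1 0.298
```

The log-rank test sees the planted per-tertile hazard step (p = 0.044 at
n = 171); the adjusted Cox hazard ratio per MATH-group step is 1.48 — near
the generator's true 1.433, with a wide interval because 171 patients at
~50% censoring carry limited information. The immune comparison on the same
cohort flags all 20 planted cell-type shifts (and, through rank
compensation, the unshifted types in the opposite direction):

```r
scores <- ssgsea_matrix(cohort$expression, immune_cell_sets())
diff <- immune_diff_table(scores,
          as.character(cc$math_group[match(colnames(scores), cc$sample_id)]))
attr(diff, "n_significant")
#> [1] 28
```

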
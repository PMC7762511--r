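#!/usr/bin/env Rscript
# Survival analysis: Kaplan-Meier curves per MATH tertile, the 3-group
# log-rank test, and the multivariate Cox model with MATH as an ordinal
# covariate adjusted for age, sex, stage, grade, radiation and histology --
# on the full cohort and on the adjuvant-chemotherapy subset with its own
# re-derived tertiles.

library(mathsurv)

tab_dir <- "results/tables"
cohort <- read.delim(file.path(tab_dir, "cohort.tsv"))
cohort$math_group <- factor(cohort$math_group,
                            levels = c("low", "intermediate", "high"))

analyse <- function(cc, tag) {
  cc <- cc[!is.na(cc$math_group), ]
  km <- do.call(rbind, lapply(levels(cc$math_group), function(g) {
    cv <- km_estimate(cc$os_time[cc$math_group == g],
                      cc$os_event[cc$math_group == g])
    if (nrow(cv)) cbind(group = g, cv) else NULL
  }))
  write.table(km, file.path(tab_dir, paste0("km_", tag, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  lr <- logrank_test(cc$os_time, cc$os_event, cc$math_group)
  fit <- cox_fit(cc$os_time, cc$os_event, encode_clinical(cc))
  write.table(fit$table, file.path(tab_dir, paste0("cox_", tag, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  m <- fit$table[fit$table$term == "MATH", ]
  cat(sprintf("[%s, n=%d] log-rank chi2=%.2f (df %d, p=%.3f); adjusted MATH HR %.3f (%.3f-%.3f), p=%.3f\n",
              tag, nrow(cc), lr$chi_square, lr$df, lr$p_value,
              m$hr, m$ci_lower, m$ci_upper, m$p))
}

analyse(cohort, "full")

chemo_ids <- cohort$sample_id[cohort$adjuvant_chemo == 1]
mt <- cohort[cohort$sample_id %in% chemo_ids,
             c("sample_id", "math", "qc_flag")]
mt <- assign_tertiles(mt)   # the chemotherapy subset gets its own tertiles
chemo <- merge(cohort[, setdiff(names(cohort), "math_group")],
               mt[, c("sample_id", "math_group")], by = "sample_id")
write.table(chemo, file.path(tab_dir, "cohort_chemo.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
analyse(chemo, "chemo")
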
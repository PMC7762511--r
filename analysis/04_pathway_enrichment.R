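#!/usr/bin/env Rscript
# GSEA between the high and low/intermediate MATH groups of the
# chemotherapy subset: signal-to-noise gene ranking, weighted KS enrichment
# scores, a 1000-permutation phenotype null, and the significance rule
# nominal p < 0.05 & |NES| >= 1 & FDR q < 0.25.

library(mathsurv)

SEED <- 17
tab_dir <- "results/tables"
expr <- read.delim("results/data/expression.tsv", check.names = FALSE)
X <- as.matrix(expr[, -1]); rownames(X) <- expr$gene
chemo <- read.delim(file.path(tab_dir, "cohort_chemo.tsv"))
chemo <- chemo[!is.na(chemo$math_group), ]

ids <- intersect(colnames(X), chemo$sample_id)
ph <- factor(ifelse(chemo$math_group[match(ids, chemo$sample_id)] == "high",
                    "high", "low_intermediate"),
             levels = c("low_intermediate", "high"))

sets <- immune_cell_sets()
res <- gsea_significance(X[, ids], ph, sets, n_perm = 1000, seed = SEED + 7)
res <- res[order(res$nominal_p, -abs(res$nes)), ]
write.table(res, file.path(tab_dir, "gsea_results.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sig <- res[res$significant, ]
cat(sprintf("GSEA on %d samples (%d high vs %d low/intermediate): %d of %d sets significant.\n",
            length(ids), sum(ph == "high"), sum(ph != "high"),
            nrow(sig), nrow(res)))
up_lo <- sig$set[sig$direction == "up_in_A"]
cat(sprintf("Up in low/intermediate (%d): %s\n", length(up_lo),
            paste(head(up_lo, 8), collapse = ", ")))
cat(sprintf("Up in high: %d sets.\n",
            sum(sig$direction == "up_in_B")))
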
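#!/usr/bin/env Rscript
# Immune-cell infiltration: single-sample enrichment scores for the 28
# packaged cell-type sets, Mann-Whitney comparison of the high vs
# low/intermediate MATH groups, and per-cell-type Cox association with OS.

library(mathsurv)

tab_dir <- "results/tables"
expr <- read.delim("results/data/expression.tsv", check.names = FALSE)
X <- as.matrix(expr[, -1]); rownames(X) <- expr$gene
chemo <- read.delim(file.path(tab_dir, "cohort_chemo.tsv"))
chemo <- chemo[!is.na(chemo$math_group), ]
ids <- intersect(colnames(X), chemo$sample_id)

sets <- immune_cell_sets()
scores <- ssgsea_matrix(X[, ids], sets, alpha = 0.25)
write.table(data.frame(cell_type = rownames(scores), scores,
                       check.names = FALSE),
            file.path(tab_dir, "immune_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

grp <- as.character(chemo$math_group[match(ids, chemo$sample_id)])
diff <- immune_diff_table(scores, grp)
write.table(diff, file.path(tab_dir, "immune_diff.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
n_sig <- attr(diff, "n_significant")
n_lo <- sum(diff$p_value < 0.05 &
              diff$direction == "higher_in_low_intermediate")
cat(sprintf("%d of %d cell types differ at p < 0.05; %d are higher in the low/intermediate group.\n",
            n_sig, nrow(diff), n_lo))

icox <- per_celltype_cox(scores, chemo[match(ids, chemo$sample_id), ])
write.table(icox, file.path(tab_dir, "immune_cox.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
assoc <- icox$cell_type[!is.na(icox$p) & icox$p < 0.05]
cat(sprintf("Cell types with OS-associated scores (univariate Cox, p < 0.05): %d\n",
            length(assoc)))
if (length(assoc)) cat(" ", paste(head(assoc, 10), collapse = ", "), "\n")
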
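#!/usr/bin/env Rscript
# Somatic-mutation summary for the chemotherapy subset: classification
# counts, per-sample variant load, top recurrently mutated genes, and the
# pairwise Fisher co-occurrence / mutual-exclusivity scan.

library(mathsurv)

tab_dir <- "results/tables"
maf <- read_maf("results/data/cohort.maf")
chemo <- read.delim(file.path(tab_dir, "cohort_chemo.tsv"))
maf <- maf[maf$sample_id %in% chemo$sample_id, ]
class(maf) <- c("maf_table", "data.frame")

s <- summarize_maf(maf)
write.table(data.frame(classification = names(s$classification_counts),
                       n = s$classification_counts),
            file.path(tab_dir, "classification_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(s$gene_ranking, file.path(tab_dir, "gene_ranking.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d samples, %d variants; most prevalent class: %s (%d); median load %d.\n",
            length(unique(maf$sample_id)), nrow(maf),
            names(s$classification_counts)[1], s$classification_counts[1],
            s$median_load))
cat("Top mutated genes:", paste(s$top_genes, collapse = ", "), "\n")

gm <- gene_sample_matrix(maf)
scan <- cooccurrence_scan(gm, top_k = 25, alpha = 0.05)
write.table(scan, file.path(tab_dir, "cooccurrence.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Pairwise Fisher scan over top 25 genes: %d co-occurring, %d exclusive of %d pairs.\n",
            sum(scan$call == "co_occurring"), sum(scan$call == "exclusive"),
            nrow(scan)))
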
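#' Non-silent variant classifications (default qualifying set)
#'
#' The classifications that mark a gene as mutated in the gene-by-sample
#' matrix unless the caller overrides them.
#' @export
nonsilent_classes <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Splice_Site", "Translation_Start_Site"
)

#' Cohort-level somatic-mutation summary
#'
#' Counts variants per classification, tallies the per-sample variant load
#' (with its cohort median), and ranks genes by the number of distinct
#' mutated samples (a gene hit twice in one sample counts that sample once;
#' ties break alphabetically).
#'
#' @param maf a `maf_table`.
#' @param top_k how many top genes to report (default 10).
#' @return list: `classification_counts` (named, descending),
#'   `sample_load` (data.frame `sample_id`, `n_variants`), `median_load`,
#'   `gene_ranking` (data.frame `gene`, `n_samples`), `top_genes`.
#' @export
summarize_maf <- function(maf, top_k = 10) {
  if (nrow(maf) == 0L) stop("empty MAF table")
  cls <- table(maf$variant_classification)
  cls <- cls[order(-cls, names(cls))]
  load <- as.data.frame(table(factor(maf$sample_id,
                                     levels = unique(maf$sample_id))),
                        stringsAsFactors = FALSE)
  names(load) <- c("sample_id", "n_variants")
  pairs <- unique(maf[, c("gene", "sample_id")])
  gr <- table(pairs$gene)
  gr <- gr[order(-gr, names(gr))]
  ranking <- data.frame(gene = names(gr), n_samples = as.integer(gr),
                        stringsAsFactors = FALSE)
  list(classification_counts = stats::setNames(as.integer(cls), names(cls)),
       sample_load = load,
       median_load = stats::median(load$n_variants),
       gene_ranking = ranking,
       top_genes = utils::head(ranking$gene, top_k))
}

#' Binary gene-by-sample mutation matrix
#'
#' @param maf a `maf_table`.
#' @param qualifying classifications that count as a mutation (default
#'   [nonsilent_classes]).
#' @return 0/1 integer matrix, genes x samples (all samples in the MAF are
#'   columns, even those with no qualifying variant).
#' @export
gene_sample_matrix <- function(maf, qualifying = nonsilent_classes) {
  samples <- unique(maf$sample_id)
  sub <- maf[maf$variant_classification %in% qualifying, , drop = FALSE]
  genes <- sort(unique(sub$gene))
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  if (nrow(sub)) {
    m[cbind(match(sub$gene, genes), match(sub$sample_id, samples))] <- 1L
  }
  m
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the probability-mass method: hypergeometric probabilities
#' of all tables with the observed margins that are no more probable than
#' the observed table are summed. The reported odds ratio is the sample OR
#' `ad/bc`, with 0.5 added to every cell when any cell is zero (display
#' only; the test itself is exact).
#'
#' @param a,b,c,d non-negative integer cell counts: `a` = both, `b` = first
#'   only, `c` = second only, `d` = neither.
#' @return list: `p_value`, `odds_ratio`, `table`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell count")
  if (sum(cells) == 0) stop("empty table")
  m <- a + b            # first row margin
  n <- c + d            # second row margin
  k <- a + c            # first column margin
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (any(cells == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(p_value = p, odds_ratio = or,
       table = matrix(cells, 2, 2, byrow = TRUE))
}

#' Pairwise co-occurrence / mutual-exclusivity scan
#'
#' Tests every pair among the `top_k` most frequently mutated genes with
#' Fisher's exact test on the 2x2 sample-count table. A pair is called
#' `co_occurring` when p < alpha with odds ratio > 1, `exclusive` when
#' p < alpha with odds ratio < 1, otherwise `ns`.
#'
#' @param matrix binary gene x sample matrix from [gene_sample_matrix()].
#' @param top_k number of top genes to scan (default 25).
#' @param alpha significance level (default 0.05).
#' @return data.frame: `gene_a`, `gene_b`, `both`, `a_only`, `b_only`,
#'   `neither`, `odds_ratio`, `p_value`, `call`.
#' @export
cooccurrence_scan <- function(matrix, top_k = 25, alpha = 0.05) {
  if (top_k < 2) stop("top_k must be at least 2")
  if (nrow(matrix) < 2L || ncol(matrix) < 2L) {
    stop("need at least 2 genes and 2 samples")
  }
  freq <- rowSums(matrix)
  top <- rownames(matrix)[order(-freq, rownames(matrix))]
  top <- utils::head(top, top_k)
  pairs <- utils::combn(top, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    ga <- pairs[1, i]; gb <- pairs[2, i]
    va <- matrix[ga, ] == 1L; vb <- matrix[gb, ] == 1L
    a <- sum(va & vb); b <- sum(va & !vb)
    c <- sum(!va & vb); d <- sum(!va & !vb)
    ft <- fisher_exact_2x2(a, b, c, d)
    call <- if (ft$p_value < alpha && ft$odds_ratio > 1) "co_occurring"
            else if (ft$p_value < alpha && ft$odds_ratio < 1) "exclusive"
            else "ns"
    data.frame(gene_a = ga, gene_b = gb, both = a, a_only = b, b_only = c,
               neither = d, odds_ratio = ft$odds_ratio,
               p_value = ft$p_value, call = call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
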
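#' Single-sample gene-set enrichment score (ssGSEA-style)
#'
#' Genes of one sample are ranked by descending expression (ties broken by
#' gene name). With in-set positions `pos_j` among N genes, the score is the
#' summed difference between the weighted in-set ECDF and the out-of-set
#' ECDF over all list positions,
#' `sum_i [P_in^w(i) - P_out(i)]`,
#' where in-set steps are weighted by `r^alpha` with `r = N - pos + 1` (the
#' descending-rank weight: the top gene carries weight `N^alpha`), normalized
#' over the set. `alpha = 0` gives the unweighted rank statistic. Being
#' rank-based, the score is invariant under strictly monotone transforms of
#' the expression column.
#'
#' @param expr_values named numeric vector: one sample's expression, names =
#'   gene symbols (>= 2 genes).
#' @param gene_set character vector; its intersection with the genes must be
#'   non-empty and a proper subset.
#' @param alpha rank-weighting exponent (default 0.25).
#' @return numeric score.
#' @export
ssgsea_score <- function(expr_values, gene_set, alpha = 0.25) {
  N <- length(expr_values)
  if (N < 2L) stop("need at least 2 genes")
  genes <- names(expr_values)
  if (is.null(genes)) stop("expression vector must be named by gene")
  inset <- genes %in% gene_set
  nh <- sum(inset)
  if (nh == 0L) stop("gene set has no genes in the expression vector")
  if (nh == N) stop("gene set covers all genes")
  ord <- order(-expr_values, genes)
  pos <- sort(which(inset[ord]))           # in-set positions, descending rank
  r <- N - pos + 1
  w <- r^alpha
  w <- w / sum(w)
  sum_pin <- sum(w * (N - pos + 1))        # sum over i of P_in^w(i)
  sum_pout <- (N * (N + 1) / 2 - sum(N - pos + 1)) / (N - nh)
  sum_pin - sum_pout
}

#' Score a gene-set collection across all samples
#'
#' @param expression genes x samples matrix (rownames = gene symbols).
#' @param sets a `gene_set_collection`, e.g. [immune_cell_sets()].
#' @param alpha passed to [ssgsea_score()].
#' @return `immune_scores` matrix, sets x samples, with attribute `alpha`.
#' @export
ssgsea_matrix <- function(expression, sets, alpha = 0.25) {
  if (length(sets) == 0L) stop("empty gene-set collection")
  out <- matrix(NA_real_, length(sets), ncol(expression),
                dimnames = list(names(sets), colnames(expression)))
  for (j in seq_len(ncol(expression))) {
    col <- expression[, j]
    names(col) <- rownames(expression)
    for (s in seq_along(sets)) {
      out[s, j] <- ssgsea_score(col, sets[[s]], alpha)
    }
  }
  structure(out, alpha = alpha, class = c("immune_scores", "matrix", "array"))
}

#' Mann-Whitney (Wilcoxon rank-sum) z test
#'
#' U statistic for `x` against `y`; `z` always comes from the normal
#' approximation with tie-corrected variance, `z = (U - n1 n2 / 2) / sd`
#' (with `continuity = TRUE` 0.5 is subtracted from `|U - mean|`). The
#' two-sided p-value is exact — summing the null U distribution over values
#' at least as extreme — whenever there are no ties and both samples are
#' small (`max(n1, n2) <= 25` under `exact = "auto"`); otherwise it falls
#' back to the normal approximation, which is what large cohort comparisons
#' use. When every value is tied across both samples `z = 0, p = 1`.
#'
#' @param x,y non-empty numeric vectors.
#' @param continuity apply the continuity correction to z (default FALSE).
#' @param exact `"auto"` (exact p when untied and small), `TRUE` (force,
#'   errors on ties) or `FALSE` (always normal approximation).
#' @return list: `u`, `z`, `p_value` (two-sided), `exact` (logical, how p
#'   was computed).
#' @export
mannwhitney_z <- function(x, y, continuity = FALSE, exact = "auto") {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) return(list(u = U, z = 0, p_value = 1, exact = FALSE))
  dev <- U - mu
  if (continuity) dev <- sign(dev) * max(abs(dev) - 0.5, 0)
  z <- dev / sqrt(v)
  use_exact <- if (isTRUE(exact)) {
    if (has_ties) stop("exact p-value not defined with ties")
    TRUE
  } else if (identical(exact, "auto")) {
    !has_ties && max(n1, n2) <= 25
  } else FALSE
  p <- if (use_exact) {
    u_all <- 0:(n1 * n2)
    pr <- stats::dwilcox(u_all, n1, n2)
    sum(pr[abs(u_all - mu) >= abs(U - mu) - 1e-9])
  } else {
    2 * stats::pnorm(-abs(z))
  }
  list(u = U, z = z, p_value = min(1, p), exact = use_exact)
}

#' Immune-cell group-difference table
#'
#' One Mann-Whitney test per cell type (row of the score matrix) comparing
#' the low/intermediate-MATH samples against the high-MATH samples.
#' Positive z means higher scores in the low/intermediate group (matching
#' the convention that infiltration is reported as enriched there). The
#' direction label follows the sign of the median score difference.
#'
#' @param scores sets x samples matrix from [ssgsea_matrix()].
#' @param groups vector over the columns with values `"high"` and
#'   `"low_intermediate"` (a 3-level MATH grouping is collapsed: low and
#'   intermediate together).
#' @param continuity passed to [mannwhitney_z()].
#' @param adjust p-adjustment method for the optional `q` column (default
#'   `"none"`: the raw per-cell-type p is the primary readout).
#' @return data.frame: `cell_type`, `z`, `p_value`, `direction` (+ `q` when
#'   adjusted); `attr(, "n_significant")` counts p < 0.05.
#' @export
immune_diff_table <- function(scores, groups, continuity = FALSE,
                              adjust = "none") {
  g <- as.character(groups)
  g[g %in% c("low", "intermediate")] <- "low_intermediate"
  if (!all(g %in% c("high", "low_intermediate"))) {
    stop("groups must be 'high' or 'low'/'intermediate'/'low_intermediate'")
  }
  hi <- g == "high"
  if (sum(hi) < 2L || sum(!hi) < 2L) stop("both groups need >= 2 samples")
  rows <- lapply(rownames(scores), function(ct) {
    lo_sc <- scores[ct, !hi]
    hi_sc <- scores[ct, hi]
    mw <- mannwhitney_z(lo_sc, hi_sc, continuity = continuity)
    md <- stats::median(lo_sc) - stats::median(hi_sc)
    dir <- if (md > 0) "higher_in_low_intermediate"
           else if (md < 0) "higher_in_high"
           else if (mw$z >= 0) "higher_in_low_intermediate" else "higher_in_high"
    data.frame(cell_type = ct, z = mw$z, p_value = mw$p_value,
               direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust != "none") out$q <- stats::p.adjust(out$p_value, method = adjust)
  rownames(out) <- NULL
  structure(out, n_significant = sum(out$p_value < 0.05))
}

#' Per-cell-type Cox association with overall survival
#'
#' Fits one proportional-hazards model per cell type on the standardized
#' enrichment score (optionally adjusted for extra covariates). Cell types
#' with a constant score are flagged and not fitted.
#'
#' @param scores sets x samples matrix from [ssgsea_matrix()].
#' @param clinical data.frame with `sample_id`, `os_time`, `os_event`
#'   matching the score columns.
#' @param covariates optional numeric matrix of adjustment covariates
#'   (rownames or order matching `clinical`).
#' @param adjust p-adjustment method for the `q` column (default `"none"`).
#' @param tie_method passed to [cox_fit()].
#' @return data.frame: `cell_type`, `hr`, `ci_lower`, `ci_upper`, `p`,
#'   `flag` (+ `q` when adjusted).
#' @export
per_celltype_cox <- function(scores, clinical, covariates = NULL,
                             adjust = "none", tie_method = "efron") {
  idx <- match(colnames(scores), clinical$sample_id)
  if (anyNA(idx)) stop("score columns missing from clinical table")
  cl <- clinical[idx, , drop = FALSE]
  rows <- lapply(rownames(scores), function(ct) {
    sc <- scores[ct, ]
    if (length(unique(sc)) == 1L) {
      return(data.frame(cell_type = ct, hr = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p = NA_real_,
                        flag = "constant_score", stringsAsFactors = FALSE))
    }
    z <- (sc - mean(sc)) / stats::sd(sc)
    X <- cbind(score = z)
    if (!is.null(covariates)) X <- cbind(X, covariates)
    fit <- cox_fit(cl$os_time, cl$os_event, X, tie_method = tie_method)
    r <- fit$table[fit$table$term == "score", ]
    data.frame(cell_type = ct, hr = r$hr, ci_lower = r$ci_lower,
               ci_upper = r$ci_upper, p = r$p, flag = fit$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust != "none") out$q <- stats::p.adjust(out$p, method = adjust)
  rownames(out) <- NULL
  out
}
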
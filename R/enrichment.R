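# signal-to-noise ranking metric with the GSEA standard-deviation floor:
# each class SD is floored at 0.2*|class mean| (0.2 absolute when mean = 0).
.snr_metric <- function(mA, mB, sA, sB) {
  fA <- pmax(sA, ifelse(mA == 0, 0.2, 0.2 * abs(mA)))
  fB <- pmax(sB, ifelse(mB == 0, 0.2, 0.2 * abs(mB)))
  (mA - mB) / (fA + fB)
}

#' Rank genes by a two-class signal-to-noise metric
#'
#' Metric per gene: `(mean_A - mean_B) / (sd_A + sd_B)` with each class SD
#' floored at `0.2 * |class mean|` (0.2 when the mean is zero), the
#' two-phenotype default of GSEA. Genes are ordered by descending metric;
#' ties break by gene symbol so the ranking is deterministic.
#'
#' @param expression numeric matrix, genes (rownames) x samples.
#' @param phenotype two-level factor/character over the columns; the first
#'   level is class A (positive metric = higher in A).
#' @return a `ranked_list` data.frame: `gene`, `metric`, in rank order.
#' @export
rank_genes <- function(expression, phenotype) {
  ph <- factor(phenotype)
  if (nlevels(ph) != 2L) stop("phenotype must have exactly 2 levels")
  if (any(table(ph) < 2L)) stop("each phenotype class needs >= 2 samples")
  if (ncol(expression) != length(ph)) stop("phenotype length != sample count")
  A <- ph == levels(ph)[1]
  mA <- rowMeans(expression[, A, drop = FALSE])
  mB <- rowMeans(expression[, !A, drop = FALSE])
  sA <- apply(expression[, A, drop = FALSE], 1, stats::sd)
  sB <- apply(expression[, !A, drop = FALSE], 1, stats::sd)
  metric <- .snr_metric(mA, mB, sA, sB)
  ord <- order(-metric, rownames(expression))
  structure(data.frame(gene = rownames(expression)[ord],
                       metric = metric[ord], stringsAsFactors = FALSE),
            classes = levels(ph), class = c("ranked_list", "data.frame"))
}

# ES from sorted hit positions: equivalent to the full running sum but O(hits).
# pos: sorted positions of set members in the ranked list; w: their weights.
.es_from_positions <- function(pos, w, N) {
  nh <- length(pos)
  W <- sum(w)
  if (W == 0) w <- rep(1, nh) else w <- w / sum(w)
  cw <- cumsum(if (W == 0) w / nh else w)
  miss <- 1 / (N - nh)
  at_hit <- cw - (pos - seq_len(nh)) * miss          # running sum at each hit
  before_hit <- c(0, cw[-nh]) - (pos - seq_len(nh)) * miss
  cand <- c(at_hit, before_hit)
  cand[which.max(abs(cand))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walking down the ranked list, set members ("hits") increment a running
#' sum by `|metric|^weight_p` normalized over the set's hits, non-members
#' decrement it by `1/(N - N_hit)`. The enrichment score is the running-sum
#' value of maximal absolute deviation from zero. `weight_p = 0` reduces to
#' the classical unweighted KS statistic.
#'
#' @param ranked a `ranked_list` from [rank_genes()].
#' @param gene_set character vector of gene symbols.
#' @param weight_p non-negative weighting exponent (default 1).
#' @return list: `es`, `running` (full running-sum profile), `hits`
#'   (logical over the ranked list).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  hit <- ranked$gene %in% gene_set
  N <- length(hit)
  nh <- sum(hit)
  if (nh == 0L) stop("gene set has no genes in the ranked list")
  if (nh == N) stop("gene set covers the whole ranked list")
  w <- abs(ranked$metric)^weight_p * hit
  W <- sum(w)
  inc <- if (W == 0) hit / nh else w / W
  running <- cumsum(inc - (!hit) / (N - nh))
  es <- running[which.max(abs(running))]
  list(es = es, running = running, hits = hit)
}

# signal-to-noise metric matrix for B permuted class assignments.
# Z: samples x B 0/1 indicator of class A membership. Returns genes x B.
.perm_metrics <- function(X, Z, nA, nB) {
  XP <- X %*% Z                 # genes x B sums over class A
  X2 <- X^2
  X2P <- X2 %*% Z
  totX <- rowSums(X)
  totX2 <- rowSums(X2)
  mA <- XP / nA
  mB <- (totX - XP) / nB
  vA <- pmax((X2P - nA * mA^2) / (nA - 1), 0)
  vB <- pmax(((totX2 - X2P) - nB * mB^2) / (nB - 1), 0)
  .snr_metric(mA, mB, sqrt(vA), sqrt(vB))
}

#' GSEA with a phenotype-permutation null
#'
#' Computes the weighted KS enrichment score for every gene set, builds a
#' null by recomputing scores under random permutations of the phenotype
#' labels, and reports, per set: the normalized enrichment score
#' (`NES = ES / mean |null ES of matching sign|`), a nominal permutation p
#' using the (b+1)/(B+1) convention over same-sign null scores, and an FDR q
#' from the standard positive/negative null-pool ratio. A set is called
#' significant when nominal p < 0.05, |NES| >= 1 and q < 0.25.
#'
#' @param expression genes x samples matrix (rownames = gene symbols).
#' @param phenotype two-level labels over the columns; first factor level is
#'   class A, `direction = "up_in_A"` means enriched at the top of the
#'   A-high ranking.
#' @param sets a `gene_set_collection` (sets with no overlap with the matrix
#'   are dropped with a warning).
#' @param n_perm number of label permutations (>= 100). If it exceeds the
#'   number of distinct label assignments the permutations are enumerated
#'   exhaustively with a warning.
#' @param seed integer seed for the permutation stream (mandatory).
#' @param weight_p KS weighting exponent (default 1).
#' @return data.frame: `set`, `size`, `es`, `nes`, `nominal_p`, `fdr_q`,
#'   `direction`, `significant`.
#' @export
gsea_significance <- function(expression, phenotype, sets, n_perm = 1000,
                              seed, weight_p = 1) {
  if (missing(seed)) stop("a seed is required for the permutation null")
  if (n_perm < 100) stop("n_perm must be at least 100")
  ph <- factor(phenotype)
  if (nlevels(ph) != 2L) stop("phenotype must have exactly 2 levels")
  genes <- rownames(expression)
  keep <- vapply(sets, function(s) {
    k <- sum(genes %in% s)
    k > 0L && k < length(genes)
  }, logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " set(s) with no usable overlap dropped")
  }
  sets <- sets[keep]
  if (length(sets) == 0L) stop("no usable gene sets")
  set_idx <- lapply(sets, function(s) which(genes %in% s))

  n <- length(ph)
  nA <- sum(ph == levels(ph)[1])
  nB <- n - nA
  total_assign <- choose(n, nA)
  exhaustive <- FALSE
  if (n_perm > total_assign) {
    warning("n_perm (", n_perm, ") exceeds the ", total_assign,
            " distinct label assignments; enumerating exhaustively")
    exhaustive <- TRUE
  }

  ranked <- rank_genes(expression, ph)
  obs_es <- vapply(names(sets), function(s) {
    enrichment_score(ranked, sets[[s]], weight_p)$es
  }, numeric(1))

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  if (exhaustive) {
    combos <- utils::combn(n, nA)
    B <- ncol(combos)
    Z <- matrix(0, n, B)
    for (b in seq_len(B)) Z[combos[, b], b] <- 1
  } else {
    B <- n_perm
    Z <- matrix(0, n, B)
    for (b in seq_len(B)) Z[sample.int(n, nA), b] <- 1
  }

  M <- .perm_metrics(as.matrix(expression), Z, nA, nB)
  S <- length(sets)
  null_es <- matrix(NA_real_, S, B)
  N <- length(genes)
  for (b in seq_len(B)) {
    m <- M[, b]
    ord <- order(-m, genes)
    invpos <- integer(N)
    invpos[ord] <- seq_len(N)
    am <- abs(m)^weight_p
    for (s in seq_len(S)) {
      pos <- sort(invpos[set_idx[[s]]])
      null_es[s, b] <- .es_from_positions(pos, am[set_idx[[s]]][
        order(invpos[set_idx[[s]]])], N)
    }
  }

  # per-set signed-mean normalization
  nes <- numeric(S); null_nes <- matrix(NA_real_, S, B); nom_p <- numeric(S)
  for (s in seq_len(S)) {
    pos_null <- null_es[s, null_es[s, ] > 0]
    neg_null <- null_es[s, null_es[s, ] < 0]
    mpos <- if (length(pos_null)) mean(pos_null) else NA_real_
    mneg <- if (length(neg_null)) mean(abs(neg_null)) else NA_real_
    if (obs_es[s] >= 0) {
      nes[s] <- if (is.na(mpos)) 0 else obs_es[s] / mpos
      nom_p[s] <- (sum(pos_null >= obs_es[s]) + 1) / (length(pos_null) + 1)
    } else {
      nes[s] <- if (is.na(mneg)) 0 else obs_es[s] / mneg
      nom_p[s] <- (sum(neg_null <= obs_es[s]) + 1) / (length(neg_null) + 1)
    }
    nn <- null_es[s, ]
    null_nes[s, ] <- ifelse(nn >= 0,
                            if (is.na(mpos)) 0 else nn / mpos,
                            if (is.na(mneg)) 0 else nn / mneg)
  }

  # FDR q: positive/negative pool ratio as in standard GSEA
  all_null <- as.vector(null_nes)
  pos_pool <- all_null[all_null >= 0]
  neg_pool <- all_null[all_null < 0]
  obs_pos <- nes[nes >= 0]
  obs_neg <- nes[nes < 0]
  fdr_q <- vapply(nes, function(v) {
    if (v >= 0) {
      num <- if (length(pos_pool)) mean(pos_pool >= v) else 0
      den <- if (length(obs_pos)) mean(obs_pos >= v) else 1
    } else {
      num <- if (length(neg_pool)) mean(neg_pool <= v) else 0
      den <- if (length(obs_neg)) mean(obs_neg <= v) else 1
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  res <- data.frame(
    set = names(sets),
    size = vapply(set_idx, length, integer(1)),
    es = unname(obs_es), nes = nes, nominal_p = nom_p, fdr_q = fdr_q,
    direction = ifelse(obs_es >= 0, "up_in_A", "up_in_B"),
    stringsAsFactors = FALSE)
  res$significant <- res$nominal_p < 0.05 & abs(res$nes) >= 1 & res$fdr_q < 0.25
  rownames(res) <- NULL
  structure(res, classes = levels(ph), n_perm = B, weight_p = weight_p)
}
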
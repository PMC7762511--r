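# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# MATH via an explicitly sorting-based median
oracle_math <- function(x) {
  sort_median <- function(v) {
    s <- sort(v)
    n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  med <- sort_median(x)
  mad <- 1.4826 * sort_median(abs(x - med))
  100 * mad / med
}

# unweighted KS enrichment statistic from the raw running sum
oracle_unweighted_ks <- function(ranked_genes, gene_set) {
  hit <- ranked_genes %in% gene_set
  nh <- sum(hit)
  N <- length(hit)
  running <- cumsum(ifelse(hit, 1 / nh, -1 / (N - nh)))
  running[which.max(abs(running))]
}

# Cox log partial likelihood for a single covariate at a scalar beta
# (Breslow form; fixtures are untied so Efron coincides)
oracle_cox_loglik <- function(times, events, x, beta) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# exact two-sided Mann-Whitney p by full enumeration of label assignments
oracle_mw_exact <- function(x, y) {
  n1 <- length(x)
  vals <- c(x, y)
  n <- length(vals)
  combos <- utils::combn(n, n1)
  r <- rank(vals)
  mu <- n1 * (n - n1) / 2
  Us <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# two-sided Fisher p by enumerating every table with the observed margins,
# with probabilities from binomial coefficients
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# write a small MAF file from vectors; returns the path
write_toy_maf <- function(path, sample_id, gene, classification,
                          t_ref, t_alt, header_comment = NULL) {
  df <- data.frame(
    Hugo_Symbol = gene, Chromosome = "1",
    Start_Position = seq_along(gene),
    Variant_Classification = classification,
    Tumor_Sample_Barcode = sample_id,
    t_ref_count = t_ref, t_alt_count = t_alt)
  lines <- c(paste(names(df), collapse = "\t"),
             apply(df, 1, paste, collapse = "\t"))
  if (!is.null(header_comment)) lines <- c(header_comment, lines)
  writeLines(lines, path)
  path
}

# named factor of MATH groups for simulator-driven tests
toy_groups <- function(n, seed, levels = c("low", "intermediate", "high")) {
  set.seed(seed)
  stats::setNames(factor(sample(levels, n, replace = TRUE), levels = levels),
                  sprintf("S%04d", seq_len(n)))
}
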
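toy_maf_table <- function(sample_id, gene, classification) {
  structure(data.frame(
    sample_id = sample_id, gene = gene, chromosome = "1",
    start_position = seq_along(gene),
    variant_classification = classification,
    t_ref_count = 70, t_alt_count = 30, vaf = 0.3,
    stringsAsFactors = FALSE),
    class = c("maf_table", "data.frame"))
}

test_that("summarize_maf counts classifications, loads and gene recurrence", {
  maf <- toy_maf_table(
    sample_id = c("S1", "S1", "S2", "S2"),
    gene = c("TP53", "TTN", "TP53", "TP53"),
    classification = c("Missense_Mutation", "Missense_Mutation",
                       "Missense_Mutation", "Nonsense_Mutation"))
  s <- summarize_maf(maf)
  expect_equal(s$classification_counts,
               c(Missense_Mutation = 3L, Nonsense_Mutation = 1L))
  expect_equal(s$sample_load$n_variants, c(2L, 2L))
  expect_equal(s$median_load, 2)
  # TP53 hit twice in S2 counts S2 once -> 2 samples; ties alphabetical
  expect_equal(s$gene_ranking$gene, c("TP53", "TTN"))
  expect_equal(s$gene_ranking$n_samples, c(2L, 1L))
})

test_that("synthetic cohort median variant load lands near the target 63", {
  sim <- simulate_maf(synthetic_config(seed = 63, n_samples = 171))
  s <- summarize_maf(sim$maf)
  expect_gte(s$median_load, 55)
  expect_lte(s$median_load, 71)
  expect_equal(names(s$classification_counts)[1], "Missense_Mutation")
})

test_that("fisher_exact_2x2 matches hand enumeration and stats oracle", {
  f <- fisher_exact_2x2(2, 0, 0, 2)
  expect_equal(f$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "negative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "empty")

  set.seed(55)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, sample(5:40, 1), rep(0.25, 4)))
    p <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p_value
    ref <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(p, ref, tolerance = 1e-9)
  }
})

test_that("fisher_exact_2x2 is invariant under simultaneous row/col swap", {
  set.seed(56)
  for (i in 1:25) {
    cells <- as.integer(rmultinom(1, 30, rep(0.25, 4)))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    expect_equal(fisher_exact_2x2(a, b, c, d)$p_value,
                 fisher_exact_2x2(d, c, b, a)$p_value, tolerance = 1e-12)
    # two-sided >= one-sided
    m <- a + b; n <- c + d; k <- a + c
    one_sided <- min(phyper(a, m, n, k), phyper(a - 1, m, n, k, lower.tail = FALSE))
    expect_gte(fisher_exact_2x2(a, b, c, d)$p_value + 1e-12, one_sided)
  }
})

test_that("cooccurrence_scan calls shared and disjoint mutation patterns", {
  samples <- sprintf("P%02d", 1:16)
  half <- samples[1:8]
  m <- rbind(
    g_co1 = as.integer(samples %in% half),
    g_co2 = as.integer(samples %in% half),
    g_ex  = as.integer(!samples %in% half))
  colnames(m) <- samples
  scan <- cooccurrence_scan(m, top_k = 3)
  row_co <- scan[scan$gene_a == "g_co1" & scan$gene_b == "g_co2", ]
  expect_equal(row_co$call, "co_occurring")
  expect_lt(row_co$p_value, 0.05)
  row_ex <- scan[scan$gene_a == "g_co1" & scan$gene_b == "g_ex", ]
  expect_equal(row_ex$call, "exclusive")
  # 2x2 counts always sum to the sample count
  expect_true(all(scan$both + scan$a_only + scan$b_only + scan$neither == 16))
  expect_error(cooccurrence_scan(m, top_k = 1), "at least 2")
})

test_that("scan calls are symmetric in gene order", {
  set.seed(57)
  m <- matrix(rbinom(8 * 40, 1, 0.3), 8, 40,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:40)))
  s1 <- cooccurrence_scan(m, top_k = 8)
  s2 <- cooccurrence_scan(m[rev(seq_len(8)), ], top_k = 8)
  key <- function(s) {
    k <- ifelse(s$gene_a < s$gene_b, paste(s$gene_a, s$gene_b),
                paste(s$gene_b, s$gene_a))
    s <- s[order(k), ]
    data.frame(key = sort(k), p = s$p_value, call = s$call)
  }
  expect_equal(key(s1), key(s2), ignore_attr = TRUE)
})

test_that("false-call rate on independent gene columns is near alpha", {
  set.seed(58)
  rates <- vapply(1:20, function(r) {
    m <- matrix(rbinom(20 * 171, 1, 0.25), 20, 171,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:171)))
    scan <- cooccurrence_scan(m, top_k = 20, alpha = 0.05)
    mean(scan$call != "ns")
  }, numeric(1))
  expect_gte(mean(rates <= 0.10), 0.9)
})

test_that("gene_sample_matrix is binary and excludes silent variants", {
  maf <- toy_maf_table(
    sample_id = c("S1", "S1", "S1", "S2"),
    gene = c("TP53", "TP53", "TTN", "TTN"),
    classification = c("Missense_Mutation", "Missense_Mutation", "Silent",
                       "Nonsense_Mutation"))
  m <- gene_sample_matrix(maf)
  expect_equal(sort(rownames(m)), c("TP53", "TTN"))
  expect_equal(m["TP53", "S1"], 1L)      # two hits still 1
  expect_equal(m["TTN", "S1"], 0L)       # silent does not qualify
  expect_equal(m["TTN", "S2"], 1L)
  expect_true(all(m %in% 0:1))
})
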
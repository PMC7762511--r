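# expression matrix with exact class means/SDs for metric checks:
# class A columns 1:3, class B columns 4:6
snr_fixture <- function() {
  m <- rbind(
    gM = c(1.5, 2.0, 2.5, 0.5, 1.0, 1.5),  # means 2,1; sds 0.5,0.5 -> 1.0
    gT = c(1.0, 2.0, 3.0, 0.5, 1.0, 1.5),  # means 2,1; sds 1,0.5 -> 2/3
    gZ = c(1.0, 2.0, 3.0, 1.0, 2.0, 3.0)   # identical classes -> 0
  )
  colnames(m) <- paste0("s", 1:6)
  m
}

test_that("signal-to-noise ranking matches direct evaluation", {
  m <- snr_fixture()
  ph <- factor(rep(c("A", "B"), each = 3), levels = c("A", "B"))
  rl <- rank_genes(m, ph)
  met <- setNames(rl$metric, rl$gene)
  expect_equal(unname(met["gM"]), 1.0)
  expect_equal(unname(met["gT"]), 2 / 3)
  expect_equal(unname(met["gZ"]), 0)
  expect_equal(rl$gene, c("gM", "gT", "gZ"))   # descending metric

  # identical class distributions: all metrics 0, lexicographic order
  m0 <- m[, c(1:3, 1:3)]
  rl0 <- rank_genes(m0, ph)
  expect_true(all(rl0$metric == 0))
  expect_equal(rl0$gene, sort(rownames(m)))

  # swapping which phenotype is class A negates every metric
  rl_sw <- rank_genes(m, factor(rep(c("A", "B"), each = 3), levels = c("B", "A")))
  expect_equal(setNames(rl_sw$metric, rl_sw$gene)[names(met)], -met)

  expect_error(rank_genes(m, factor(c("A", "B", "B", "B", "B", "B"))),
               ">= 2 samples")
})

test_that("enrichment score matches the hand running sum", {
  ranked <- structure(
    data.frame(gene = paste0("g", 1:4), metric = c(2, 1, 0.5, 0.1)),
    class = c("ranked_list", "data.frame"))
  es <- enrichment_score(ranked, "g1", weight_p = 1)
  expect_equal(es$running, c(1, 1 - 1 / 3, 1 - 2 / 3, 0))
  expect_equal(es$es, 1.0)

  expect_lt(enrichment_score(ranked, "g4", weight_p = 1)$es, 0)
  expect_error(enrichment_score(ranked, "nope"), "no genes")
  expect_error(enrichment_score(ranked, paste0("g", 1:4)), "whole")
})

test_that("weight 0 reduces to the classical unweighted KS statistic", {
  set.seed(14)
  for (i in 1:20) {
    genes <- paste0("g", 1:50)
    ranked <- structure(
      data.frame(gene = genes, metric = sort(rnorm(50), decreasing = TRUE)),
      class = c("ranked_list", "data.frame"))
    gs <- sample(genes, sample(3:20, 1))
    expect_equal(enrichment_score(ranked, gs, weight_p = 0)$es,
                 oracle_unweighted_ks(genes, gs), tolerance = 1e-12)
  }
})

test_that("running sum is bounded in [-1,1] and returns to zero", {
  set.seed(15)
  for (i in 1:20) {
    N <- sample(20:100, 1)
    ranked <- structure(
      data.frame(gene = paste0("g", 1:N),
                 metric = sort(rnorm(N), decreasing = TRUE)),
      class = c("ranked_list", "data.frame"))
    gs <- sample(ranked$gene, sample(2:(N - 2), 1))
    es <- enrichment_score(ranked, gs, weight_p = sample(c(0, 0.5, 1, 2), 1))
    expect_lte(abs(es$es), 1 + 1e-12)
    expect_lt(abs(es$running[N]), 1e-9)
  }
})

test_that("gsea_significance: conventions, determinism, column duplication", {
  set.seed(16)
  X <- matrix(rnorm(80 * 12), 80, 12,
              dimnames = list(paste0("g", 1:80), paste0("s", 1:12)))
  ph <- factor(rep(c("A", "B"), each = 6))
  sets <- structure(list(s1 = paste0("g", 1:10), s2 = paste0("g", 30:45)),
                    class = "gene_set_collection")
  r1 <- gsea_significance(X, ph, sets, n_perm = 150, seed = 5)
  r2 <- gsea_significance(X, ph, sets, n_perm = 150, seed = 5)
  expect_equal(r1, r2)

  expect_true(all(r1$nominal_p > 0))            # (b+1)/(B+1): never zero
  expect_true(all(r1$nominal_p <= 1))
  expect_true(all(sign(r1$nes) == sign(r1$es) | r1$es == 0))
  expect_equal(r1$direction, ifelse(r1$es >= 0, "up_in_A", "up_in_B"))

  # duplicating every sample leaves the observed ES unchanged
  Xd <- cbind(X, X)
  rl <- rank_genes(X, ph)
  rld <- rank_genes(Xd, factor(rep(as.character(ph), 2)))
  for (s in names(sets)) {
    expect_equal(enrichment_score(rld, sets[[s]])$es,
                 enrichment_score(rl, sets[[s]])$es, tolerance = 1e-10)
  }

  expect_error(gsea_significance(X, ph, sets, n_perm = 50, seed = 1),
               "at least 100")
})

test_that("permutations are capped at the number of distinct assignments", {
  set.seed(18)
  X <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:10)))
  ph <- factor(rep(c("A", "B"), each = 5))   # choose(10,5) = 252 assignments
  sets <- structure(list(s1 = paste0("g", 1:8)),
                    class = "gene_set_collection")
  expect_warning(r <- gsea_significance(X, ph, sets, n_perm = 300, seed = 2),
                 "exhaustively")
  expect_equal(attr(r, "n_perm"), 252)
})
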
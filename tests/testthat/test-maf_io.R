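test_that("read_maf derives VAFs and tolerates comment lines", {
  p1 <- write_toy_maf(tempfile(fileext = ".maf"),
                      sample_id = c("S1", "S1", "S2"),
                      gene = c("TP53", "TTN", "MUC16"),
                      classification = rep("Missense_Mutation", 3),
                      t_ref = c(70, 90, 50), t_alt = c(30, 10, 50))
  maf <- read_maf(p1)
  expect_s3_class(maf, "maf_table")
  expect_equal(maf$vaf, c(0.30, 0.10, 0.50))
  expect_equal(attr(maf, "n_flagged"), 0L)

  p2 <- write_toy_maf(tempfile(fileext = ".maf"),
                      sample_id = c("S1", "S1", "S2"),
                      gene = c("TP53", "TTN", "MUC16"),
                      classification = rep("Missense_Mutation", 3),
                      t_ref = c(70, 90, 50), t_alt = c(30, 10, 50),
                      header_comment = "#version 2.4")
  expect_equal(as.data.frame(read_maf(p2)), as.data.frame(maf),
               ignore_attr = TRUE)
})

test_that("read_maf errors on missing required columns, flags bad counts", {
  p <- tempfile(fileext = ".maf")
  writeLines(c("Hugo_Symbol\tVariant_Classification\tt_ref_count\tt_alt_count",
               "TP53\tMissense_Mutation\t70\t30"), p)
  expect_error(read_maf(p), "Tumor_Sample_Barcode")

  p2 <- write_toy_maf(tempfile(fileext = ".maf"),
                      sample_id = c("S1", "S2"), gene = c("TP53", "TTN"),
                      classification = rep("Silent", 2),
                      t_ref = c("70", "oops"), t_alt = c("30", "10"))
  maf <- read_maf(p2)
  expect_equal(nrow(maf), 2L)
  expect_true(is.na(maf$vaf[2]))
  expect_equal(attr(maf, "n_flagged"), 1L)
})

test_that("MAF round-trips through write_maf/read_maf", {
  sim <- simulate_maf(synthetic_config(seed = 5, n_samples = 4))
  p <- tempfile(fileext = ".maf")
  write_maf(sim$maf, p)
  back <- read_maf(p)
  cols <- c("sample_id", "gene", "chromosome", "start_position",
            "variant_classification", "t_ref_count", "t_alt_count")
  expect_equal(as.data.frame(back)[cols], as.data.frame(sim$maf)[cols])
  expect_equal(back$vaf, sim$maf$vaf, tolerance = 1e-12)
})

test_that("vaf_profiles filters, trims and partitions consistently", {
  p <- write_toy_maf(tempfile(fileext = ".maf"),
                     sample_id = c("S1", "S1", "S1", "S2", "S2", "S2"),
                     gene = rep(c("A", "B", "C"), 2),
                     classification = rep(c("Missense_Mutation", "Silent",
                                            "Missense_Mutation"), 2),
                     t_ref = c(70, 50, 10, 60, 40, 55),
                     t_alt = c(30, 50, 90, 40, 60, 45))
  maf <- read_maf(p)

  # vaf_max trim
  prof <- vaf_profiles(maf, vaf_max = 0.75)
  expect_equal(prof$S1, c(0.3, 0.5))          # 0.9 trimmed
  expect_equal(prof$S2, c(0.4, 0.6, 0.45))

  # classification filter: one missense VAF left per sample... two here
  prof_m <- vaf_profiles(maf, include = "Silent", vaf_max = 1)
  expect_equal(lengths(prof_m), c(S1 = 1L, S2 = 1L))

  # no filtering: vectors of length 3 per sample
  prof_all <- vaf_profiles(maf, vaf_max = 1)
  expect_equal(lengths(prof_all), c(S1 = 3L, S2 = 3L))

  # partition consistency: retained variants across samples = retained rows
  expect_equal(sum(lengths(prof)), attr(prof, "n_retained"))
  expect_equal(sum(lengths(prof)),
               sum(!is.na(maf$vaf) & maf$vaf <= 0.75))

  # empty include-list is an error; empty samples are kept
  expect_error(vaf_profiles(maf, include = character(0)), "include-list")
  prof_none <- vaf_profiles(maf, include = "Nonsense_Mutation")
  expect_named(prof_none, c("S1", "S2"))
  expect_equal(lengths(prof_none), c(S1 = 0L, S2 = 0L))
})

test_that("read_gmt parses, deduplicates and validates", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdescA\tg1\tg2\tg1", "setB\tdescB\tg3"), p)
  gsc <- read_gmt(p)
  expect_length(gsc, 2)
  expect_equal(gsc$setA, c("g1", "g2"))     # duplicate gene deduplicated

  p2 <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1", "setA\tdesc\tg2"), p2)
  expect_error(read_gmt(p2), "duplicate")

  p3 <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1", "empty\tdesc"), p3)
  expect_error(read_gmt(p3), "line 2")
})

test_that("packaged immune-cell collection has 28 sets and round-trips", {
  gsc <- immune_cell_sets()
  expect_length(gsc, 28)
  expect_true(all(lengths(gsc) >= 1))
  expect_false(anyDuplicated(names(gsc)) > 0)
  p <- tempfile(fileext = ".gmt")
  write_gmt(gsc, p)
  back <- read_gmt(p)
  expect_equal(unclass(back)[names(gsc)], unclass(gsc)[names(gsc)],
               ignore_attr = TRUE)
})
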
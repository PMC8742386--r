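test_that("the overlap score is the sum of a set's bits", {
  uni <- tiny_universe(3L)  # positions 100, 1100, 2100
  trk <- track_sample("A", "t", "c", "DNase", "X",
                      data.frame(chrom = "chr1",
                                 start = c(50L, 2000L),
                                 end = c(150L, 2200L)))
  db <- build_overlap_db(uni, list(trk))  # bits 1, 0, 1
  expect_equal(overlap_score(db, c("rs1", "rs2", "rs3"), "A"), 2L)
  expect_equal(overlap_score(db, character(0), "A"), 0L)
  expect_equal(overlap_score(db, c("rs1", "rs3"), "A"), 2L)
  expect_error(overlap_score(db, "rs1", "nope"), "unknown sample_id")
  expect_error(overlap_score(db, "rsX", "A"), "not in database")
})

test_that("the exact binomial upper tail matches hand and oracle values", {
  expect_equal(binom_test_upper(0, 10, 0.3), 1)
  expect_equal(binom_test_upper(7, 7, 1), 1)
  expect_equal(binom_test_upper(5, 10, 0.5), 638 / 1024)
  # spot-check against independent log-space pmf summation
  for (case in list(c(3, 12, 0.1), c(19, 20, 0.7), c(50, 100, 0.25))) {
    expect_equal(binom_test_upper(case[[1]], case[[2]], case[[3]]),
                 oracle_binom_upper(case[[1]], case[[2]], case[[3]]),
                 tolerance = 1e-13)
  }
  # monotone non-increasing in k at fixed n, p
  pv <- binom_test_upper(0:20, 20, 0.3)
  expect_true(all(diff(pv) <= 0))
  expect_error(binom_test_upper(5, 4, 0.5), "k <= n")
})

test_that("z-scores use the n-1 sd and flag degenerate backgrounds", {
  expect_equal(overlap_z_score(5, c(4, 5, 6)), 0)
  expect_equal(overlap_z_score(6, c(2, 4)), 3 / sqrt(2))
  expect_equal(overlap_z_score(7, c(3, 3, 3)), Inf)
  expect_equal(overlap_z_score(1, c(3, 3, 3)), -Inf)
  expect_equal(overlap_z_score(3, c(3, 3, 3)), 0)
  expect_error(overlap_z_score(5, 3), "at least 2")
})

test_that("BH adjustment matches the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:60, 1L))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(q >= p) && all(q <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("background sets are matched exactly on all three deciles", {
  study <- sim_small_study(n_snps = 5000L, n_samples = 5L, seed = 31L)
  uni <- study$universe
  set.seed(2)
  input <- sample(uni$rsid, 25L)
  cfg <- enrichment_config(n_background_sets = 200L, seed = 99L)
  bg <- sample_matched_backgrounds(uni, input, cfg)
  expect_equal(dim(bg$sets), c(25L, 200L))
  # hard invariant: every drawn SNP shares the matched input SNP's bin key
  input_keys <- uni$bin_key[match(input, uni$rsid)]
  drawn_keys <- matrix(uni$bin_key[bg$sets], nrow = 25L)
  expect_true(all(drawn_keys == input_keys))
  # pooled per-covariate occupancy is exactly n_sets x input occupancy
  for (cov in c("maf", "tss", "gc")) {
    rep <- bg$matching_report[[cov]]
    expect_identical(rep[, "background"], 200L * rep[, "input"])
  }
  # input SNPs never appear among their backgrounds
  expect_false(any(uni$rsid[bg$sets] %in% input))
})

test_that("background draws are uniform within a bin and seeded", {
  # one input SNP whose bin holds 40 other SNPs
  n <- 41L
  uni <- assign_decile_bins(tiny_universe(n))
  cfg <- enrichment_config(n_background_sets = 1000L, seed = 12L)
  bg <- sample_matched_backgrounds(uni, "rs1", cfg)
  draws <- table(factor(bg$sets, levels = 2:41))
  expect_equal(sum(draws), 1000)
  gof <- suppressWarnings(chisq.test(as.vector(draws)))
  expect_gt(gof$p.value, 1e-3)
  # determinism: the same seed reproduces the collection exactly
  bg2 <- sample_matched_backgrounds(uni, "rs1", cfg)
  expect_identical(bg$sets, bg2$sets)
  bg3 <- sample_matched_backgrounds(
    uni, "rs1", enrichment_config(n_background_sets = 1000L, seed = 13L))
  expect_false(identical(bg$sets, bg3$sets))
})

test_that("within one set a bin's draws are without replacement", {
  uni <- assign_decile_bins(tiny_universe(30L))
  cfg <- enrichment_config(n_background_sets = 50L, seed = 4L)
  bg <- sample_matched_backgrounds(uni, c("rs1", "rs2", "rs3"), cfg)
  # all three inputs share one bin; each column must hold distinct SNPs
  expect_true(all(apply(bg$sets, 2L, function(s) !anyDuplicated(s))))
})

test_that("an isolated bin errors hard; a thin neighbour is borrowed", {
  # 9 SNPs in one corner bin, 1 input SNP alone in the opposite corner
  uni <- assign_decile_bins(tiny_universe(
    10L, maf = c(rep(0.05, 9L), 0.45),
    tss = c(rep(100, 9L), 9e5), gc = c(rep(0.3, 9L), 0.6)))
  cfg <- enrichment_config(n_background_sets = 10L, seed = 1L)
  expect_error(sample_matched_backgrounds(uni, "rs10", cfg),
               "no background candidates")

  # the input SNP is its bin's only member, but a MAF-neighbouring bin
  # is occupied: fallback widens by one decile with a warning
  uni2 <- assign_decile_bins(tiny_universe(
    20L, maf = c(seq(0.02, 0.38, by = 0.02), 0.40)))
  inputs <- uni2$rsid[uni2$maf_bin == 10L]
  solo <- sample_matched_backgrounds(uni2, inputs, cfg)
  expect_true(any(grepl("widened", solo$warnings)))
  expect_true(all(uni2$maf_bin[solo$sets] == 9L))
})
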
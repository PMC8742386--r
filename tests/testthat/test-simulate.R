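test_that("simulated universes respect record invariants, deterministically", {
  cfg <- sim_config(n_snps = 1000L, n_chroms = 3L, chrom_length = 1e6,
                    n_samples = 2L, seed = 7L)
  uni <- simulate_universe(cfg)
  expect_equal(nrow(uni), 1000L)
  expect_true(all(uni$maf >= 0.005 & uni$maf <= 0.5))
  expect_true(all(uni$gc >= 0 & uni$gc <= 1))
  expect_true(all(uni$tss_distance >= 0))
  expect_true(all(uni$pos >= 0 & uni$pos < 1e6))
  expect_equal(uni$rsid, paste0("rs", 1:1000))

  # identical TSV bytes from the same configuration
  p1 <- tempfile(); p2 <- tempfile()
  simulate_universe(cfg, path = p1)
  simulate_universe(cfg, path = p2)
  expect_identical(readLines(p1), readLines(p2))

  expect_error(sim_config(n_snps = 10L, seed = 1L), "n_snps")
  expect_error(sim_config(n_snps = 1000L), "seed")
})

test_that("track coverage concentrates around the configured base rate", {
  cfg <- sim_config(n_snps = 10000L, n_chroms = 2L, chrom_length = 5e7,
                    n_samples = 4L, base_overlap_rate = 0.1,
                    confounding = c(maf = 0, tss = 0, gc = 0), seed = 3L)
  uni <- simulate_universe(cfg)
  tr <- simulate_tracks(uni, cfg)
  frac <- colMeans(tr$truth)
  sd3 <- 3 * sqrt(0.1 * 0.9 / 10000)
  expect_true(all(abs(frac - 0.1) <= sd3))
})

test_that("a bin-wide spike multiplies the spiked sample's coverage", {
  base <- sim_config(n_snps = 10000L, n_chroms = 2L, chrom_length = 5e7,
                     n_samples = 4L, base_overlap_rate = 0.1,
                     confounding = c(maf = 0, tss = 0, gc = 0), seed = 3L)
  spiked <- sim_config(n_snps = 10000L, n_chroms = 2L, chrom_length = 5e7,
                       n_samples = 4L, base_overlap_rate = 0.1,
                       confounding = c(maf = 0, tss = 0, gc = 0),
                       spike = list(sample = "S002", fold = 3), seed = 3L)
  uni <- simulate_universe(base)
  tr <- simulate_tracks(uni, spiked)
  frac <- colMeans(tr$truth)
  expect_gt(frac[["S002"]], 0.25)
  expect_lt(frac[["S002"]], 0.35)
  expect_true(all(abs(frac[c("S001", "S003", "S004")] - 0.1) < 0.02))
})

test_that("the ground-truth matrix is exactly recovered from the BEDs", {
  cfg <- sim_config(n_snps = 3000L, n_chroms = 3L, chrom_length = 2e7,
                    n_samples = 5L, seed = 19L)
  uni <- simulate_universe(cfg)
  dir <- tempfile()
  tr <- simulate_tracks(uni, cfg, dir = dir)
  # via in-memory tracks
  db <- build_overlap_db(assign_decile_bins(uni), tr$tracks)
  expect_identical(db$bits, tr$truth)
  # and via the files on disk (BED round trip, manifest wiring)
  tracks2 <- read_track_manifest(file.path(dir, "samples.tsv"))
  db2 <- build_overlap_db(uni, tracks2)
  expect_identical(unname(db2$bits), unname(tr$truth))
  # determinism of written fixtures
  dir2 <- tempfile()
  simulate_tracks(uni, cfg, dir = dir2)
  expect_identical(readLines(file.path(dir, "S001.bed")),
                   readLines(file.path(dir2, "S001.bed")))
})

test_that("targeted input sets hit the intended sample's elements", {
  cfg <- sim_config(n_snps = 5000L, n_chroms = 2L, chrom_length = 2e7,
                    n_samples = 3L, seed = 23L)
  uni <- simulate_universe(cfg)
  tr <- simulate_tracks(uni, cfg)
  full <- simulate_input_set(uni, tr$truth, "S002", 50L, 1, seed = 1L)
  idx <- match(full, uni$rsid)
  expect_equal(sum(tr$truth[idx, "S002"]), 50L)

  mixed <- simulate_input_set(uni, tr$truth, "S002", 50L, 0.6, seed = 2L)
  expect_gte(sum(tr$truth[match(mixed, uni$rsid), "S002"]), 30L)
  expect_equal(length(mixed), 50L)
  expect_false(anyDuplicated(mixed) > 0L)

  nullset <- simulate_input_set(uni, tr$truth, "S002", 50L, 0, seed = 3L)
  expect_equal(length(nullset), 50L)

  expect_error(simulate_input_set(uni, tr$truth, "S002", 50L, 1.5, 1L),
               "enrichment_fraction")
  expect_error(simulate_input_set(uni, tr$truth, "S002", 3L, 0.5, 1L),
               "size")
  expect_error(simulate_input_set(uni, tr$truth, "nope", 50L, 0.5, 1L),
               "unknown target sample")
})

test_that("the FPR report keeps exact test accounting", {
  study <- sim_small_study(n_snps = 4000L, n_samples = 5L, seed = 88L)
  rep <- fpr_experiment(study$db, study$universe, set_sizes = c(5L, 10L),
                        sets_per_size = 8L,
                        config = enrichment_config(
                          n_background_sets = 50L, seed = 2L))
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$n_tests[rep$set_size == "overall"], 2L * 8L * 5L)
  expect_equal(rep$n_tests[rep$set_size == "5"], 8L * 5L)
  expect_equal(rep$rate_per_100k,
               1e5 * rep$n_significant / rep$n_tests)
})

test_that("a saturated database can never look enriched", {
  uni <- assign_decile_bins(tiny_universe(120L))
  full <- track_sample("ALL", "t", "c", "DNase", "X",
                       data.frame(chrom = "chr1", start = 0L,
                                  end = 200000L))
  db <- build_overlap_db(uni, list(full))
  rep <- fpr_experiment(db, uni, set_sizes = c(5L, 10L),
                        sets_per_size = 5L,
                        config = enrichment_config(
                          n_background_sets = 20L, seed = 4L))
  expect_equal(rep$n_significant, c(0L, 0L, 0L))
})
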
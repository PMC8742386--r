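test_that("catalogue parsing filters, splits and deduplicates traits", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "DATE\tDISEASE/TRAIT\tSNPS\tPVALUE",
    "2019\tTrait A\trs1\t1e-8",
    "2019\tTrait A\trs2; rs3\t1e-9",
    "2019\tTrait A\trs4 x rs5\t1e-8",
    "2019\tTrait A\trs1\t2e-8",          # duplicate rsid
    "2019\tTrait A\tchr6:32413\t1e-8",   # malformed token
    "2019\tTrait B\trs10\t1e-8",
    "2019\tTrait B\trs11; rs12; rs13\t1e-8"), path)
  expect_warning(map <- read_gwas_catalogue(path, min_snps = 5L),
                 "malformed")
  # A has 5 unique rsids and is kept; B has 4 and is dropped
  expect_equal(names(map), "Trait A")
  expect_equal(map[["Trait A"]], c("rs1", "rs2", "rs3", "rs4", "rs5"))

  map2 <- suppressWarnings(read_gwas_catalogue(path, min_snps = 4L))
  expect_setequal(names(map2), c("Trait A", "Trait B"))
  expect_equal(length(map2[["Trait B"]]), 4L)

  writeLines("A\tB", path)
  expect_error(read_gwas_catalogue(path), "required column")
})

test_that("batch assembly fills -log10(q) cells and isolates failures", {
  study <- sim_small_study(n_snps = 8000L, n_samples = 6L, seed = 300L)
  set.seed(4)
  map <- phenotype_map(
    traits = rep(c("asthma", "height", "ghost"), times = c(6L, 8L, 5L)),
    snp_cells = c(sample(study$universe$rsid, 6L),
                  sample(study$universe$rsid, 8L),
                  paste0("rs", 900001:900005)),
    min_snps = 5L)
  expect_setequal(names(map), c("asthma", "height", "ghost"))
  cfg <- enrichment_config(n_background_sets = 100L, seed = 77L)
  expect_warning(pm <- batch_enrichment(study$db, study$universe, map,
                                        config = cfg),
                 "ghost.*skipped")
  expect_equal(sort(rownames(pm$matrix)), c("asthma", "height"))
  expect_equal(ncol(pm$matrix), 6L)
  # cells equal the per-run -log10(q)
  r <- pm$runs[["asthma"]]
  expect_equal(unname(pm$matrix["asthma", r$sample_id]),
               ifelse(r$q >= 1, 0, -log10(r$q)))
  expect_named(pm$skipped, "ghost")

  # determinism and batch-order invariance
  pm2 <- suppressWarnings(
    batch_enrichment(study$db, study$universe, map[c(2L, 3L, 1L)],
                     config = cfg))
  expect_equal(pm2$matrix[rownames(pm$matrix), ], pm$matrix)
})

test_that("row normalisation divides by the row maximum", {
  pm <- structure(list(matrix = rbind(a = c(1, 2, 4),
                                      b = c(0, 0, 0),
                                      c = c(3, 3, 3)),
                       row_normalised = FALSE, row_max = NULL),
                  class = "phenotype_matrix")
  norm <- row_normalise(pm)
  expect_equal(unname(norm$matrix["a", ]), c(0.25, 0.5, 1))
  expect_equal(unname(norm$matrix["b", ]), c(0, 0, 0))
  expect_equal(unname(norm$matrix["c", ]), c(1, 1, 1))
  expect_equal(unname(norm$row_max), c(4, 0, 3))
  # nonzero rows peak at exactly 1
  expect_true(all(apply(norm$matrix[c("a", "c"), ], 1L, max) == 1))
})

test_that("complete-linkage clustering reproduces hand-computed merges", {
  m <- rbind(p1 = c(0, 0), p2 = c(0, 3), p3 = c(4, 0))
  cl <- cluster_rows(m)
  # nearest pair (p1,p2) merges at 3; final merge at max distance 5
  expect_equal(cl$hclust$height, c(3, 5))
  expect_equal(sort(cl$order), c("p1", "p2", "p3"))
  expect_true(grepl("p1", cl$newick))

  # identical rows merge first at height 0
  m2 <- rbind(x = c(1, 1), y = c(5, 9), z = c(1, 1))
  cl2 <- cluster_rows(m2)
  expect_equal(cl2$hclust$height[[1L]], 0)
  first <- cl2$hclust$merge[1L, ]
  expect_setequal(cl2$hclust$labels[-first], c("x", "z"))

  # single row: identity order, no tree
  cl1 <- cluster_rows(m[1L, , drop = FALSE])
  expect_equal(cl1$order, "p1")
  expect_null(cl1$hclust)
})

test_that("clustering agrees with a brute-force agglomeration oracle", {
  set.seed(15)
  for (i in 1:12) {
    nr <- sample(3:12, 1L); nc <- sample(2:6, 1L)
    m <- matrix(rnorm(nr * nc), nr,
                dimnames = list(paste0("r", seq_len(nr)), NULL))
    cl <- cluster_rows(m)
    expect_equal(sort(cl$hclust$height),
                 sort(oracle_complete_linkage_heights(m)),
                 tolerance = 1e-10)
  }
  # permutation invariance of the tree heights and leaf set
  m <- matrix(runif(24), 6, dimnames = list(letters[1:6], NULL))
  cl_a <- cluster_rows(m)
  cl_b <- cluster_rows(m[sample(6L), , drop = FALSE])
  expect_equal(cl_a$hclust$height, cl_b$hclust$height)
  expect_setequal(cl_a$order, cl_b$order)
})

test_that("newick export round-trips through ape", {
  m <- matrix(runif(20), 5, dimnames = list(paste0("ph", 1:5), NULL))
  cl <- cluster_rows(m)
  tree <- ape::read.tree(text = cl$newick)
  expect_setequal(tree$tip.label, rownames(m))
})

test_that("intersection summaries count every region of the set algebra", {
  out <- intersection_summary(list(A = c("x", "y"), B = c("y", "z")))
  get <- function(comb) out$n[out$combination == comb]
  expect_equal(get("A"), 1L)
  expect_equal(get("B"), 1L)
  expect_equal(get("A & B"), 1L)

  disj <- intersection_summary(list(A = "a", B = "b", C = "c"))
  expect_true(all(disj$n[disj$degree > 1L] == 0L))
  expect_true(all(disj$n[disj$degree == 1L] == 1L))

  same <- intersection_summary(list(A = c("u", "v"), B = c("u", "v")))
  expect_equal(get2 <- same$n[same$combination == "A & B"], 2L)
  expect_true(all(same$n[same$degree == 1L] == 0L))
})

test_that("phenotype matrices and trees are written to disk", {
  study <- sim_small_study(n_snps = 5000L, n_samples = 4L, seed = 123L)
  set.seed(5)
  map <- list(t1 = sample(study$universe$rsid, 6L),
              t2 = sample(study$universe$rsid, 7L))
  pm <- batch_enrichment(study$db, study$universe, map,
                         config = enrichment_config(
                           n_background_sets = 50L, seed = 9L))
  dir <- tempfile()
  write_phenotype_matrix(pm, dir)
  expect_true(file.exists(file.path(dir, "matrix.tsv")))
  m <- utils::read.delim(file.path(dir, "matrix.tsv"),
                         check.names = FALSE)
  expect_equal(m$phenotype, rownames(pm$matrix))
  expect_true(file.exists(file.path(dir, "pheno_001_results.tsv")))
})
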
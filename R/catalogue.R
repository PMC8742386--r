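#' Parse a GWAS-catalogue association file into per-phenotype SNP lists
#'
#' Reads the catalogue's "all associations" TSV dialect: one row per
#' association, with a trait column and a SNP column whose cells may hold
#' several rsids separated by `"; "` or `" x "` (interaction entries).
#' Tokens not matching `rs<digits>` are dropped with a warning; rsids are
#' deduplicated per trait in order of first appearance; traits with fewer
#' than `min_snps` SNPs are removed.
#'
#' @param path TSV path.
#' @param min_snps Minimum SNPs a phenotype must have to be retained
#'   (default 5).
#' @param trait_col,snp_col Column names (defaults `"DISEASE/TRAIT"` and
#'   `"SNPS"`).
#' @return A `phenotype_map`: named list of rsid vectors.
#' @export
read_gwas_catalogue <- function(path, min_snps = 5L,
                                trait_col = "DISEASE/TRAIT",
                                snp_col = "SNPS") {
  if (!file.exists(path)) stop("catalogue file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c(trait_col, snp_col), names(df))
  if (length(missing) > 0L) {
    stop("catalogue lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  phenotype_map(df[[trait_col]], df[[snp_col]], min_snps = min_snps)
}

#' Build a phenotype map from trait and SNP-cell vectors
#'
#' @param traits Character vector of trait labels (one per association).
#' @param snp_cells Parallel vector of SNP cells; each may list several
#'   rsids separated by `"; "` or `" x "`.
#' @param min_snps Minimum retained-phenotype size (default 5).
#' @return A `phenotype_map` (named list of deduplicated rsid vectors).
#' @export
phenotype_map <- function(traits, snp_cells, min_snps = 5L) {
  stopifnot(length(traits) == length(snp_cells))
  tokens <- strsplit(as.character(snp_cells), "\\s*;\\s*|\\s+x\\s+")
  trait_rep <- rep(as.character(traits), lengths(tokens))
  tok <- trimws(unlist(tokens, use.names = FALSE))
  valid <- grepl("^rs[0-9]+$", tok)
  n_bad <- sum(!valid & nzchar(tok))
  if (n_bad > 0L) {
    warning(n_bad, " malformed SNP token(s) dropped from catalogue",
            call. = FALSE)
  }
  m <- lapply(split(tok[valid], trait_rep[valid]),
              function(x) unique(x))
  m <- m[vapply(m, length, integer(1)) >= min_snps]
  structure(m, class = "phenotype_map", min_snps = as.integer(min_snps))
}

# deterministic 31-bit string hash, for order-independent per-phenotype
# seed derivation
.stable_hash <- function(label) {
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

#' Batch enrichment over a phenotype map
#'
#' Runs [snp_enrichment()] once per phenotype against the same database
#' and universe, with a per-phenotype seed derived deterministically from
#' the master seed and the phenotype label (independent of batch order),
#' and assembles the phenotype-by-biosample matrix of `-log10(q)` values
#' (0 where q >= 1). BH correction is applied within each phenotype run,
#' across that run's biosamples. Per-phenotype failures (e.g. no input
#' SNP found in the database) are logged and skipped, never fatal to the
#' batch.
#'
#' @param db An `overlap_db`.
#' @param universe A binned `snp_universe` (binned automatically if not).
#' @param map A `phenotype_map` (or named list of rsid vectors).
#' @param ld Optional `ld_table` applied to every phenotype.
#' @param config An `enrichment_config`; its `seed` is the master seed.
#' @param statistic Matrix cell statistic, `"neglog10q"` (default) or
#'   `"z"`.
#' @return A `phenotype_matrix` object: `$matrix` (phenotypes x samples),
#'   `$runs` (per-phenotype result tables), `$any_significant` (logical
#'   per phenotype), `$skipped` (failed phenotypes with reasons).
#' @export
batch_enrichment <- function(db, universe, map, ld = NULL,
                             config = enrichment_config(),
                             statistic = c("neglog10q", "z")) {
  statistic <- match.arg(statistic)
  stopifnot(length(map) >= 1L)
  if (!isTRUE(attr(universe, "binned"))) {
    universe <- assign_decile_bins(universe)
  }
  labels <- names(map)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("phenotype map must be a named list")
  }
  samples <- db$samples$sample_id
  runs <- list(); skipped <- list()
  for (ph in labels) {
    seed_ph <- bitwXor(config$seed, .stable_hash(ph))
    cfg_ph <- enrichment_config(
      n_background_sets = config$n_background_sets,
      r2_threshold = config$r2_threshold,
      q_threshold = config$q_threshold,
      seed = seed_ph,
      exclude_input_from_background = config$exclude_input_from_background)
    fit <- tryCatch(
      suppressWarnings(snp_enrichment(db, universe, map[[ph]], ld = ld,
                                      config = cfg_ph)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      skipped[[ph]] <- conditionMessage(fit)
      warning("phenotype '", ph, "' skipped: ", conditionMessage(fit),
              call. = FALSE)
    } else {
      runs[[ph]] <- fit
    }
  }
  if (length(runs) == 0L) stop("no phenotype could be analysed")
  mat <- matrix(0, nrow = length(runs), ncol = length(samples),
                dimnames = list(names(runs), samples))
  for (ph in names(runs)) {
    r <- runs[[ph]]$results
    val <- switch(statistic,
                  neglog10q = ifelse(r$q >= 1, 0,
                                     -log10(pmax(r$q, 1e-300))),
                  z = r$z)
    mat[ph, r$sample_id] <- val
  }
  structure(list(matrix = mat,
                 statistic = statistic,
                 runs = lapply(runs, function(f) f$results),
                 any_significant = vapply(runs, function(f)
                   any(f$results$significant), logical(1)),
                 skipped = skipped,
                 row_normalised = FALSE,
                 row_max = NULL,
                 config = config),
            class = "phenotype_matrix")
}

#' Row-normalise a phenotype matrix
#'
#' Divides each row by its maximum (the convention behind row-normalised
#' enrichment heatmaps, whose side line-plot shows each row's top
#' enrichment value). All-zero rows are left as zeros; row maxima are
#' retained in `$row_max`.
#'
#' @param pm A `phenotype_matrix`.
#' @return The normalised `phenotype_matrix`.
#' @export
row_normalise <- function(pm) {
  stopifnot(inherits(pm, "phenotype_matrix"))
  if (isTRUE(pm$row_normalised)) return(pm)
  mx <- apply(pm$matrix, 1L, max)
  scale <- ifelse(mx > 0, mx, 1)
  pm$matrix <- pm$matrix / scale
  pm$row_max <- mx
  pm$row_normalised <- TRUE
  pm
}

#' Complete-linkage clustering of phenotype rows
#'
#' Agglomerative hierarchical clustering of the matrix rows with complete
#' linkage on Euclidean distances. Rows are ordered by label before
#' clustering so that ties merge deterministically regardless of input
#' order.
#'
#' @param x A `phenotype_matrix` or a numeric matrix with row names.
#' @return For >= 2 rows, a list with `order` (leaf labels left to
#'   right), `hclust` (the merge tree) and `newick` (the tree in Newick
#'   text form, merge heights as branch lengths). For a single row, the
#'   identity order and `NULL` tree.
#' @export
cluster_rows <- function(x) {
  m <- if (inherits(x, "phenotype_matrix")) x$matrix else as.matrix(x)
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  if (nrow(m) < 2L) {
    return(list(order = rownames(m), hclust = NULL, newick = NULL))
  }
  m <- m[order(rownames(m)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "complete")
  phy <- ape::as.phylo(hc)
  list(order = hc$labels[hc$order], hclust = hc,
       newick = ape::write.tree(phy))
}

#' Shared and unique counts over named sets
#'
#' UpSet-style exact region counts of the set algebra: for every
#' combination of the named sets, the number of elements belonging to
#' exactly that combination and no other set.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return Data frame with one row per combination: `combination`
#'   (set names joined by `&`), `degree`, and `n` (exclusive count).
#' @export
intersection_summary <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  k <- length(sets)
  elements <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) elements %in% s,
                       logical(length(elements)))
  if (length(elements) == 1L) membership <- matrix(membership, nrow = 1L)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(combos) <- names(sets)
  n <- apply(combos, 1L, function(cmb) {
    sum(apply(membership, 1L, function(row) all(row == cmb)))
  })
  out <- data.frame(
    combination = apply(combos, 1L, function(cmb)
      paste(names(sets)[as.logical(cmb)], collapse = " & ")),
    degree = rowSums(combos),
    n = as.integer(n),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$degree, out$combination), , drop = FALSE]
}

#' Write the phenotype matrix and per-phenotype results to disk
#'
#' @param pm A `phenotype_matrix`.
#' @param dir Output directory (created if needed). Writes `matrix.tsv`
#'   and one `pheno_<i>_results.tsv` per phenotype, plus an index table
#'   mapping file names to phenotype labels.
#' @return `dir`, invisibly.
#' @export
write_phenotype_matrix <- function(pm, dir) {
  stopifnot(inherits(pm, "phenotype_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- data.frame(phenotype = rownames(pm$matrix), pm$matrix,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(m, file.path(dir, "matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  idx <- data.frame(file = sprintf("pheno_%03d_results.tsv",
                                   seq_along(pm$runs)),
                    phenotype = names(pm$runs),
                    any_significant = pm$any_significant,
                    stringsAsFactors = FALSE)
  utils::write.table(idx, file.path(dir, "phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (i in seq_along(pm$runs)) {
    utils::write.table(pm$runs[[i]], file.path(dir, idx$file[[i]]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat("Phenotype matrix:", nrow(x$matrix), "phenotype(s) x",
      ncol(x$matrix), "biosample(s); statistic:", x$statistic,
      if (isTRUE(x$row_normalised)) "(row-normalised)" else "", "\n")
  cat("  phenotypes with >= 1 significant sample:",
      sum(x$any_significant), "\n")
  if (length(x$skipped) > 0L) {
    cat("  skipped:", paste(names(x$skipped), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Heatmap of a phenotype matrix
#'
#' Base-graphics image of the (optionally row-normalised) matrix with
#' rows in complete-linkage cluster order.
#'
#' @param x A `phenotype_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.phenotype_matrix <- function(x, ...) {
  m <- x$matrix
  if (nrow(m) >= 2L) {
    cl <- cluster_rows(x)
    m <- m[cl$order, , drop = FALSE]
  }
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  axes = FALSE, ...)
  graphics::axis(2, at = seq(1, 0, length.out = nrow(m)),
                 labels = rownames(m), las = 2, cex.axis = 0.7)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(m)),
                 labels = colnames(m), las = 2, cex.axis = 0.6)
  invisible(x)
}
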
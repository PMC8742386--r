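#' Analysis configuration
#'
#' @param n_background_sets Number of matched background SNP sets drawn
#'   per analysis (default 1000).
#' @param r2_threshold LD pruning threshold: input SNPs at r2 >= threshold
#'   with an earlier retained SNP are excluded (default 0.8).
#' @param q_threshold Significance threshold on the BH-adjusted q value
#'   (default 0.01; enrichments at q < 0.01 are called significant).
#' @param seed Integer seed controlling background sampling.
#' @param exclude_input_from_background If `TRUE` (default) input SNPs are
#'   not eligible as background candidates.
#' @return An `enrichment_config` object.
#' @export
enrichment_config <- function(n_background_sets = 1000L,
                              r2_threshold = 0.8,
                              q_threshold = 0.01,
                              seed = 1L,
                              exclude_input_from_background = TRUE) {
  stopifnot(n_background_sets >= 1L,
            r2_threshold > 0, r2_threshold <= 1,
            q_threshold > 0, q_threshold <= 1,
            is.numeric(seed), length(seed) == 1L)
  structure(list(n_background_sets = as.integer(n_background_sets),
                 r2_threshold = r2_threshold,
                 q_threshold = q_threshold,
                 seed = as.integer(seed),
                 exclude_input_from_background =
                   isTRUE(exclude_input_from_background)),
            class = "enrichment_config")
}

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring
# the caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Overlap score of a SNP set in one biosample
#'
#' The overlap score is the number of SNPs in the set whose position falls
#' inside the biosample's annotated intervals (the sum of the set's
#' overlap bits).
#'
#' @param db An `overlap_db`.
#' @param snp_set Character vector of rsids, all present in the database.
#' @param sample_id Biosample identifier.
#' @return Integer overlap count in `0..length(snp_set)`.
#' @export
overlap_score <- function(db, snp_set, sample_id) {
  stopifnot(inherits(db, "overlap_db"))
  j <- match(sample_id, db$samples$sample_id)
  if (is.na(j)) stop("unknown sample_id: ", sample_id)
  if (length(snp_set) == 0L) return(0L)
  i <- match(snp_set, db$rsid)
  if (anyNA(i)) stop("rsid not in database: ", snp_set[is.na(i)][[1L]])
  sum(db$bits[i, j])
}

#' One-sided upper-tail binomial test
#'
#' Exact upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p)` (no
#' normal approximation). Used to compare the observed overlap score with
#' the background-estimated per-SNP overlap probability.
#'
#' @param k Observed count(s), `0 <= k <= n`.
#' @param n Number of trials.
#' @param p Success probability in `[0, 1]` (vectorised with `k`).
#' @return Upper-tail p-value(s).
#' @export
binom_test_upper <- function(k, n, p) {
  m <- max(length(k), length(p), length(n))
  k <- rep_len(k, m); n <- rep_len(n, m); p <- rep_len(p, m)
  stopifnot(all(k >= 0), all(k <= n), all(p >= 0), all(p <= 1))
  ifelse(k <= 0, 1, stats::pbinom(k - 1, n, p, lower.tail = FALSE))
}

#' Z-score of an observed overlap against background overlap scores
#'
#' `(k_obs - mean(bg)) / sd(bg)` with the sample (n-1) standard
#' deviation. For a degenerate background (sd = 0) the score is 0 when
#' the observation equals the background, otherwise signed infinity.
#'
#' @param k_obs Observed overlap score.
#' @param bg_scores At least two background overlap scores.
#' @return Numeric z-score.
#' @export
overlap_z_score <- function(k_obs, bg_scores) {
  if (length(bg_scores) < 2L) {
    stop("at least 2 background scores are required for a z-score")
  }
  m <- mean(bg_scores); s <- stats::sd(bg_scores)
  if (s == 0) {
    if (k_obs == m) return(0)
    return(sign(k_obs - m) * Inf)
  }
  (k_obs - m) / s
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment across all tests of
#' one analysis run, via [stats::p.adjust()].
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Candidate pool for one decile bin, optionally excluding input SNPs.
# When the exact bin is empty the pool is expanded one decile step at a
# time, in MAF, then TSS, then GC (each tried from the original bin).
.bin_candidates <- function(key, bin_index, exclude_idx) {
  pool <- function(keys) {
    keys <- keys[keys >= 0L & keys <= 999L]
    members <- unlist(bin_index[as.character(keys)], use.names = FALSE)
    if (length(exclude_idx) > 0L && length(members) > 0L) {
      members <- members[!(members %in% exclude_idx)]
    }
    members
  }
  cand <- pool(key)
  if (length(cand) > 0L) return(list(cand = cand, fallback = NA_character_))
  trip <- .decode_bin_key(key)
  steps <- list(
    maf = c(key - 100L, key + 100L)[c(trip[1L, "maf"] > 1L,
                                      trip[1L, "maf"] < 10L)],
    tss = c(key - 10L, key + 10L)[c(trip[1L, "tss"] > 1L,
                                    trip[1L, "tss"] < 10L)],
    gc  = c(key - 1L, key + 1L)[c(trip[1L, "gc"] > 1L,
                                  trip[1L, "gc"] < 10L)])
  for (dim in names(steps)) {
    cand <- pool(steps[[dim]])
    if (length(cand) > 0L) return(list(cand = cand, fallback = dim))
  }
  NULL
}

#' Draw covariate-matched background SNP sets
#'
#' For each background set and each input SNP, one SNP is drawn from the
#' same (MAF, TSS-distance, GC) decile bin of the universe, so that the
#' pooled background decile occupancy per covariate equals exactly
#' `n_background_sets` times the input's occupancy. Within one background
#' set, draws are without replacement inside a bin whenever the bin holds
#' at least as many candidates as input SNPs; otherwise drawing falls back
#' to replacement with a warning. If a bin has no eligible candidate at
#' all, the pool is widened by one decile step (MAF, then TSS, then GC);
#' an empty pool after fallback is an error.
#'
#' @param universe A binned `snp_universe` (see [assign_decile_bins()]).
#' @param input_rsids Input SNPs, all present in the universe.
#' @param config An `enrichment_config`; `seed` drives all draws.
#' @return A `background_collection`: `sets` is an
#'   `n_input x n_background_sets` matrix of universe row indices, row i
#'   matched to input SNP i; `matching_report` tabulates per-covariate
#'   decile occupancy for the input and the pooled backgrounds.
#' @export
sample_matched_backgrounds <- function(universe, input_rsids, config) {
  stopifnot(inherits(universe, "snp_universe"),
            isTRUE(attr(universe, "binned")),
            inherits(config, "enrichment_config"))
  idx <- match(input_rsids, universe$rsid)
  if (anyNA(idx)) {
    stop("input rsid not in universe: ", input_rsids[is.na(idx)][[1L]])
  }
  n <- length(idx)
  n_sets <- config$n_background_sets
  bin_index <- attr(universe, "bin_index")
  keys <- universe$bin_key[idx]
  exclude <- if (config$exclude_input_from_background) idx else integer(0)
  sets <- matrix(NA_integer_, nrow = n, ncol = n_sets)
  warnings <- character(0)

  .with_seed(config$seed, {
    for (key in unique(keys)) {
      rows <- which(keys == key)
      m <- length(rows)
      cp <- .bin_candidates(key, bin_index, exclude)
      if (is.null(cp)) {
        trip <- .decode_bin_key(key)
        stop("no background candidates for decile bin (maf=", trip[1L, 1L],
             ", tss=", trip[1L, 2L], ", gc=", trip[1L, 3L],
             "), even after single-step fallback")
      }
      if (!is.na(cp$fallback)) {
        warnings <- c(warnings, paste0(
          "bin ", key, " empty; widened by one ", cp$fallback,
          " decile for ", m, " input SNP(s)"))
      }
      cand <- cp$cand
      L <- length(cand)
      if (m == 1L) {
        sets[rows, ] <- cand[sample.int(L, n_sets, replace = TRUE)]
      } else if (L >= m) {
        sets[rows, ] <- vapply(seq_len(n_sets),
                               function(s) cand[sample.int(L, m)],
                               integer(m))
      } else {
        warnings <- c(warnings, paste0(
          "bin ", key, " holds ", L, " candidate(s) for ", m,
          " input SNP(s); sampling with replacement"))
        sets[rows, ] <- matrix(cand[sample.int(L, m * n_sets,
                                               replace = TRUE)],
                               nrow = m, ncol = n_sets)
      }
    }
  })

  report <- lapply(c(maf = "maf_bin", tss = "tss_bin", gc = "gc_bin"),
                   function(col) {
                     input <- tabulate(universe[[col]][idx], nbins = 10L)
                     pooled <- tabulate(universe[[col]][as.vector(sets)],
                                        nbins = 10L)
                     cbind(decile = 1:10, input = input, background = pooled)
                   })
  structure(list(sets = sets, input_rsids = input_rsids, input_idx = idx,
                 matching_report = report, warnings = warnings,
                 n_background_sets = n_sets),
            class = "background_collection")
}

#' Test a SNP set for enrichment across all biosamples
#'
#' The full analysis pipeline: greedy LD pruning of the input (when an LD
#' table is supplied), removal of rsids absent from the database or
#' universe, a single draw of covariate-matched background sets shared
#' across all biosamples, then per biosample the observed overlap score
#' `k_obs`, the background score distribution, the background per-SNP
#' overlap probability `p_hat = sum(background overlaps) / (n_sets * n)`,
#' an exact one-sided binomial p-value for `k_obs` against
#' `Binomial(n, p_hat)`, and an empirical z-score. P-values are BH-adjusted
#' across all biosamples of the run and enrichments at `q < q_threshold`
#' are flagged significant. Depletion (z < 0) is reported but never
#' flagged. Results are ordered by q, then z descending, ties broken by
#' sample_id.
#'
#' @param db An `overlap_db`.
#' @param universe A binned `snp_universe` (binned automatically if not).
#' @param input_rsids Character vector of input SNPs (at least one).
#' @param ld Optional `ld_table` for input pruning; `NULL` disables it.
#' @param config An `enrichment_config`.
#' @return A `snp_enrichment` object; `$results` is the per-biosample
#'   table, `$dropped` the rsids removed before testing, `$matching` the
#'   background matching report.
#' @examples
#' cfg <- sim_config(n_snps = 2000, n_samples = 5, seed = 11)
#' uni <- assign_decile_bins(simulate_universe(cfg))
#' trk <- simulate_tracks(uni, cfg)
#' db <- build_overlap_db(uni, trk$tracks)
#' fit <- snp_enrichment(db, uni, sample(uni$rsid, 20),
#'                       config = enrichment_config(n_background_sets = 100,
#'                                                  seed = 3))
#' fit
#' @export
snp_enrichment <- function(db, universe, input_rsids, ld = NULL,
                           config = enrichment_config()) {
  stopifnot(inherits(db, "overlap_db"), inherits(universe, "snp_universe"),
            inherits(config, "enrichment_config"))
  if (length(input_rsids) < 1L) stop("at least one input rsid is required")
  if (!isTRUE(attr(universe, "binned"))) {
    universe <- assign_decile_bins(universe)
  }
  input_rsids <- as.character(input_rsids)
  warnings <- character(0)

  used <- unique(input_rsids)
  if (length(used) < length(input_rsids)) {
    warnings <- c(warnings, paste0(length(input_rsids) - length(used),
                                   " duplicate input rsid(s) collapsed"))
  }
  if (!is.null(ld)) used <- ld_prune(used, ld, config$r2_threshold)
  n_pruned <- length(unique(input_rsids)) - length(used)

  present <- used %in% db$rsid & used %in% universe$rsid
  dropped <- used[!present]
  if (length(dropped) > 0L) {
    warnings <- c(warnings, paste0(length(dropped),
                                   " input rsid(s) absent from database/",
                                   "universe were dropped"))
    warning(length(dropped), " input SNP(s) not in the database/universe; ",
            "dropped: ", paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "", call. = FALSE)
  }
  used <- used[present]
  n <- length(used)
  if (n < 1L) stop("no input SNPs found in database")

  bg <- sample_matched_backgrounds(universe, used, config)
  warnings <- c(warnings, bg$warnings)
  n_sets <- config$n_background_sets

  # map universe rows to database rows (identity when built from the
  # same universe, in the same order)
  if (identical(universe$rsid, db$rsid)) {
    u2d <- seq_along(db$rsid)
  } else {
    u2d <- match(universe$rsid, db$rsid)
  }
  dbi <- u2d[bg$input_idx]
  if (anyNA(dbi)) stop("input SNP present in universe but not in database")
  k_obs <- colSums(db$bits[dbi, , drop = FALSE])

  bg_flat <- u2d[as.vector(bg$sets)]
  if (anyNA(bg_flat)) {
    stop("background SNP present in universe but not in database; ",
         "database and universe are inconsistent")
  }
  scores <- rowsum(db$bits[bg_flat, , drop = FALSE],
                   group = rep(seq_len(n_sets), each = n), reorder = TRUE)
  bg_mean <- colMeans(scores)
  bg_sd <- apply(scores, 2L, stats::sd)
  p_hat <- colSums(scores) / (n_sets * n)
  floored <- p_hat == 0 & k_obs > 0
  p_hat[p_hat == 0] <- 1 / (2 * n_sets * n)
  if (any(floored)) {
    warnings <- c(warnings, paste0("p_hat floored at 1/(2*n_sets*n) for ",
                                   sum(floored), " sample(s)"))
  }
  p_binom <- binom_test_upper(k_obs, n, p_hat)
  z <- ifelse(is.na(bg_sd), NA_real_,
              ifelse(bg_sd > 0, (k_obs - bg_mean) / bg_sd,
                     ifelse(k_obs == bg_mean, 0,
                            sign(k_obs - bg_mean) * Inf)))
  if (anyNA(bg_sd)) {
    warnings <- c(warnings,
                  "z undefined with a single background set")
  } else if (any(bg_sd == 0)) {
    warnings <- c(warnings, paste0("degenerate background (sd = 0) for ",
                                   sum(bg_sd == 0), " sample(s)"))
  }
  q <- bh_adjust(p_binom)

  res <- data.frame(db$samples,
                    n = n, k_obs = as.integer(k_obs), p_hat = p_hat,
                    bg_mean = bg_mean, bg_sd = bg_sd, z = z,
                    p_binom = p_binom, q = q,
                    significant = q < config$q_threshold,
                    stringsAsFactors = FALSE)
  res <- res[order(res$q, -res$z, res$sample_id), , drop = FALSE]
  rownames(res) <- NULL

  structure(list(results = res, config = config,
                 input_rsids = input_rsids, used_rsids = used,
                 n_used = n, n_pruned = n_pruned, dropped = dropped,
                 matching = bg$matching_report, warnings = warnings),
            class = "snp_enrichment")
}

#' Per-variant overlap report
#'
#' Long-format table of the raw overlap bits behind an enrichment call:
#' one row per (SNP, biosample) pair, optionally restricted to a set of
#' biosamples (e.g. the significant samples of a prior run).
#'
#' @param db An `overlap_db`.
#' @param input_rsids SNPs to report (unknown rsids are dropped silently
#'   unless none resolve).
#' @param samples_filter Optional character vector of sample_ids.
#' @return Data frame with columns `rsid`, `sample_id`, `tissue`,
#'   `cell_type`, `mark`, `overlap` (0/1).
#' @export
per_variant_report <- function(db, input_rsids, samples_filter = NULL) {
  q <- query_overlaps(db, input_rsids)
  s <- db$samples
  keep <- if (is.null(samples_filter)) seq_len(nrow(s))
          else which(s$sample_id %in% samples_filter)
  m <- q$matrix[, keep, drop = FALSE]
  if (length(keep) == 0L || nrow(m) == 0L) {
    return(data.frame(rsid = character(), sample_id = character(),
                      tissue = character(), cell_type = character(),
                      mark = character(), overlap = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    rsid = rep(rownames(m), times = length(keep)),
    sample_id = rep(s$sample_id[keep], each = nrow(m)),
    tissue = rep(s$tissue[keep], each = nrow(m)),
    cell_type = rep(s$cell_type[keep], each = nrow(m)),
    mark = rep(s$mark[keep], each = nrow(m)),
    overlap = as.integer(m),
    stringsAsFactors = FALSE)
}

#' @export
print.snp_enrichment <- function(x, ...) {
  cat("SNP-set enrichment across", nrow(x$results), "biosamples\n")
  cat("  input SNPs used:", x$n_used,
      sprintf("(%d pruned by LD, %d dropped)", x$n_pruned,
              length(x$dropped)), "\n")
  cat("  background sets:", x$config$n_background_sets,
      " seed:", x$config$seed, "\n")
  nsig <- sum(x$results$significant)
  cat("  significant at q <", x$config$q_threshold, ":", nsig, "\n")
  if (nsig > 0L) {
    top <- utils::head(x$results[x$results$significant,
                                 c("sample_id", "tissue", "cell_type",
                                   "mark", "k_obs", "z", "q")], 10L)
    print(top, digits = 3)
  }
  invisible(x)
}

#' @export
summary.snp_enrichment <- function(object, ...) {
  r <- object$results
  cat("Call: enrichment of", object$n_used, "SNPs vs",
      object$config$n_background_sets, "matched background sets\n")
  cat("Samples tested:", nrow(r), "  significant (q <",
      object$config$q_threshold, "):", sum(r$significant), "\n")
  cat("q-value range: [", format(min(r$q), digits = 3), ",",
      format(max(r$q), digits = 3), "]\n")
  if (length(object$warnings) > 0L) {
    cat("Warnings:\n"); for (w in object$warnings) cat("  -", w, "\n")
  }
  print(utils::head(r, 10L), digits = 3)
  invisible(object)
}

#' @export
as.data.frame.snp_enrichment <- function(x, ...) x$results

#' Plot enrichment q-values per biosample
#'
#' Barplot of -log10(q) in result order, with the significance threshold
#' drawn as a dashed line.
#'
#' @param x A `snp_enrichment`.
#' @param top Number of top samples to show (default 25).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.snp_enrichment <- function(x, top = 25L, ...) {
  r <- utils::head(x$results, top)
  h <- -log10(pmax(r$q, 1e-300))
  graphics::barplot(h, names.arg = r$sample_id, las = 2,
                    col = ifelse(r$significant, "firebrick", "grey70"),
                    ylab = expression(-log[10](q)), ...)
  graphics::abline(h = -log10(x$config$q_threshold), lty = 2)
  invisible(x)
}
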
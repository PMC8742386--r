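#' Simulation configuration
#'
#' Defines the synthetic study conditions: a SNP universe with realistic
#' covariate distributions, biosample tracks whose per-SNP coverage
#' depends on those covariates (confounding), and optionally a spiked
#' biosample with multiplicatively elevated coverage in a chosen set of
#' decile bins.
#'
#' @param n_snps Number of SNPs (>= 100; default 200000).
#' @param n_chroms Number of chromosomes (default 22, named `chr1..`).
#' @param chrom_length Chromosome length in bp (default 1e8).
#' @param n_samples Number of biosamples (default 50).
#' @param base_overlap_rate Per-biosample baseline probability that a SNP
#'   falls inside the sample's intervals; scalar (recycled) or one value
#'   per sample, in (0, 1). Default 0.2, a typical SNP coverage for broad
#'   accessibility/histone domains.
#' @param confounding Named coefficients `c(maf=, tss=, gc=)` linking the
#'   standardised covariates (log10 scale for TSS distance) to coverage on
#'   the log scale: `p = base * exp(sum(beta * z))`, clipped to (0, 1).
#'   Defaults `c(maf = 0.4, tss = -0.4, gc = 0.4)`; set to zeros for
#'   unconfounded coverage.
#' @param spike Optional list `list(sample =, fold =, bins =)`: the given
#'   sample's coverage probability is multiplied by `fold` for SNPs whose
#'   `bin_key` is in `bins` (`NULL` bins = all SNPs).
#' @param decoy_intervals Number of intervals per sample placed between
#'   SNPs, covering no SNP (default 50).
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 200000L, n_chroms = 22L,
                       chrom_length = 1e8, n_samples = 50L,
                       base_overlap_rate = 0.2,
                       confounding = c(maf = 0.4, tss = -0.4, gc = 0.4),
                       spike = NULL, decoy_intervals = 50L, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(n_snps >= 100L, n_chroms >= 1L, n_samples >= 1L,
            all(base_overlap_rate > 0), all(base_overlap_rate < 1),
            all(c("maf", "tss", "gc") %in% names(confounding)))
  if (!is.null(spike)) {
    stopifnot(is.list(spike), !is.null(spike$sample), !is.null(spike$fold),
              spike$fold > 0)
  }
  structure(list(n_snps = as.integer(n_snps),
                 n_chroms = as.integer(n_chroms),
                 chrom_length = as.numeric(chrom_length),
                 n_samples = as.integer(n_samples),
                 base_overlap_rate = rep_len(base_overlap_rate,
                                             as.integer(n_samples)),
                 confounding = confounding[c("maf", "tss", "gc")],
                 spike = spike,
                 decoy_intervals = as.integer(decoy_intervals),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an annotated SNP universe
#'
#' Draws `rs1..rsN` with positions uniform (and unique) per chromosome,
#' MAF from a low-frequency-skewed scaled Beta on (0.005, 0.5), TSS
#' distance from an equal mixture of a near-TSS exponential (mean 10 kb)
#' and a long-tail exponential (mean 200 kb), and GC from a Beta centred
#' at 0.41. Deterministic per seed.
#'
#' @param cfg A `sim_config`.
#' @param path Optional TSV output path (see [write_snp_universe()]).
#' @return A `snp_universe` (decile bins not yet assigned).
#' @export
simulate_universe <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_snps
  uni <- .with_seed(cfg$seed, {
    chrom <- paste0("chr", sample.int(cfg$n_chroms, n, replace = TRUE))
    # unique positions per chromosome so every interval can be clipped
    # to cover exactly one SNP
    pos <- integer(n)
    for (cn in unique(chrom)) {
      i <- which(chrom == cn)
      pos[i] <- as.integer(sample.int(cfg$chrom_length, length(i)) - 1L)
    }
    maf <- 0.005 + (0.5 - 0.005) * stats::rbeta(n, 0.8, 3)
    near <- stats::runif(n) < 0.5
    tss <- ifelse(near, stats::rexp(n, 1 / 1e4), stats::rexp(n, 1 / 2e5))
    gc <- stats::rbeta(n, 20.5, 29.5)
    snp_universe(paste0("rs", seq_len(n)), chrom, pos, maf, round(tss), gc)
  })
  if (!is.null(path)) write_snp_universe(uni, path)
  uni
}

# Per-SNP log-scale covariate effect on coverage, standardised so the
# average multiplicative effect is ~1.
.confounding_factor <- function(universe, beta) {
  zs <- function(x) (x - mean(x)) / max(stats::sd(x), 1e-12)
  lin <- beta[["maf"]] * zs(universe$maf) +
    beta[["tss"]] * zs(log10(universe$tss_distance + 1)) +
    beta[["gc"]] * zs(universe$gc)
  exp(lin - mean(lin))
}

#' Simulate biosample tracks over a SNP universe
#'
#' Each SNP is covered by each biosample independently with probability
#' `base_rate[sample] * confounding_factor(SNP) * spike_multiplier`,
#' clipped to (0, 1). Covered SNPs receive a short interval around their
#' position, clipped so that it cannot reach any neighbouring SNP: the
#' generator's ground-truth coverage matrix is therefore exactly the
#' overlap matrix that [build_overlap_db()] recovers from the BED files.
#' Decoy intervals covering no SNP are added to exercise interval
#' handling. Deterministic per seed.
#'
#' @param universe A `snp_universe` from [simulate_universe()]. Decile
#'   bins are assigned here if missing (needed for bin-restricted spikes).
#' @param cfg The same `sim_config`.
#' @param dir Optional directory; when given, one BED per sample plus a
#'   samples manifest (`samples.tsv`) are written there.
#' @return A list with `tracks` (list of `track_sample`), `truth`
#'   (integer ground-truth coverage matrix, SNPs x samples) and
#'   `manifest` (sample metadata data frame).
#' @export
simulate_tracks <- function(universe, cfg, dir = NULL) {
  stopifnot(inherits(universe, "snp_universe"), inherits(cfg, "sim_config"))
  if (!isTRUE(attr(universe, "binned"))) {
    universe <- assign_decile_bins(universe)
  }
  n <- nrow(universe)
  S <- cfg$n_samples
  tissues <- c("blood", "brain", "liver", "lung", "heart", "kidney",
               "muscle", "skin", "gut", "pancreas")
  cells <- c("T cell", "B cell", "monocyte", "HSC", "neuron", "astrocyte",
             "hepatocyte", "fibroblast", "epithelial", "islet")
  marks <- c("DNase", "H3K4me1", "H3K4me3", "H3K27ac", "H3K36me3",
             "H3K9me3", "Enh", "TssA")
  consortia <- c("ENCODE", "Roadmap", "BLUEPRINT")
  cf <- .confounding_factor(universe, cfg$confounding)

  res <- .with_seed(cfg$seed + 1L, {
    meta <- data.frame(
      sample_id = sprintf("S%03d", seq_len(S)),
      tissue = sample(tissues, S, replace = TRUE),
      cell_type = sample(cells, S, replace = TRUE),
      mark = sample(marks, S, replace = TRUE),
      consortium = sample(consortia, S, replace = TRUE),
      stringsAsFactors = FALSE)
    truth <- matrix(0L, nrow = n, ncol = S,
                    dimnames = list(universe$rsid, meta$sample_id))
    tracks <- vector("list", S)
    pos_key <- paste(universe$chrom, universe$pos)
    # neighbour-clipped interval bounds per SNP, per chromosome
    lo <- integer(n); hi <- integer(n)
    for (cn in unique(universe$chrom)) {
      i <- which(universe$chrom == cn)
      o <- i[order(universe$pos[i])]
      p <- universe$pos[o]
      lo[o] <- pmax(p - 300L, c(0L, p[-length(p)] + 1L))
      hi[o] <- pmin(p + 301L, c(p[-1L], as.integer(cfg$chrom_length)))
    }
    for (j in seq_len(S)) {
      p_cov <- pmin(cfg$base_overlap_rate[[j]] * cf, 0.99)
      if (!is.null(cfg$spike) &&
          cfg$spike$sample == meta$sample_id[[j]]) {
        hit <- if (is.null(cfg$spike$bins)) rep(TRUE, n)
               else universe$bin_key %in% cfg$spike$bins
        p_cov[hit] <- pmin(p_cov[hit] * cfg$spike$fold, 0.99)
      }
      cov <- which(stats::runif(n) < p_cov)
      truth[cov, j] <- 1L
      w_lo <- as.integer(floor(stats::runif(length(cov), 0, 301)))
      w_hi <- as.integer(floor(stats::runif(length(cov), 1, 301)))
      iv <- data.frame(chrom = universe$chrom[cov],
                       start = pmax(universe$pos[cov] - w_lo, lo[cov]),
                       end = pmin(universe$pos[cov] + w_hi, hi[cov]),
                       stringsAsFactors = FALSE)
      # decoys: 2-bp intervals at coordinates occupied by no SNP
      if (cfg$decoy_intervals > 0L) {
        dc <- paste0("chr", sample.int(cfg$n_chroms, cfg$decoy_intervals,
                                       replace = TRUE))
        dpos <- floor(stats::runif(cfg$decoy_intervals, 0,
                                   cfg$chrom_length - 2))
        dk <- !(paste(dc, dpos) %in% pos_key) &
          !(paste(dc, dpos + 1) %in% pos_key)
        if (any(dk)) {
          iv <- rbind(iv, data.frame(chrom = dc[dk],
                                     start = as.integer(dpos[dk]),
                                     end = as.integer(dpos[dk] + 2),
                                     stringsAsFactors = FALSE))
        }
      }
      iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
      rownames(iv) <- NULL
      tracks[[j]] <- track_sample(meta$sample_id[[j]], meta$tissue[[j]],
                                  meta$cell_type[[j]], meta$mark[[j]],
                                  meta$consortium[[j]], iv)
    }
    list(tracks = tracks, truth = truth, manifest = meta)
  })

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    bed_paths <- file.path(dir, paste0(res$manifest$sample_id, ".bed"))
    for (j in seq_along(res$tracks)) {
      iv <- res$tracks[[j]]$intervals
      utils::write.table(iv, bed_paths[[j]], sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    man <- cbind(res$manifest, bed_path = basename(bed_paths))
    utils::write.table(man, file.path(dir, "samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  res
}

#' Simulate an input SNP set hitting one biosample's elements
#'
#' Emulates a GWAS whose hits fall preferentially in one cell type's
#' regulatory elements: a fixed fraction of the set is drawn (without
#' replacement) from SNPs covered by the target biosample, the remainder
#' uniformly from the rest of the universe.
#'
#' @param universe A `snp_universe`.
#' @param truth Ground-truth coverage matrix from [simulate_tracks()].
#' @param target_sample Column (sample_id) of `truth` to enrich towards.
#' @param size Set size (>= 5, the minimum analysable phenotype size).
#' @param enrichment_fraction Fraction of the set drawn from covered SNPs,
#'   in `[0, 1]`; 0 gives a null (uniform) input set.
#' @param seed Integer seed.
#' @return Character vector of rsids of length `size`.
#' @export
simulate_input_set <- function(universe, truth, target_sample, size,
                               enrichment_fraction, seed) {
  stopifnot(inherits(universe, "snp_universe"), size >= 5L)
  if (enrichment_fraction < 0 || enrichment_fraction > 1) {
    stop("enrichment_fraction must lie in [0, 1]")
  }
  j <- match(target_sample, colnames(truth))
  if (is.na(j)) stop("unknown target sample: ", target_sample)
  n_cov <- round(enrichment_fraction * size)
  covered <- which(truth[, j] > 0L)
  if (length(covered) < n_cov) {
    stop("target sample covers fewer SNPs (", length(covered),
         ") than requested (", n_cov, ")")
  }
  .with_seed(seed, {
    hit <- sample(covered, n_cov)
    rest <- sample(setdiff(seq_len(nrow(universe)), hit), size - n_cov)
    universe$rsid[c(hit, rest)]
  })
}

#' False-positive-rate experiment on uniform-random input sets
#'
#' Draws uniform-random input SNP sets of the given sizes from the
#' universe, runs the full enrichment pipeline on each, and counts
#' sample-level results significant at `q < q_threshold`. One test is one
#' (input set, biosample) pair; rates are reported per 100,000 tests,
#' overall and per set size.
#'
#' @param db An `overlap_db`.
#' @param universe A binned `snp_universe`.
#' @param set_sizes Input set sizes (default `c(5,10,15,20,30,40,50,100)`).
#' @param sets_per_size Random sets drawn per size (default 1000).
#' @param config An `enrichment_config`; its seed is the master seed from
#'   which every set's draw and background seed derive.
#' @param progress Print a line per size (default `FALSE`).
#' @return An `fpr_report`: data frame
#'   `set_size n_sets n_tests n_significant rate_per_100k` with one row
#'   per size plus an `"overall"` row.
#' @export
fpr_experiment <- function(db, universe,
                           set_sizes = c(5L, 10L, 15L, 20L, 30L, 40L,
                                         50L, 100L),
                           sets_per_size = 1000L,
                           config = enrichment_config(),
                           progress = FALSE) {
  stopifnot(inherits(db, "overlap_db"), inherits(universe, "snp_universe"))
  if (!isTRUE(attr(universe, "binned"))) {
    universe <- assign_decile_bins(universe)
  }
  n_samples <- nrow(db$samples)
  # all input sets drawn up front from one seeded stream
  draws <- .with_seed(config$seed, {
    lapply(set_sizes, function(sz) {
      lapply(seq_len(sets_per_size),
             function(i) universe$rsid[sample.int(nrow(universe), sz)])
    })
  })
  rows <- vector("list", length(set_sizes))
  counter <- 0L
  for (si in seq_along(set_sizes)) {
    sz <- set_sizes[[si]]
    nsig <- 0L
    for (i in seq_len(sets_per_size)) {
      counter <- counter + 1L
      run_cfg <- enrichment_config(
        n_background_sets = config$n_background_sets,
        r2_threshold = config$r2_threshold,
        q_threshold = config$q_threshold,
        seed = (config$seed + counter) %% .Machine$integer.max,
        exclude_input_from_background =
          config$exclude_input_from_background)
      fit <- snp_enrichment(db, universe, draws[[si]][[i]],
                            ld = NULL, config = run_cfg)
      nsig <- nsig + sum(fit$results$significant)
    }
    n_tests <- sets_per_size * n_samples
    rows[[si]] <- data.frame(set_size = as.character(sz),
                             n_sets = sets_per_size, n_tests = n_tests,
                             n_significant = nsig,
                             rate_per_100k = 1e5 * nsig / n_tests,
                             stringsAsFactors = FALSE)
    if (progress) {
      message("size ", sz, ": ", nsig, " significant / ", n_tests,
              " tests")
    }
  }
  rep_df <- do.call(rbind, rows)
  total <- data.frame(set_size = "overall",
                      n_sets = sum(rep_df$n_sets),
                      n_tests = sum(rep_df$n_tests),
                      n_significant = sum(rep_df$n_significant),
                      rate_per_100k = 1e5 * sum(rep_df$n_significant) /
                        sum(rep_df$n_tests),
                      stringsAsFactors = FALSE)
  out <- rbind(rep_df, total)
  rownames(out) <- NULL
  class(out) <- c("fpr_report", "data.frame")
  out
}
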
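# Shared fixtures and independent oracles, built in code at test time.

# small hand-made universe with controllable covariates
tiny_universe <- function(n = 12L, maf = NULL, tss = NULL, gc = NULL) {
  snp_universe(rsid = paste0("rs", seq_len(n)),
               chrom = rep("chr1", n),
               pos = seq(100L, by = 1000L, length.out = n),
               maf = if (is.null(maf)) rep(0.25, n) else maf,
               tss_distance = if (is.null(tss)) rep(5000, n) else tss,
               gc = if (is.null(gc)) rep(0.4, n) else gc)
}

# write a universe TSV and return its path
write_universe_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# independent oracle: decile bin by counting internal empirical deciles
# strictly below the value
oracle_decile_bin <- function(x) {
  edges <- stats::quantile(x, probs = seq(0.1, 0.9, 0.1), names = FALSE)
  vapply(x, function(v) 1L + sum(edges < v), integer(1))
}

# independent oracle: upper-tail binomial probability by pmf summation
# (log-space pmf, smallest terms summed first)
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  j <- n:k
  sum(exp(lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)))
}

# independent oracle: literal BH step-up, q_(i) = min_{j>=i} p_(j)*m/j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m),
              function(i) min(1, min(ps[i:m] * m / (i:m))),
              numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# independent oracle: naive double-loop SNP x sample overlap matrix
oracle_overlap_matrix <- function(universe, tracks) {
  m <- matrix(0L, nrow = nrow(universe), ncol = length(tracks))
  for (i in seq_len(nrow(universe))) {
    for (j in seq_along(tracks)) {
      iv <- tracks[[j]]$intervals
      hit <- any(iv$chrom == universe$chrom[[i]] &
                   iv$start <= universe$pos[[i]] &
                   universe$pos[[i]] < iv$end)
      m[i, j] <- as.integer(hit)
    }
  }
  dimnames(m) <- list(universe$rsid,
                      vapply(tracks, function(t) t$sample_id,
                             character(1)))
  m
}

# independent oracle: naive O(n^3) complete-linkage agglomeration;
# returns the sorted sequence of merge heights
oracle_complete_linkage_heights <- function(m) {
  d <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        h <- max(d[clusters[[a]], clusters[[b]]])
        if (h < best[[1L]]) best <- c(h, a, b)
      }
    }
    heights <- c(heights, best[[1L]])
    merged <- c(clusters[[best[[2L]]]], clusters[[best[[3L]]]])
    clusters <- clusters[-c(best[[2L]], best[[3L]])]
    clusters <- c(clusters, list(merged))
  }
  heights
}

# random track over a universe: a few intervals per chromosome
random_track <- function(universe, id, n_intervals = 10L,
                         width_range = c(200L, 3000L)) {
  chroms <- unique(universe$chrom)
  cn <- sample(chroms, n_intervals, replace = TRUE)
  start <- sapply(cn, function(x) sample.int(max(universe$pos) + 5000L, 1L))
  w <- sample(width_range[[1L]]:width_range[[2L]], n_intervals,
              replace = TRUE)
  track_sample(id, "tissue", "cell", "DNase", "SIM",
               data.frame(chrom = cn, start = start, end = start + w,
                          stringsAsFactors = FALSE))
}

# shared moderate-scale synthetic study for enrichment-level tests
sim_small_study <- function(n_snps = 20000L, n_samples = 20L, seed = 404L,
                            ...) {
  cfg <- sim_config(n_snps = n_snps, n_chroms = 4L, chrom_length = 5e7,
                    n_samples = n_samples, seed = seed, ...)
  uni <- assign_decile_bins(simulate_universe(cfg))
  tr <- simulate_tracks(uni, cfg)
  list(cfg = cfg, universe = uni, tracks = tr$tracks, truth = tr$truth,
       db = build_overlap_db(uni, tr$tracks))
}
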
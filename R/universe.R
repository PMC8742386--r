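#' Read an annotated SNP universe from a TSV file
#'
#' The SNP universe is the population of variants from which matched
#' background sets are drawn (for real analyses, typically all common
#' variants of a reference panel). Each SNP carries the three matching
#' covariates: minor allele frequency (MAF), absolute distance to the
#' nearest transcription start site (TSS), and the GC fraction of a fixed
#' window around the variant (by convention +/- 50 bp for real data; the
#' value is consumed as given, the window is never recomputed here).
#'
#' @param path Path to a tab-separated file with header columns
#'   `rsid`, `chrom`, `pos`, `maf`, `tss_distance`, `gc`. Positions are
#'   0-based.
#' @return A `snp_universe` object: a data frame of SNP records. Decile
#'   bins are not yet assigned; see [assign_decile_bins()].
#' @seealso [assign_decile_bins()], [snp_universe()]
#' @export
read_snp_universe <- function(path) {
  if (!file.exists(path)) stop("SNP universe file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("rsid", "chrom", "pos", "maf", "tss_distance", "gc")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("SNP universe file lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("SNP universe file is empty: ", path)
  snp_universe(df$rsid, df$chrom, df$pos, df$maf, df$tss_distance, df$gc)
}

#' Construct a SNP universe from vectors
#'
#' @param rsid Character vector of unique SNP identifiers.
#' @param chrom Chromosome names. `"chr1"` and `"1"` are distinct names;
#'   no aliasing is applied.
#' @param pos 0-based base positions (non-negative integers).
#' @param maf Minor allele frequencies in `[0, 0.5]`.
#' @param tss_distance Non-negative distances (bp) to the nearest TSS
#'   (unsigned; strand is ignored).
#' @param gc GC fractions in `[0, 1]`.
#' @return A `snp_universe` data frame.
#' @export
snp_universe <- function(rsid, chrom, pos, maf, tss_distance, gc) {
  df <- data.frame(rsid = as.character(rsid), chrom = as.character(chrom),
                   pos = as.integer(pos), maf = as.numeric(maf),
                   tss_distance = as.numeric(tss_distance),
                   gc = as.numeric(gc), stringsAsFactors = FALSE)
  dup <- df$rsid[duplicated(df$rsid)]
  if (length(dup) > 0L) stop("duplicate rsid ", dup[[1L]], " in SNP universe")
  .check_range(df$maf, 0, 0.5, "maf")
  .check_range(df$gc, 0, 1, "gc")
  .check_range(df$tss_distance, 0, Inf, "tss_distance")
  .check_range(df$pos, 0, Inf, "pos")
  rownames(df) <- NULL
  class(df) <- c("snp_universe", "data.frame")
  attr(df, "binned") <- FALSE
  df
}

.check_range <- function(x, lo, hi, field) {
  bad <- which(!is.finite(x) | x < lo | x > hi)
  if (length(bad) > 0L) {
    stop("field '", field, "' out of range [", lo, ", ", hi, "] at row ",
         bad[[1L]], " (value ", x[bad[[1L]]], ")")
  }
  invisible(TRUE)
}

#' Assign covariate decile bins to a SNP universe
#'
#' Computes empirical deciles (quantiles at 0.1, ..., 0.9) of each matching
#' covariate over the whole universe and assigns every SNP an ordered
#' triple of decile indices `(maf_bin, tss_bin, gc_bin)`, each in 1..10.
#' A value falling exactly on a bin edge is assigned to the lower bin.
#' Degenerate covariate distributions (heavy ties) collapse bins; with all
#' values identical every SNP lands in bin 1.
#'
#' @param universe A `snp_universe`.
#' @return The universe with `maf_bin`, `tss_bin`, `gc_bin` and an integer
#'   `bin_key` column (0..999 encoding the triple), plus a `decile_edges`
#'   attribute holding, per covariate, the 11 boundary values
#'   (min, 9 internal deciles, max), and a precomputed bin index used by
#'   the background sampler.
#' @export
assign_decile_bins <- function(universe) {
  stopifnot(inherits(universe, "snp_universe"))
  covs <- c(maf = "maf", tss = "tss_distance", gc = "gc")
  edges <- lapply(covs, function(col) {
    x <- universe[[col]]
    c(min(x), stats::quantile(x, probs = seq(0.1, 0.9, by = 0.1),
                              names = FALSE, type = 7), max(x))
  })
  bins <- lapply(covs, function(col) {
    decile_bin(universe[[col]], edges[[if (col == "tss_distance") "tss"
                                       else col]])
  })
  universe$maf_bin <- bins$maf
  universe$tss_bin <- bins$tss
  universe$gc_bin <- bins$gc
  universe$bin_key <- bin_key(bins$maf, bins$tss, bins$gc)
  attr(universe, "decile_edges") <- edges
  attr(universe, "binned") <- TRUE
  # bin index: universe row numbers per occupied bin key, for O(1) lookup
  attr(universe, "bin_index") <-
    split(seq_len(nrow(universe)), universe$bin_key)
  universe
}

#' Decile bin of values given boundary values
#'
#' @param x Numeric vector.
#' @param edges 11 boundary values (min, internal deciles, max) as stored
#'   by [assign_decile_bins()]; only the 9 internal edges determine bins.
#' @return Integer bins in 1..10; values exactly on an edge go to the
#'   lower bin.
#' @export
decile_bin <- function(x, edges) {
  internal <- edges[2:10]
  findInterval(x, internal, left.open = TRUE) + 1L
}

#' Encode a decile triple as a single integer key
#'
#' @param maf_bin,tss_bin,gc_bin Integer decile indices in 1..10.
#' @return Integer in 0..999.
#' @export
bin_key <- function(maf_bin, tss_bin, gc_bin) {
  (maf_bin - 1L) * 100L + (tss_bin - 1L) * 10L + (gc_bin - 1L)
}

.decode_bin_key <- function(key) {
  cbind(maf = key %/% 100L + 1L, tss = (key %/% 10L) %% 10L + 1L,
        gc = key %% 10L + 1L)
}

#' Write a SNP universe to a TSV file
#'
#' @param universe A `snp_universe`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_universe <- function(universe, path) {
  utils::write.table(universe[, c("rsid", "chrom", "pos", "maf",
                                  "tss_distance", "gc")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.snp_universe <- function(x, ...) {
  cat("SNP universe:", nrow(x), "variants on",
      length(unique(x$chrom)), "chromosome(s);",
      if (isTRUE(attr(x, "binned"))) "decile bins assigned"
      else "decile bins not yet assigned", "\n")
  invisible(x)
}
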
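#' Read intervals from a BED file
#'
#' Parses the first three BED columns (chrom, start, end; 0-based
#' half-open). `track`, `browser`, comment (`#`) and blank lines are
#' skipped. Overlapping or adjacent intervals are not merged; point
#' membership tests are unaffected by merging.
#'
#' @param path Path to a BED3+ file.
#' @param strip_chr_prefix If `TRUE`, a leading `"chr"` is removed from
#'   chromosome names at load. By default no aliasing is performed:
#'   `"chr1"` and `"1"` are distinct names.
#' @return A data frame with columns `chrom` (character), `start`, `end`
#'   (integer, 0-based half-open).
#' @export
read_bed <- function(path, strip_chr_prefix = FALSE) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- idx[which(nf < 3L)[1L]]
    stop("BED line ", bad, " has fewer than 3 fields in ", path)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  s_chr <- vapply(fields, `[[`, character(1), 2L)
  e_chr <- vapply(fields, `[[`, character(1), 3L)
  bad_int <- which(!grepl("^[0-9]+$", s_chr) | !grepl("^[0-9]+$", e_chr))
  if (length(bad_int) > 0L) {
    stop("BED line ", idx[bad_int[[1L]]],
         " has non-integer coordinates in ", path)
  }
  start <- as.integer(s_chr); end <- as.integer(e_chr)
  bad_iv <- which(start >= end)
  if (length(bad_iv) > 0L) {
    stop("BED line ", idx[bad_iv[[1L]]], " has start >= end (empty interval) in ",
         path)
  }
  if (strip_chr_prefix) chrom <- sub("^chr", "", chrom)
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' One biosample's annotation track
#'
#' Bundles a biosample's genomic intervals with its metadata: tissue,
#' cell type, assay or mark (e.g. `DNase`, `H3K4me1`, a chromatin-state
#' label), and originating consortium.
#'
#' @param sample_id Unique sample identifier.
#' @param tissue,cell_type,mark,consortium Metadata strings.
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open), as returned by [read_bed()].
#' @return A `track_sample` object.
#' @export
track_sample <- function(sample_id, tissue, cell_type, mark, consortium,
                         intervals) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) > 0L && any(intervals$start >= intervals$end)) {
    stop("track ", sample_id, " has an interval with start >= end")
  }
  structure(list(sample_id = as.character(sample_id),
                 tissue = as.character(tissue),
                 cell_type = as.character(cell_type),
                 mark = as.character(mark),
                 consortium = as.character(consortium),
                 intervals = intervals),
            class = "track_sample")
}

#' Read a collection of tracks from a samples manifest
#'
#' The manifest is a TSV with columns
#' `sample_id  tissue  cell_type  mark  consortium  bed_path`; relative
#' BED paths are resolved against the manifest's directory.
#'
#' @param path Manifest path.
#' @param strip_chr_prefix Passed to [read_bed()].
#' @return A list of `track_sample` objects, in manifest row order.
#' @export
read_track_manifest <- function(path, strip_chr_prefix = FALSE) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "tissue", "cell_type", "mark", "consortium",
                "bed_path")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("samples manifest lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  base <- dirname(path)
  lapply(seq_len(nrow(df)), function(i) {
    bp <- df$bed_path[[i]]
    if (!file.exists(bp)) bp <- file.path(base, df$bed_path[[i]])
    if (!file.exists(bp)) {
      stop("manifest row ", i, " (sample ", df$sample_id[[i]],
           "): BED file not found: ", df$bed_path[[i]])
    }
    track_sample(df$sample_id[[i]], df$tissue[[i]], df$cell_type[[i]],
                 df$mark[[i]], df$consortium[[i]],
                 read_bed(bp, strip_chr_prefix = strip_chr_prefix))
  })
}

#' Point membership of SNP positions in an interval set
#'
#' A SNP at 0-based position `p` overlaps an interval `(chrom, s, e)` iff
#' the chromosome matches and `s <= p < e` (half-open convention).
#'
#' @param chrom Chromosome name (scalar or vector parallel to `pos`).
#' @param pos 0-based position(s).
#' @param intervals Interval data frame (`chrom`, `start`, `end`).
#' @return Logical vector, one element per position.
#' @export
snp_overlaps <- function(chrom, pos, intervals) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  out <- logical(n)
  if (nrow(intervals) == 0L) return(out)
  for (cn in unique(chrom)) {
    qi <- which(chrom == cn)
    iv <- intervals[intervals$chrom == cn, , drop = FALSE]
    if (nrow(iv) == 0L) next
    ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    q <- IRanges::IRanges(start = pos[qi] + 1L, width = 1L)
    out[qi] <- IRanges::overlapsAny(q, ir)
  }
  out
}

#' Build the SNP-by-biosample overlap database
#'
#' Computes, for every SNP in the universe and every track, whether the
#' SNP position falls inside one of the track's intervals, and stores the
#' result as a boolean matrix (conceptually one bitstring per SNP, one bit
#' per sample in manifest order). SNPs on chromosomes absent from a track
#' simply get bit 0.
#'
#' @param universe A `snp_universe`.
#' @param tracks List of `track_sample` objects (at least one).
#' @return An `overlap_db` object with elements `rsid`, `samples`
#'   (metadata data frame), `bits` (integer 0/1 matrix, SNPs x samples)
#'   and `provenance`.
#' @export
build_overlap_db <- function(universe, tracks) {
  stopifnot(inherits(universe, "snp_universe"))
  if (length(tracks) < 1L) stop("at least one track is required")
  if (nrow(universe) < 1L) stop("universe is empty")
  ids <- vapply(tracks, function(t) t$sample_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) stop("duplicate sample_id ", dup[[1L]])
  n <- nrow(universe)
  bits <- matrix(0L, nrow = n, ncol = length(tracks),
                 dimnames = list(universe$rsid, ids))
  for (j in seq_along(tracks)) {
    bits[, j] <- as.integer(snp_overlaps(universe$chrom, universe$pos,
                                         tracks[[j]]$intervals))
  }
  samples <- data.frame(
    sample_id = ids,
    tissue = vapply(tracks, function(t) t$tissue, character(1)),
    cell_type = vapply(tracks, function(t) t$cell_type, character(1)),
    mark = vapply(tracks, function(t) t$mark, character(1)),
    consortium = vapply(tracks, function(t) t$consortium, character(1)),
    stringsAsFactors = FALSE)
  structure(list(rsid = universe$rsid, samples = samples, bits = bits,
                 provenance = list(format = "epienrich-db",
                                   version = 1L,
                                   n_snps = n,
                                   n_samples = length(tracks))),
            class = "overlap_db")
}

#' Query overlap bits for a set of SNPs
#'
#' @param db An `overlap_db`.
#' @param rsids Character vector of SNP identifiers.
#' @return A list with `matrix` (logical, rows in input order for the
#'   rsids found in the database) and `dropped` (rsids absent from the
#'   database). All rsids unknown is an error.
#' @export
query_overlaps <- function(db, rsids) {
  stopifnot(inherits(db, "overlap_db"))
  rsids <- as.character(rsids)
  idx <- match(rsids, db$rsid)
  dropped <- rsids[is.na(idx)]
  found <- which(!is.na(idx))
  if (length(found) == 0L) stop("no input SNPs found in database")
  m <- db$bits[idx[found], , drop = FALSE] > 0L
  rownames(m) <- rsids[found]
  list(matrix = m, dropped = dropped)
}

#' Write an overlap database to a single portable text file
#'
#' The format is line-oriented: a versioned header, one `#sample` line per
#' biosample (bit order equals sample line order), then one
#' `rsid<TAB>bitstring` line per SNP, sorted by rsid for binary-search
#' lookup by external tools.
#'
#' @param db An `overlap_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_db <- function(db, path) {
  stopifnot(inherits(db, "overlap_db"))
  ord <- order(db$rsid, method = "radix")
  bitstrings <- apply(db$bits[ord, , drop = FALSE], 1L, paste,
                      collapse = "")
  s <- db$samples
  header <- c(
    paste0("#epienrich-db\t", db$provenance$version),
    paste0("#n_snps\t", nrow(db$bits)),
    paste0("#n_samples\t", nrow(s)),
    paste("#sample", s$sample_id, s$tissue, s$cell_type, s$mark,
          s$consortium, sep = "\t"))
  writeLines(c(header, paste(db$rsid[ord], bitstrings, sep = "\t")), path)
  invisible(path)
}

#' Read an overlap database written by [write_overlap_db()]
#'
#' @param path Database file path.
#' @return An `overlap_db`.
#' @export
read_overlap_db <- function(path) {
  if (!file.exists(path)) stop("database file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[[1L]], "#epienrich-db")) {
    stop("not an epienrich overlap database: ", path)
  }
  is_header <- startsWith(lines, "#")
  hdr <- lines[is_header]
  sample_lines <- hdr[startsWith(hdr, "#sample\t")]
  sf <- do.call(rbind, strsplit(sample_lines, "\t", fixed = TRUE))
  samples <- data.frame(sample_id = sf[, 2L], tissue = sf[, 3L],
                        cell_type = sf[, 4L], mark = sf[, 5L],
                        consortium = sf[, 6L], stringsAsFactors = FALSE)
  body <- strsplit(lines[!is_header], "\t", fixed = TRUE)
  rsid <- vapply(body, `[[`, character(1), 1L)
  bitstr <- vapply(body, `[[`, character(1), 2L)
  bits <- matrix(as.integer(unlist(strsplit(bitstr, "", fixed = TRUE))),
                 nrow = length(rsid), ncol = nrow(samples), byrow = TRUE,
                 dimnames = list(rsid, samples$sample_id))
  structure(list(rsid = rsid, samples = samples, bits = bits,
                 provenance = list(format = "epienrich-db",
                                   version = as.integer(
                                     strsplit(lines[[1L]], "\t")[[1L]][2L]),
                                   n_snps = length(rsid),
                                   n_samples = nrow(samples))),
            class = "overlap_db")
}

#' @export
print.overlap_db <- function(x, ...) {
  cat("Overlap database:", nrow(x$bits), "SNPs x", ncol(x$bits),
      "biosamples;", sum(x$bits), "overlap bits set\n")
  invisible(x)
}
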
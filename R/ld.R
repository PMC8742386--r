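#' Construct a sparse pairwise LD table
#'
#' Stores pairwise linkage-disequilibrium r-squared values symmetrically:
#' `r2(a, b) == r2(b, a)`, `r2(a, a)` is treated as 1, and any absent pair
#' has r2 = 0.
#'
#' @param rsid_a,rsid_b Character vectors of SNP identifiers (paired).
#' @param r2 Numeric r-squared values in `[0, 1]`.
#' @return An `ld_table` object.
#' @export
ld_table <- function(rsid_a = character(), rsid_b = character(),
                     r2 = numeric()) {
  stopifnot(length(rsid_a) == length(rsid_b),
            length(rsid_a) == length(r2))
  if (length(r2) > 0L) .check_range(r2, 0, 1, "r2")
  env <- new.env(hash = TRUE, parent = emptyenv())
  a <- as.character(rsid_a); b <- as.character(rsid_b)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  for (i in seq_along(key)) assign(key[[i]], r2[[i]], envir = env)
  structure(list(pairs = env, n_records = length(key)), class = "ld_table")
}

#' Read a pairwise LD table from a TSV file
#'
#' Expects columns `rsid_a`, `rsid_b`, `r2`; the symmetric closure is
#' applied on load, so each pair needs to be listed only once.
#'
#' @param path Path to the TSV file.
#' @return An `ld_table`.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("LD table file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("rsid_a", "rsid_b", "r2")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("LD table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  ld_table(df$rsid_a, df$rsid_b, df$r2)
}

#' Look up pairwise r-squared values
#'
#' @param ld An `ld_table`.
#' @param a,b Character vectors of rsids (recycled against each other).
#' @return Numeric vector of r2 values; 1 on the diagonal, 0 for pairs not
#'   present in the table.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_table"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  out <- vapply(seq_len(n), function(i) {
    if (a[[i]] == b[[i]]) return(1)
    v <- get0(key[[i]], envir = ld$pairs, ifnotfound = 0)
    as.numeric(v)
  }, numeric(1))
  out
}

#' Greedy LD pruning of an ordered SNP list
#'
#' Scans the input in order and retains a SNP only if its r-squared with
#' every previously retained SNP is below the threshold; the first SNP is
#' always retained. Dropped SNPs do not shield later ones: candidates are
#' compared against retained SNPs only. Output preserves input order and
#' the operation is idempotent.
#'
#' @param rsids Character vector (possibly empty), in priority order.
#' @param ld An `ld_table`, or `NULL` for no pruning.
#' @param r2_threshold SNPs at `r2 >= r2_threshold` with a retained SNP
#'   are excluded (default 0.8). Must be in (0, 1].
#' @return The retained rsids, a subsequence of the input.
#' @export
ld_prune <- function(rsids, ld, r2_threshold = 0.8) {
  stopifnot(is.numeric(r2_threshold), length(r2_threshold) == 1L,
            r2_threshold > 0, r2_threshold <= 1)
  rsids <- as.character(rsids)
  if (length(rsids) == 0L || is.null(ld)) return(rsids)
  stopifnot(inherits(ld, "ld_table"))
  kept <- character(0)
  for (r in rsids) {
    if (length(kept) == 0L || all(ld_r2(ld, rep(r, length(kept)), kept) <
                                  r2_threshold)) {
      kept <- c(kept, r)
    }
  }
  kept
}

#' @export
print.ld_table <- function(x, ...) {
  cat("LD table:", x$n_records, "stored pair(s)\n")
  invisible(x)
}
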
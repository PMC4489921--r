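#' Binned contact counts
#'
#' Sparse symmetric per-chromosome contact matrix at a fixed bin size, stored
#' as upper-triangle triplets (1-based bin indices, `i <= j`).
#'
#' @param entries data.frame/data.table with integer columns `i`, `j`, `count`.
#' @param bin_size bin width in bp.
#' @param n_bins number of bins on the chromosome.
#' @return object of class `contact_counts`.
#' @export
contact_counts <- function(entries, bin_size, n_bins) {
  dt <- as.data.table(entries)
  if (!all(c("i", "j", "count") %in% names(dt)))
    stopf("entries must have columns i, j, count")
  dt <- dt[, .(i = as.integer(i), j = as.integer(j), count = as.numeric(count))]
  if (nrow(dt)) {
    if (any(dt$i > dt$j)) stopf("entries must satisfy i <= j")
    if (any(dt$i < 1L) || any(dt$j > n_bins)) stopf("bin index out of range")
    if (any(dt$count < 0)) stopf("counts must be non-negative")
    dt <- dt[count > 0]
    if (anyDuplicated(dt, by = c("i", "j")))
      dt <- dt[, .(count = sum(count)), by = .(i, j)]
  }
  setkey(dt, i, j)
  structure(list(entries = dt, bin_size = bin_size,
                 n_bins = as.integer(n_bins), total = sum(dt$count)),
            class = "contact_counts")
}

#' @export
print.contact_counts <- function(x, ...) {
  cat(sprintf("<contact_counts> %d bins @ %g Kb, %d non-zero cells, total %.4g\n",
              x$n_bins, x$bin_size / 1e3, nrow(x$entries), x$total))
  invisible(x)
}

#' @describeIn contact_counts dense symmetric matrix (small inputs only).
#' @param x a `contact_counts` object.
#' @param ... unused.
#' @export
as.matrix.contact_counts <- function(x, ...) {
  if (x$n_bins > 3000) stopf("refusing to densify %d bins", x$n_bins)
  m <- matrix(0, x$n_bins, x$n_bins)
  if (nrow(x$entries)) {
    m[cbind(x$entries$i, x$entries$j)] <- x$entries$count
    m[cbind(x$entries$j, x$entries$i)] <- x$entries$count
  }
  m
}

# vectorized count lookup, zeros for absent cells; i <= j required
contact_lookup <- function(counts, i, j) {
  q <- data.table(i = as.integer(i), j = as.integer(j))
  res <- counts$entries[q, on = c("i", "j")]$count
  res[is.na(res)] <- 0
  res
}

#' Read / write contact triplets
#'
#' Plain TSV with columns `bin1`, `bin2`, `count` (0-based bin indices, as in
#' single-resolution text dumps of binned contact data). Gzip is handled by
#' file extension.
#'
#' @param path file path (`.tsv` or `.tsv.gz`).
#' @param bin_size,n_bins grid description (stored in a header comment on
#'   write; required on read if the file lacks one).
#' @return [contact_counts()] for `read_contacts`; invisible path for
#'   `write_contacts`.
#' @export
read_contacts <- function(path, bin_size = NULL, n_bins = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- lines[1]
  if (startsWith(hdr, "#cohesim")) {
    kv <- strsplit(strsplit(sub("^#cohesim\\s+", "", hdr), "\\s+")[[1]], "=")
    vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    bin_size <- bin_size %||% as.numeric(vals[["bin_size"]])
    n_bins <- n_bins %||% as.integer(vals[["n_bins"]])
  }
  if (is.null(bin_size) || is.null(n_bins))
    stopf("bin_size and n_bins required (no header in %s)", path)
  body <- lines[!startsWith(lines, "#")]
  dt <- fread(text = body, col.names = c("bin1", "bin2", "count"))
  contact_counts(data.table(i = dt$bin1 + 1L, j = dt$bin2 + 1L,
                            count = dt$count),
                 bin_size = bin_size, n_bins = n_bins)
}

#' @rdname read_contacts
#' @param counts a `contact_counts` object.
#' @export
write_contacts <- function(counts, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#cohesim bin_size=%g n_bins=%d",
                     counts$bin_size, counts$n_bins), con)
  e <- counts$entries
  writeLines(paste(e$i - 1L, e$j - 1L,
                   format(e$count, trim = TRUE, scientific = FALSE),
                   sep = "\t"), con)
  invisible(path)
}
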
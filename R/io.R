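#' Write genomic intervals as BED
#'
#' 0-based half-open intervals; the `name` column carries class labels where
#' available.
#'
#' @param x data.frame with `start`/`end` (bp) or `start_bin`/`end_bin`
#'   columns, optionally `name` or `class`.
#' @param path output path.
#' @param chrom chromosome name for column 1.
#' @param bin_size required if `x` carries bin coordinates.
#' @export
write_bed <- function(x, path, chrom = "chrS", bin_size = NULL) {
  dt <- as.data.table(x)
  if (all(c("start_bin", "end_bin") %in% names(dt))) {
    if (is.null(bin_size)) stopf("bin_size required for bin coordinates")
    dt[, `:=`(start = (start_bin - 1) * bin_size, end = end_bin * bin_size)]
  } else if ("pos" %in% names(dt) && !"start" %in% names(dt)) {
    dt[, `:=`(start = floor(pos), end = floor(pos) + 1)]
  }
  if (!all(c("start", "end") %in% names(dt)))
    stopf("x must have start/end, start_bin/end_bin, or pos")
  nm <- if ("name" %in% names(dt)) dt$name
        else if ("class" %in% names(dt)) dt$class
        else "."
  out <- data.table(chrom = chrom, start = format(dt$start, scientific = FALSE, trim = TRUE),
                    end = format(dt$end, scientific = FALSE, trim = TRUE), name = nm)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a per-bin track as bedGraph
#'
#' @param values numeric per-bin vector (NA bins are skipped).
#' @param bin_size bin width in bp.
#' @param path output path.
#' @param chrom chromosome name.
#' @export
write_bedgraph <- function(values, bin_size, path, chrom = "chrS") {
  keep <- is.finite(values)
  idx <- which(keep)
  out <- data.table(chrom = chrom,
                    start = format((idx - 1) * bin_size, scientific = FALSE, trim = TRUE),
                    end = format(idx * bin_size, scientific = FALSE, trim = TRUE),
                    value = values[idx])
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track onto a fixed bin grid
#'
#' @param path bedGraph path.
#' @param bin_size bin width in bp.
#' @param n_bins number of bins.
#' @return numeric per-bin vector (0 where absent).
#' @export
read_bedgraph <- function(path, bin_size, n_bins) {
  dt <- fread(path, col.names = c("chrom", "start", "end", "value"))
  v <- numeric(n_bins)
  idx <- dt$start %/% bin_size + 1L
  ok <- idx >= 1 & idx <= n_bins
  v[idx[ok]] <- dt$value[ok]
  v
}

#' Active/passive intra-domain intensity ratio
#'
#' Linear-scale contact enrichment of active versus passive domains at
#' intermediate separations: per class, the summed observed counts over
#' intra-domain cells divided by their summed decay/bias expectation (the
#' unbiased estimator of mean linear enrichment), then the active/passive
#' ratio.
#'
#' @param enrich a [compute_enrichment()] object.
#' @param domains classified `domain_set` or generator domains table (needs a
#'   `class` column).
#' @param dist_range separation range in bp (default 60-180 Kb).
#' @return list with `ratio`, `active`, `passive` (per-class linear
#'   enrichment), `n_cells` per class.
#' @export
domain_intensity_ratio <- function(enrich, domains, dist_range = c(6e4, 1.8e5)) {
  stopifnot(inherits(enrich, "hic_enrichment"))
  dom <- domain_table(domains)
  if (!"class" %in% names(dom) || all(is.na(dom$class)))
    stopf("domains must be classified")
  bs <- enrich$bin_size
  n <- enrich$n_bins
  d_lo <- max(1L, ceiling(dist_range[1] / bs))
  d_hi <- min(n - 1L, floor(dist_range[2] / bs))
  dom_id <- integer(n); act <- logical(n)
  for (k in seq_len(nrow(dom))) {
    idx <- dom$start_bin[k]:dom$end_bin[k]
    dom_id[idx] <- k
    act[idx] <- identical(dom$class[k], "active")
  }
  OBS <- enrichment_band(enrich, d_hi, what = "obs")
  EXP <- enrichment_band(enrich, d_hi, what = "exp")
  so <- c(active = 0, passive = 0); se <- so; nc <- c(active = 0L, passive = 0L)
  for (d in d_lo:d_hi) {
    idx <- seq_len(n - d)
    intra <- dom_id[idx] == dom_id[idx + d]
    ok <- intra & is.finite(EXP[idx, d]) & is.finite(OBS[idx, d])
    cls <- ifelse(act[idx][ok], "active", "passive")
    for (cl in c("active", "passive")) {
      sel <- cls == cl
      so[cl] <- so[cl] + sum(OBS[idx, d][ok][sel])
      se[cl] <- se[cl] + sum(EXP[idx, d][ok][sel])
      nc[cl] <- nc[cl] + sum(sel)
    }
  }
  a <- so[["active"]] / se[["active"]]
  p <- so[["passive"]] / se[["passive"]]
  list(ratio = a / p, active = a, passive = p, n_cells = nc)
}
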
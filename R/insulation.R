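#' Band contact-insulation track
#'
#' The insulation statistic at locus `x` for band `w` is the mean corrected
#' enrichment over contacts crossing `x` within a `w x w` square:
#' pairs `(i, j)` with `i` in `[x - w, x)` and `j` in `[x, x + w)`. Because
#' the enrichment is already distance-controlled, the track is a local,
#' distance-controlled measure of crossing-contact intensity; insulating
#' elements appear as minima.
#'
#' @param enrich a [compute_enrichment()] object.
#' @param w band size in bp (multiple of the bin size, `>= 5` bins).
#' @param min_pairs minimum number of defined cells in the square; loci with
#'   fewer (near masked regions or chromosome ends) are `NA`.
#' @param statistic `"mean"`: mean of the per-cell log2 enrichment (the
#'   site-level insulation statistic used for meta profiles); `"ratio"`:
#'   log2 of summed observed over summed expected counts in the square — a
#'   count-weighted variant that stays informative at large bands where
#'   individual long-range cells are too sparse for per-cell log values;
#'   `"boundary"`: the ratio statistic minus the mean of the two within-side
#'   (triangle) ratios — crossing depletion relative to the flanking
#'   within-domain intensity, which cancels regional context and pins domain
#'   borders (used for border calling).
#' @return object of class `insulation_track`: list with `values` (per-bin,
#'   `NA` where undefined), `w`, `bin_size`, `n_bins`, `n_cells`,
#'   `statistic`.
#' @export
band_insulation_track <- function(enrich, w, min_pairs = 10L,
                                  statistic = c("mean", "ratio", "boundary")) {
  stopifnot(inherits(enrich, "hic_enrichment"))
  statistic <- match.arg(statistic)
  bs <- enrich$bin_size
  if (w %% bs != 0) stopf("band w must be a multiple of the bin size")
  k <- as.integer(w / bs)
  if (k < 5) stopf("band w must be at least 5 bins")
  n <- enrich$n_bins
  if (n < 2 * k + 1) stopf("chromosome shorter than twice the band")
  # crossing square: i in [x-k, x), j in [x, x+k)
  band_sum <- function(M) {
    S <- M; S[is.na(S)] <- 0
    out <- numeric(n)
    for (d in seq_len(2L * k - 1L)) {
      cs <- cumsum(S[, d])
      hi <- xs - max(1L, d - k + 1L)
      lo <- xs - min(k, d) - 1L
      out[xs] <- out[xs] + cs[hi] - ifelse(lo >= 1L, cs[pmax(lo, 1L)], 0)
    }
    out
  }
  # within-side triangles: both ends in [x-k, x) (left) or [x, x+k) (right)
  tri_sum <- function(M, side) {
    S <- M; S[is.na(S)] <- 0
    out <- numeric(n)
    for (d in seq_len(k - 1L)) {
      cs <- cumsum(S[, d])
      if (side == "left") { hi <- xs - 1L - d; lo <- xs - k - 1L }
      else { hi <- xs + k - 1L - d; lo <- xs - 1L }
      hi <- pmin(hi, n - d)
      out[xs] <- out[xs] + pmax(cs[pmax(hi, 1L)] * (hi >= 1L) -
                                  ifelse(lo >= 1L, cs[pmax(lo, 1L)], 0), 0)
    }
    out
  }
  xs <- (k + 1L):(n - k + 1L)
  if (statistic == "mean") {
    E <- enrichment_band(enrich, 2L * k - 1L)
    cnt <- band_sum((!is.na(E)) + 0)
    vals <- band_sum(E)
    out0 <- vals / cnt
  } else {
    EX <- enrichment_band(enrich, 2L * k - 1L, what = "exp")
    OB <- enrichment_band(enrich, 2L * k - 1L, what = "obs")
    OB[is.na(EX)] <- NA
    cnt <- band_sum((!is.na(EX)) + 0)
    psi <- enrich$pseudocount
    lr <- function(o, e) log2((o + psi) / (e + psi))
    out0 <- lr(band_sum(OB), band_sum(EX))
    if (statistic == "boundary") {
      out0 <- out0 - 0.5 * (lr(tri_sum(OB, "left"), tri_sum(EX, "left")) +
                              lr(tri_sum(OB, "right"), tri_sum(EX, "right")))
    }
  }
  out <- rep(NA_real_, n)
  ok <- logical(n); ok[xs] <- TRUE
  ok <- ok & cnt >= min_pairs
  out[ok] <- out0[ok]
  structure(list(values = out, w = w, bin_size = bs, n_bins = n,
                 n_cells = cnt, min_pairs = min_pairs, statistic = statistic),
            class = "insulation_track")
}

#' @export
print.insulation_track <- function(x, ...) {
  cat(sprintf("<insulation_track> band %g Kb, %d/%d bins defined\n",
              x$w / 1e3, sum(!is.na(x$values)), x$n_bins))
  invisible(x)
}

#' Site-aligned meta insulation profile
#'
#' Averages the band insulation track over loci aligned on a site set, at
#' offsets `-2w .. +2w`. The peak-to-trough ratio is the fold difference
#' between the maximal flanking value (offsets in `(w/2, 2w]`) and the
#' minimal central value (offsets within `w/2`), i.e.
#' `2^(max P_flank - min P_center)`.
#'
#' @param enrich a [compute_enrichment()] object.
#' @param sites site positions in bp (numeric vector).
#' @param bands band sizes in bp.
#' @param min_sites minimum usable sites per band (default 50).
#' @param trough_frac,peak_range trough window `|o| <= trough_frac * w` and
#'   peak window `(trough_frac * w, peak_range * w]`; the defaults (0.5, 2)
#'   are a convention, exposed here.
#' @param min_pairs passed to [band_insulation_track()].
#' @return list of `meta_profile` objects (one per band): `offsets` (bp),
#'   `P`, `n_sites`, `peak_to_trough`, `w`.
#' @export
meta_insulation_profile <- function(enrich, sites, bands = c(1e4, 2e4, 4e4, 8e4),
                                    min_sites = 50L, trough_frac = 0.5,
                                    peak_range = 2, min_pairs = 10L) {
  stopifnot(inherits(enrich, "hic_enrichment"))
  lapply(bands, function(w) {
    track <- band_insulation_track(enrich, w, min_pairs = min_pairs)
    meta_profile_from_track(track, sites, min_sites = min_sites,
                            trough_frac = trough_frac, peak_range = peak_range)
  })
}

# profile of an existing track over aligned sites
meta_profile_from_track <- function(track, sites, min_sites = 50L,
                                    trough_frac = 0.5, peak_range = 2) {
  stopifnot(inherits(track, "insulation_track"))
  bs <- track$bin_size
  k <- as.integer(track$w / bs)
  s_bins <- pos_to_bin(sites, bs)
  offs <- (-2L * k):(2L * k)
  idx <- outer(s_bins, offs, `+`)
  idx[idx < 1L | idx > track$n_bins] <- NA_integer_
  V <- matrix(track$values[idx], nrow = length(s_bins))
  usable <- rowSums(is.finite(V)) > 0
  if (sum(usable) < min_sites)
    stopf("band %g Kb: only %d usable sites (need >= %d)",
          track$w / 1e3, sum(usable), min_sites)
  P <- colMeans(V[usable, , drop = FALSE], na.rm = TRUE)
  o_bp <- offs * bs
  trough <- abs(o_bp) <= trough_frac * track$w
  peak <- abs(o_bp) > trough_frac * track$w &
    abs(o_bp) <= peak_range * track$w
  ptt <- 2^(max(P[peak], na.rm = TRUE) - min(P[trough], na.rm = TRUE))
  structure(list(offsets = o_bp, P = P, n_sites = sum(usable),
                 peak_to_trough = ptt, w = track$w),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("<meta_profile> band %g Kb, %d sites, peak-to-trough %.3f\n",
              x$w / 1e3, x$n_sites, x$peak_to_trough))
  invisible(x)
}

#' Peak-to-trough ratio of a meta profile
#' @param profile a `meta_profile`.
#' @return the fold ratio.
#' @export
peak_to_trough <- function(profile) {
  stopifnot(inherits(profile, "meta_profile"))
  profile$peak_to_trough
}

#' Group sites by their insulation strength
#'
#' Ranks sites by the 80-Kb-band insulation value at their position
#' (ascending: strong insulation = low crossing intensity) and splits them
#' into bottom quartile (most insulating), middle half, and top quartile.
#' Ties are broken by genomic coordinate.
#'
#' @param track an [band_insulation_track()] result (conventionally the
#'   80-Kb band).
#' @param sites site positions in bp.
#' @param min_defined_frac error if the track is defined at fewer than this
#'   fraction of sites.
#' @return data.table with `pos`, `I` (insulation at site), `group` in
#'   `{"bottom", "middle", "top"}`.
#' @export
group_sites_by_insulation <- function(track, sites, min_defined_frac = 0.8) {
  stopifnot(inherits(track, "insulation_track"))
  s_bins <- pos_to_bin(sites, track$bin_size)
  s_bins[s_bins > track$n_bins] <- track$n_bins
  I <- track$values[s_bins]
  if (mean(is.finite(I)) < min_defined_frac)
    stopf("track defined at only %.0f%% of sites", 100 * mean(is.finite(I)))
  keep <- is.finite(I)
  ord <- order(I[keep], sites[keep])
  nk <- sum(keep)
  q1 <- floor(nk / 4); q3 <- nk - floor(nk / 4)
  grp <- character(nk)
  grp[ord[seq_len(q1)]] <- "bottom"
  grp[ord[(q1 + 1):q3]] <- "middle"
  if (q3 < nk) grp[ord[(q3 + 1):nk]] <- "top"
  out <- data.table(pos = sites[keep], I = I[keep], group = grp)
  data.table::setorder(out, pos)
  out[]
}
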
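#' Normalize a 4C-seq coverage profile
#'
#' Zeroes the viewpoint exclusion zone and scales the remaining per-bin
#' coverage to reads per million (RPM), making profiles comparable across
#' libraries of different depth.
#'
#' @param raw numeric vector of per-bin raw coverage (e.g. from
#'   [simulate_fourc()] or a bedGraph import).
#' @param viewpoint viewpoint position in bp.
#' @param exclusion half-width (bp) of the excluded zone around the viewpoint.
#' @param bin_size bin width in bp (taken from `attr(raw, "bin_size")` if
#'   absent).
#' @param condition optional condition label.
#' @return object of class `fourc_profile`: list with `coverage` (RPM, zero
#'   inside the exclusion zone), `viewpoint`, `exclusion`, `bin_size`,
#'   `included` (logical), `condition`.
#' @export
normalize_fourc <- function(raw, viewpoint, exclusion = 1e4, bin_size = NULL,
                            condition = NA_character_) {
  bin_size <- bin_size %||% attr(raw, "bin_size")
  if (is.null(bin_size)) stopf("bin_size required")
  if (any(raw < 0)) stopf("raw coverage must be non-negative")
  n <- length(raw)
  if (viewpoint < 0 || viewpoint > n * bin_size)
    stopf("viewpoint outside chromosome")
  centers <- (seq_len(n) - 0.5) * bin_size
  included <- abs(centers - viewpoint) > exclusion
  v <- as.numeric(raw)
  v[!included] <- 0
  tot <- sum(v)
  if (tot <= 0) stopf("no coverage outside the exclusion zone")
  v <- v / tot * 1e6
  if (is.na(condition)) condition <- attr(raw, "condition") %||% NA_character_
  structure(list(coverage = v, viewpoint = viewpoint, exclusion = exclusion,
                 bin_size = bin_size, included = included,
                 condition = condition),
            class = "fourc_profile")
}

#' @export
print.fourc_profile <- function(x, ...) {
  cat(sprintf("<fourc_profile> viewpoint %.3g, %d bins @ %g Kb%s\n",
              x$viewpoint, length(x$coverage), x$bin_size / 1e3,
              if (is.na(x$condition)) "" else paste0(", ", x$condition)))
  invisible(x)
}

#' Sliding-median 4C track
#'
#' Value at each bin is the median of the profile over bins whose centers
#' fall within half the window on either side; the median suppresses
#' single-fragment spikes.
#'
#' @param profile a [normalize_fourc()] profile.
#' @param window window size in bp (default 5 Kb).
#' @return numeric per-bin track.
#' @export
sliding_median_track <- function(profile, window = 5e3) {
  stopifnot(inherits(profile, "fourc_profile"))
  bs <- profile$bin_size
  if (window < bs) stopf("window must be at least one bin")
  half <- floor((window / 2) / bs)
  v <- profile$coverage
  n <- length(v)
  vapply(seq_len(n), function(x) {
    median(v[max(1L, x - half):min(n, x + half)])
  }, 0)
}

#' Multi-scale 4C domainogram
#'
#' Mean normalized coverage in centered windows of geometrically increasing
#' size, quantile-rank scaled to the unit interval within each window size so that
#' scales are comparable. Bins inside the viewpoint exclusion zone are `NA`.
#'
#' @param profile a [normalize_fourc()] profile.
#' @param min_w,max_w smallest / largest window (bp).
#' @param n_scales number of window sizes (geometric steps).
#' @return object of class `domainogram`: `values` (n_scales x n_bins matrix,
#'   rows named by window size), `windows` (bp).
#' @export
build_domainogram <- function(profile, min_w = 2e3, max_w = 5e4,
                              n_scales = 20L) {
  stopifnot(inherits(profile, "fourc_profile"))
  if (max_w <= min_w) stopf("max_w must exceed min_w")
  bs <- profile$bin_size
  windows <- exp(seq(log(min_w), log(max_w), length.out = n_scales))
  v <- profile$coverage
  n <- length(v)
  cs <- c(0, cumsum(v))
  # windowed means count included bins only, so the zeroed exclusion zone
  # does not depress neighbouring windows
  cn <- c(0, cumsum(as.numeric(profile$included)))
  vals <- matrix(NA_real_, n_scales, n,
                 dimnames = list(sprintf("%.0f", windows), NULL))
  for (s in seq_len(n_scales)) {
    half <- max(0L, floor((windows[s] / 2) / bs))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    k_inc <- cn[hi + 1L] - cn[lo]
    m <- ifelse(k_inc > 0, (cs[hi + 1L] - cs[lo]) / k_inc, NA_real_)
    m[!profile$included] <- NA_real_
    ok <- is.finite(m)
    r <- rep(NA_real_, n)
    # signif() collapses cumulative-sum float jitter so equal coverage ties
    r[ok] <- rank(signif(m[ok], 10), ties.method = "average") / sum(ok)
    vals[s, ] <- r
  }
  structure(list(values = vals, windows = windows, bin_size = bs,
                 viewpoint = profile$viewpoint),
            class = "domainogram")
}

#' @export
print.domainogram <- function(x, ...) {
  cat(sprintf("<domainogram> %d scales (%.1f-%.1f Kb) x %d bins\n",
              length(x$windows), min(x$windows) / 1e3, max(x$windows) / 1e3,
              ncol(x$values)))
  invisible(x)
}

#' Compare 4C profiles across conditions in a target region
#'
#' Mean RPM coverage of each profile over a target region (e.g. the partner
#' anchor of the viewpoint), plus monotonicity flags over the supplied
#' condition order — the readout for progressive-depletion time courses.
#'
#' @param profiles list of [normalize_fourc()] profiles on a common grid.
#' @param region c(lo, hi) target interval in bp.
#' @return list with `means` (named per condition), `monotone_decreasing`,
#'   `monotone_increasing`.
#' @export
compare_fourc_conditions <- function(profiles, region) {
  if (length(profiles) < 2) stopf("need at least 2 profiles")
  if (!all(vapply(profiles, inherits, TRUE, "fourc_profile")))
    stopf("profiles must be fourc_profile objects")
  n <- length(profiles[[1]]$coverage)
  bs <- profiles[[1]]$bin_size
  for (p in profiles)
    if (length(p$coverage) != n || p$bin_size != bs)
      stopf("profiles are on different grids")
  if (region[1] < 0 || region[2] > n * bs || region[1] >= region[2])
    stopf("region outside chromosome")
  centers <- (seq_len(n) - 0.5) * bs
  sel <- centers >= region[1] & centers <= region[2]
  if (!any(sel)) stopf("region contains no bins")
  means <- vapply(profiles, function(p) mean(p$coverage[sel]), 0)
  labs <- vapply(seq_along(profiles), function(q) {
    profiles[[q]]$condition %||% NA_character_
  }, "")
  if (!anyNA(labs) && !anyDuplicated(labs)) names(means) <- labs
  list(means = means,
       monotone_decreasing = all(diff(means) <= 0),
       monotone_increasing = all(diff(means) >= 0))
}
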
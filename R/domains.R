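# Accept either a domain_set or a generator-style domains table.
domain_table <- function(domains) {
  if (inherits(domains, "domain_set")) return(domains$domains)
  dt <- as.data.table(domains)
  if (!all(c("start_bin", "end_bin") %in% names(dt)))
    stopf("domains must have start_bin/end_bin columns")
  dt
}

#' Call domain borders from an insulation track
#'
#' Borders are local minima of the insulation track that fall below the
#' track's `depth_quantile`, stand out from their neighbourhood by at least
#' `min_prominence` (log2; against the lower of the two flanking maxima
#' within `min_domain`), and are separated by at least `min_domain`. The
#' intervals between consecutive borders (and the chromosome ends) are the
#' domains. Border calling uses a large band (conventionally 640 Kb), where
#' crossing contacts probe domain-scale structure; the count-weighted
#' `statistic = "ratio"` track is the intended input — at realistic coverage
#' the per-cell log2 values of Mb-scale cells are pseudocount-dominated and
#' carry no border signal.
#'
#' @param track an [band_insulation_track()] result (ratio statistic
#'   recommended).
#' @param min_domain minimum domain size in bp (minimum border separation).
#' @param depth_quantile borders must lie below this track quantile.
#' @param min_prominence minimal depth (log2) of a border below its flanking
#'   maxima; suppresses shallow noise minima on structureless input.
#' @param refine_track optional second [band_insulation_track()] at a small
#'   band (e.g. 80 Kb, ratio statistic): each border is snapped to that
#'   track's minimum within `refine_window`. The large band locates borders
#'   robustly but its minima can be displaced by tens of Kb when the flanking
#'   domains differ in intensity; the small band pins the crossing minimum.
#' @param refine_window half-width (bp) of the refinement search.
#' @return object of class `domain_set`: list with `borders` (bin indices),
#'   `domains` (data.table: start_bin, end_bin, class = NA), `bin_size`.
#' @export
call_domains <- function(track, min_domain = 4e5, depth_quantile = 0.25,
                         min_prominence = 0.2, refine_track = NULL,
                         refine_window = 6.4e4) {
  stopifnot(inherits(track, "insulation_track"))
  v <- track$values
  n <- track$n_bins
  thr <- quantile(v, depth_quantile, na.rm = TRUE)
  vv <- v
  vv[is.na(vv)] <- Inf
  # local minima (plateau-aware: centre bin of a minimal plateau)
  r <- rle(vv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- integer(0)
  for (q in seq_along(r$values)) {
    if (!is.finite(r$values[q])) next
    left_up <- q == 1 || r$values[q - 1] > r$values[q]
    right_up <- q == length(r$values) || r$values[q + 1] > r$values[q]
    if (left_up && right_up && q > 1 && q < length(r$values))
      cand <- c(cand, starts[q] + (r$lengths[q] - 1L) %/% 2L)
  }
  cand <- cand[vv[cand] <= thr]
  min_sep <- max(1L, floor(min_domain / track$bin_size))
  if (length(cand) && min_prominence > 0) {
    prom <- vapply(cand, function(x) {
      lo <- max(1L, x - min_sep); hi <- min(n, x + min_sep)
      lmax <- suppressWarnings(max(v[lo:x], na.rm = TRUE))
      rmax <- suppressWarnings(max(v[x:hi], na.rm = TRUE))
      min(lmax, rmax) - v[x]
    }, 0)
    cand <- cand[is.finite(prom) & prom >= min_prominence]
  }
  borders <- integer(0)
  for (x in cand[order(vv[cand])]) {        # deepest minima take precedence
    if (!length(borders) || all(abs(borders - x) >= min_sep))
      borders <- c(borders, x)
  }
  if (!is.null(refine_track) && length(borders)) {
    stopifnot(inherits(refine_track, "insulation_track"))
    rw <- max(1L, floor(refine_window / track$bin_size))
    rv <- refine_track$values
    borders <- vapply(borders, function(x) {
      lo <- max(1L, x - rw); hi <- min(n, x + rw)
      seg <- rv[lo:hi]
      if (all(!is.finite(seg))) return(x)
      as.integer(lo + which.min(seg) - 1L)
    }, 0L)
    borders <- unique(borders)
    keep <- rep(TRUE, length(borders))
    ord <- order(v[borders])
    taken <- integer(0)
    for (x in borders[ord]) {
      if (length(taken) && any(abs(taken - x) < min_sep)) {
        keep[match(x, borders)] <- FALSE
      } else taken <- c(taken, x)
    }
    borders <- borders[keep]
  }
  borders <- sort(borders)
  edges <- c(1L, borders, n + 1L)
  domains <- data.table(start_bin = head(edges, -1L),
                        end_bin = tail(edges, -1L) - 1L,
                        class = NA_character_)
  domains <- domains[end_bin >= start_bin]
  structure(list(borders = borders, domains = domains,
                 bin_size = track$bin_size, n_bins = n),
            class = "domain_set")
}

#' @export
print.domain_set <- function(x, ...) {
  cl <- x$domains$class
  cat(sprintf("<domain_set> %d borders, %d domains%s\n",
              length(x$borders), nrow(x$domains),
              if (all(is.na(cl))) " (unclassified)" else
                sprintf(" (%d active / %d passive)",
                        sum(cl == "active", na.rm = TRUE),
                        sum(cl == "passive", na.rm = TRUE))))
  invisible(x)
}

#' Classify domains into active and passive
#'
#' Two-cluster grouping of domains on two features: mean intra-domain
#' enrichment at 60-180 Kb separations, and TSS density. Clustering is a
#' deterministic 2-means (centers initialized at the 10th/90th feature
#' quantiles, then Lloyd iterations), so results do not depend on domain
#' order or RNG state. The cluster with the higher TSS density is labelled
#' active. If the features are (near-)constant the classification is flagged
#' degenerate and a single class is returned.
#'
#' @param enrich a [compute_enrichment()] object.
#' @param domains a `domain_set` (or generator domains table).
#' @param tss TSS positions in bp.
#' @param dist_range intra-domain separation range (bp) for the contact
#'   feature.
#' @return a `domain_set` with `class` filled in and attribute `degenerate`.
#' @export
classify_domain_activity <- function(enrich, domains, tss,
                                     dist_range = c(6e4, 1.8e5)) {
  stopifnot(inherits(enrich, "hic_enrichment"))
  dom <- domain_table(domains)
  if (nrow(dom) < 4) stopf("need at least 4 domains to classify")
  bs <- enrich$bin_size
  d_lo <- max(1L, ceiling(dist_range[1] / bs))
  d_hi <- floor(dist_range[2] / bs)
  OBS <- enrichment_band(enrich, d_hi, what = "obs")
  EXP <- enrichment_band(enrich, d_hi, what = "exp")
  psi <- enrich$pseudocount
  # linear mean enrichment per domain (ratio of sums: unbiased at sparse
  # coverage, unlike the mean of pseudocounted per-cell log values)
  mean_e <- vapply(seq_len(nrow(dom)), function(k) {
    a <- dom$start_bin[k]; z <- dom$end_bin[k]
    so <- 0; se <- 0
    for (d in d_lo:d_hi) {
      if (a > z - d) next
      idx <- a:(z - d)
      ok <- is.finite(EXP[idx, d])
      so <- so + sum(OBS[idx, d][ok]); se <- se + sum(EXP[idx, d][ok])
    }
    if (se <= 0) NA_real_ else log2((so + psi) / (se + psi))
  }, 0)
  tss_bin <- pos_to_bin(tss, bs)
  tss_density <- vapply(seq_len(nrow(dom)), function(k) {
    sum(tss_bin >= dom$start_bin[k] & tss_bin <= dom$end_bin[k]) /
      ((dom$end_bin[k] - dom$start_bin[k] + 1) * bs / 1e6)
  }, 0)
  feats <- cbind(mean_e, tss_density)
  feats[!is.finite(feats)] <- 0
  rng <- apply(feats, 2, function(col) diff(range(col)))
  degenerate <- all(rng < 1e-9)
  if (!degenerate) {
    z <- scale(feats)
    z[!is.finite(z)] <- 0
    cl <- lloyd_2means(z)
    if (length(unique(cl)) < 2) degenerate <- TRUE
  }
  out <- if (inherits(domains, "domain_set")) domains else
    structure(list(borders = dom$start_bin[-1L], domains = dom,
                   bin_size = bs, n_bins = enrich$n_bins),
              class = "domain_set")
  out$domains <- data.table::copy(domain_table(out))
  if (degenerate) {
    out$domains[, class := "passive"]
  } else {
    act_cluster <- which.max(tapply(tss_density, cl, mean))
    out$domains[, class := ifelse(cl == as.integer(names(act_cluster)),
                                  "active", "passive")]
  }
  attr(out, "degenerate") <- degenerate
  attr(out, "features") <- data.table(mean_e = mean_e,
                                      tss_density = tss_density)
  out
}

# deterministic 2-means: quantile-initialized Lloyd iterations
lloyd_2means <- function(z, max_iter = 100L) {
  c1 <- apply(z, 2, quantile, 0.1)
  c2 <- apply(z, 2, quantile, 0.9)
  cl <- rep(1L, nrow(z))
  for (it in seq_len(max_iter)) {
    d1 <- colSums((t(z) - c1)^2)
    d2 <- colSums((t(z) - c2)^2)
    new_cl <- ifelse(d2 < d1, 2L, 1L)
    if (all(new_cl == cl) && it > 1) break
    cl <- new_cl
    if (any(cl == 1L)) c1 <- colMeans(z[cl == 1L, , drop = FALSE])
    if (any(cl == 2L)) c2 <- colMeans(z[cl == 2L, , drop = FALSE])
  }
  cl
}

#' Adjacent-site spacing comparison between domain classes
#'
#' Distances between consecutive COH sites lying in the same domain, split by
#' the domain's activity class, compared with a two-sample Kolmogorov-Smirnov
#' test.
#'
#' @param sites data.table with `pos` and (optionally) `class` columns; only
#'   `class == "COH"` rows are used if a class column is present.
#' @param domains classified `domain_set` or generator domains table (needs a
#'   `class` column).
#' @param bin_size bin size (bp) used to map positions to domains when
#'   `domains` carries bin coordinates.
#' @return object of class `spacing_comparison`: list with `spacings`
#'   (list: active, passive), `D`, `p_value`.
#' @export
adjacent_spacing_ks <- function(sites, domains, bin_size = NULL) {
  dom <- domain_table(domains)
  if (!"class" %in% names(dom) || all(is.na(dom$class)))
    stopf("domains must be classified")
  st <- as.data.table(sites)
  if ("class" %in% names(st)) st <- st[class == "COH"]
  bs <- bin_size %||% (if (inherits(domains, "domain_set")) domains$bin_size
                       else stopf("bin_size required"))
  st[, bin := pos_to_bin(pos, bs)]
  st[, dom_k := findInterval(bin, dom$start_bin)]
  data.table::setorder(st, pos)
  sp <- st[, if (.N >= 2) .(spacing = diff(pos)) else NULL, by = dom_k]
  sp[, cls := dom$class[dom_k]]
  spacings <- list(active = sp[cls == "active", spacing],
                   passive = sp[cls == "passive", spacing])
  if (length(spacings$active) < 20 || length(spacings$passive) < 20)
    stopf("need >= 20 spacings per class")
  kt <- suppressWarnings(ks.test(spacings$active, spacings$passive))
  structure(list(spacings = spacings, D = unname(kt$statistic),
                 p_value = kt$p.value),
            class = "spacing_comparison")
}

#' @export
print.spacing_comparison <- function(x, ...) {
  cat(sprintf("<spacing_comparison> n=%d/%d spacings, KS D=%.4f, p=%.3g\n",
              length(x$spacings$active), length(x$spacings$passive),
              x$D, x$p_value))
  invisible(x)
}

#' Contact enrichment by intervening-site count
#'
#' Groups all bin pairs in each distance stratum by the number of COH sites
#' separating them (capped at `cap`, i.e. "cap+"), and reports the mean
#' enrichment of each group relative to the stratum-wide mean.
#'
#' @param enrich a [compute_enrichment()] object.
#' @param sites COH site positions in bp.
#' @param distance_strata list of c(lo, hi) separation ranges in bp.
#' @param cap intervening-site counts at or above this are pooled.
#' @return data.table with `stratum`, `k` (intervening sites), `relative_e`,
#'   `n_cells`.
#' @export
intervening_site_curve <- function(enrich, sites,
                                   distance_strata = list(c(6e4, 1.8e5)),
                                   cap = 6L) {
  stopifnot(inherits(enrich, "hic_enrichment"))
  bs <- enrich$bin_size
  n <- enrich$n_bins
  s_bins <- pos_to_bin(sites, bs)
  s_bins <- s_bins[s_bins <= n]
  site_cum <- cumsum(tabulate(s_bins, nbins = n))
  out <- vector("list", length(distance_strata))
  for (q in seq_along(distance_strata)) {
    lo <- max(1L, ceiling(distance_strata[[q]][1] / bs))
    hi <- min(n - 1L, floor(distance_strata[[q]][2] / bs))
    if (hi < lo) stopf("stratum %d outside available distances", q)
    E <- enrichment_band(enrich, hi)
    es <- numeric(0); ks <- integer(0)
    for (d in lo:hi) {
      idx <- seq_len(n - d)
      e <- E[idx, d]
      keep <- is.finite(e)
      # sites strictly between the bins (i < s < j)
      kk <- site_cum[idx + d - 1L] - site_cum[idx]
      es <- c(es, e[keep]); ks <- c(ks, kk[keep])
    }
    ks <- pmin(ks, cap)
    gm <- mean(es)
    dt <- data.table(e = es, k = ks)[, .(relative_e = mean(e) - gm,
                                         n_cells = .N), by = k]
    dt[, stratum := sprintf("%g-%g", distance_strata[[q]][1],
                            distance_strata[[q]][2])]
    out[[q]] <- dt
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, stratum, k)
  res[, .(stratum, k, relative_e, n_cells)]
}
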
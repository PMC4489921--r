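#' Build site pairs for pooled analyses
#'
#' Enumerates ordered pairs of loci (from one or two position sets) with a
#' given genomic separation range and domain relation.
#'
#' @param pos1,pos2 locus positions in bp (`pos2` defaults to `pos1`).
#' @param domains `domain_set` or generator domains table.
#' @param stratum c(lo, hi) separation range in bp.
#' @param relation `"intra"` (same domain), `"inter"` (different domains) or
#'   `"any"`.
#' @param bin_size bin size in bp.
#' @param n_bins number of bins.
#' @param max_pairs optional cap; pairs are subsampled deterministically
#'   (evenly spaced after sorting) if exceeded.
#' @return data.table with `pos1`, `pos2`, `bin1`, `bin2` (`bin1 < bin2`).
#' @export
site_pairs <- function(pos1, pos2 = NULL, domains, stratum,
                       relation = c("intra", "inter", "any"),
                       bin_size, n_bins, max_pairs = Inf) {
  relation <- match.arg(relation)
  same_set <- is.null(pos2)
  if (same_set) pos2 <- pos1
  dom <- domain_table(domains)
  p1 <- sort(unique(pos1)); p2 <- sort(unique(pos2))
  idx2_lo <- findInterval(p1 + stratum[1], p2) + 1L
  idx2_hi <- findInterval(p1 + stratum[2], p2)
  keep <- idx2_hi >= idx2_lo
  reps <- pmax(idx2_hi - idx2_lo + 1L, 0L)
  a <- rep(p1[keep], reps[keep])
  bidx <- unlist(lapply(which(keep), function(q) idx2_lo[q]:idx2_hi[q]),
                 use.names = FALSE)
  b <- p2[bidx]
  if (!same_set) {
    # also pairs where the set-2 locus is upstream
    idx1_lo <- findInterval(p2 + stratum[1], p1) + 1L
    idx1_hi <- findInterval(p2 + stratum[2], p1)
    keep2 <- idx1_hi >= idx1_lo
    reps2 <- pmax(idx1_hi - idx1_lo + 1L, 0L)
    b2 <- rep(p2[keep2], reps2[keep2])
    aidx <- unlist(lapply(which(keep2), function(q) idx1_lo[q]:idx1_hi[q]),
                   use.names = FALSE)
    a <- c(a, b2); b <- c(b, p1[aidx])
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  dt <- unique(data.table(pos1 = lo, pos2 = hi))
  dt[, `:=`(bin1 = pos_to_bin(pos1, bin_size), bin2 = pos_to_bin(pos2, bin_size))]
  dt <- dt[bin1 >= 1L & bin2 <= n_bins & bin2 > bin1]
  if (relation != "any") {
    d1 <- findInterval(dt$bin1, dom$start_bin)
    d2 <- findInterval(dt$bin2, dom$start_bin)
    dt <- if (relation == "intra") dt[d1 == d2] else dt[d1 != d2]
  }
  data.table::setorder(dt, pos1, pos2)
  if (nrow(dt) > max_pairs) {
    pick <- unique(round(seq(1L, nrow(dt), length.out = max_pairs)))
    dt <- dt[pick]
  }
  dt[]
}

#' Pool enrichment submatrices aligned on site pairs
#'
#' For each pair `(a, b)` the enrichment values at offsets
#' `(u, v) in [-half_width, +half_width]` from the two anchors are collected,
#' and per-offset cell means are computed over all contributing pairs. The
#' observed and expected sums per cell are kept alongside the log2 mean, so
#' fold enrichments can be measured on the linear scale (ratio of sums, the
#' unbiased estimator at sparse coverage) as well as in log space.
#'
#' @param enrich a [compute_enrichment()] object.
#' @param pairs data.table with `bin1`, `bin2` (from [site_pairs()] or the
#'   generator's `anchor_pairs`).
#' @param half_width submatrix half-width in bp (default 40 Kb).
#' @param stratum optional c(lo, hi) bp range; pairs outside are dropped.
#' @param relation free-form label stored on the result.
#' @return object of class `pooled_matrix`: `M` (mean log2 enrichment),
#'   `n` (contributing pairs per cell), `sum_obs`, `sum_exp`, `offsets` (bp),
#'   `n_pairs`, `half_width`, `bin_size`.
#' @export
pool_pair_submatrices <- function(enrich, pairs, half_width = 4e4,
                                  stratum = NULL, relation = NA_character_) {
  stopifnot(inherits(enrich, "hic_enrichment"))
  p <- as.data.table(pairs)
  if (!all(c("bin1", "bin2") %in% names(p)))
    stopf("pairs must have bin1/bin2 columns")
  bs <- enrich$bin_size
  if (!is.null(stratum)) {
    sep <- (p$bin2 - p$bin1) * bs
    p <- p[sep >= stratum[1] & sep <= stratum[2]]
  }
  if (!nrow(p)) stopf("empty pair list")
  hw <- as.integer(half_width / bs)
  offs <- (-hw):hw
  n_off <- length(offs)
  n <- enrich$n_bins
  psi <- enrich$pseudocount

  q <- data.table(
    pair = rep(seq_len(nrow(p)), each = n_off * n_off),
    u = rep(rep(offs, each = n_off), nrow(p)),
    v = rep(rep(offs, n_off), nrow(p)))
  q[, `:=`(i = p$bin1[pair] + u, j = p$bin2[pair] + v)]
  q <- q[i >= 1L & j <= n & i < j]
  q[, expd := expected_at(enrich, i, j)]
  q <- q[is.finite(expd)]
  q[, cnt := contact_lookup(enrich$counts, i, j)]
  q[, e := log2((cnt + psi) / (expd + psi))]
  agg <- q[, .(M = mean(e), n = .N, sum_obs = sum(cnt), sum_exp = sum(expd)),
           by = .(u, v)]

  to_mat <- function(col) {
    m <- matrix(NA_real_, n_off, n_off, dimnames = list(offs * bs, offs * bs))
    m[cbind(match(agg$u, offs), match(agg$v, offs))] <- agg[[col]]
    m
  }
  structure(list(M = to_mat("M"), n = to_mat("n"),
                 sum_obs = to_mat("sum_obs"), sum_exp = to_mat("sum_exp"),
                 offsets = offs * bs, n_pairs = nrow(p),
                 half_width = half_width, bin_size = bs,
                 stratum = stratum, relation = relation),
            class = "pooled_matrix")
}

#' @export
print.pooled_matrix <- function(x, ...) {
  cat(sprintf("<pooled_matrix> %dx%d cells @ %g Kb, %d pairs%s\n",
              nrow(x$M), ncol(x$M), x$bin_size / 1e3, x$n_pairs,
              if (is.null(x$stratum)) "" else
                sprintf(", stratum %g-%g Kb", x$stratum[1] / 1e3,
                        x$stratum[2] / 1e3)))
  invisible(x)
}

#' Center-relative fold enrichment of a pooled matrix
#'
#' Fold enrichment of the pooled matrix center (3x3 cells around the aligned
#' anchor pair), against one of three backgrounds:
#'
#' * `"ring"`: the pooled matrix's own background ring (cells with both
#'   offsets beyond `ring_min`). Simple, but the ring sits next to the
#'   anchors, so any insulation the anchor sites themselves impose depresses
#'   it and inflates the fold.
#' * `"expected"`: the decay/bias expectation alone. Unbiased for the loop
#'   only if the aligned pairs sit in average chromatin context — intra-domain
#'   anchor pairs do not (domain intensity and crossing effects inflate it).
#' * `"control"`: the center of a second pooled matrix built from matched
#'   control pairs (same separations, same domain class, away from binding
#'   sites; see [matched_control_pairs()]). This cancels shared context and
#'   recovers the loop-specific fold; it is what the pair-level analyses use.
#'
#' @param pooled a [pool_pair_submatrices()] result.
#' @param background `"ring"`, `"expected"` or `"control"`.
#' @param space `"log2"` (2 to the difference of mean per-cell log2 values,
#'   pseudocount included) or `"linear"` (ratio of summed observed to summed
#'   expected — the unbiased estimator at sparse coverage).
#' @param control a `pooled_matrix` of control pairs (required for
#'   `background = "control"`).
#' @param center_cells half-width (cells) of the center block (1 = 3x3).
#' @param ring_min minimal |offset| (bp) of ring cells.
#' @return the fold (numeric scalar).
#' @export
center_relative_enrichment <- function(pooled,
                                       background = c("ring", "expected", "control"),
                                       space = c("log2", "linear"),
                                       control = NULL,
                                       center_cells = 1L, ring_min = 2e4) {
  stopifnot(inherits(pooled, "pooled_matrix"))
  background <- match.arg(background)
  space <- match.arg(space)
  if (background == "control" && !inherits(control, "pooled_matrix"))
    stopf("background = 'control' needs a pooled control matrix")
  val <- function(pm, sel) {
    if (space == "linear") {
      so <- sum(pm$sum_obs[sel], na.rm = TRUE)
      se <- sum(pm$sum_exp[sel], na.rm = TRUE)
      if (se <= 0) return(NA_real_)
      so / se
    } else {
      2^mean(pm$M[sel], na.rm = TRUE)
    }
  }
  blocks <- function(pm) {
    o <- pm$offsets
    ctr <- abs(o) <= center_cells * pm$bin_size
    list(ctr = outer(ctr, ctr, `&`),
         ring = outer(abs(o) > ring_min, abs(o) > ring_min, `&`))
  }
  bp <- blocks(pooled)
  ctr_val <- val(pooled, bp$ctr)
  switch(background,
         expected = ctr_val,
         ring = ctr_val / val(pooled, bp$ring),
         control = ctr_val / val(control, blocks(control)$ctr))
}

#' Matched control pairs for pooled analyses
#'
#' For each test pair, control pairs at the same bin separation are drawn
#' from chromatin matched on domain relation and (for intra-domain pairs)
#' domain class, with both loci at least `clearance` away from any site.
#' With `zero_crossing = TRUE` the control pair must additionally lie inside
#' a single inter-site interval (crossing no COH site), matching the
#' crossing count of direct anchor pairs. Selection is deterministic
#' (evenly spaced over the candidate positions).
#'
#' @param pairs data.table with `bin1`, `bin2` (test pairs).
#' @param sites COH site positions in bp.
#' @param domains `domain_set` or generator domains table (with `class` if
#'   class matching is wanted).
#' @param bin_size,n_bins grid description.
#' @param clearance minimal distance (bp) of control loci to any site.
#' @param n_per control pairs per test pair.
#' @param zero_crossing require control pairs to cross no COH site.
#' @return list with `test` (test pairs that found controls) and `control`
#'   (data.table of control pairs).
#' @export
matched_control_pairs <- function(pairs, sites, domains, bin_size, n_bins,
                                  clearance = 5e3, n_per = 5L,
                                  zero_crossing = TRUE) {
  p <- as.data.table(pairs)
  dom <- domain_table(domains)
  has_class <- "class" %in% names(dom) && !all(is.na(dom$class))
  sites <- sort(sites)
  d1 <- findInterval(p$bin1, dom$start_bin)
  d2 <- findInterval(p$bin2, dom$start_bin)
  p_intra <- d1 == d2
  p_class <- if (has_class) dom$class[d1] else rep("any", nrow(p))
  cl_bins <- max(1L, ceiling(clearance / bin_size))

  ctrl_list <- vector("list", nrow(p))
  keep <- logical(nrow(p))

  if (zero_crossing) {
    # candidate intervals: within-domain gaps between consecutive COH sites
    gaps <- data.table::rbindlist(lapply(seq_len(nrow(dom)), function(k) {
      lo_bp <- (dom$start_bin[k] - 1) * bin_size
      hi_bp <- dom$end_bin[k] * bin_size
      s <- sites[sites >= lo_bp & sites < hi_bp]
      if (length(s) < 2) return(NULL)
      data.table(gs = head(s, -1), ge = tail(s, -1),
                 class = if (has_class) dom$class[k] else "any")
    }))
    for (r in seq_len(nrow(p))) {
      db <- p$bin2[r] - p$bin1[r]
      need <- db * bin_size + 2 * clearance
      g <- gaps[class == p_class[r] & (ge - gs) >= need]
      if (!nrow(g)) next
      xs <- unlist(lapply(seq_len(nrow(g)), function(q) {
        lo <- g$gs[q] + clearance
        hi <- g$ge[q] - clearance - db * bin_size
        n_here <- max(1L, min(3L, floor((hi - lo) / bin_size)))
        seq(lo, hi, length.out = n_here)
      }), use.names = FALSE)
      if (!length(xs)) next
      xs <- xs[unique(round(seq(1L, length(xs),
                                length.out = min(n_per, length(xs)))))]
      b1 <- pos_to_bin(xs, bin_size)
      ctrl_list[[r]] <- data.table(bin1 = b1, bin2 = b1 + db, pair_id = r)
      keep[r] <- TRUE
    }
  } else {
    # generic far-from-site loci, matched on relation, domain class (intra)
    # and the number of COH sites crossed (conditioning control endpoints on
    # site-free zones otherwise biases the interior site count downwards)
    centers <- (seq_len(n_bins) - 0.5) * bin_size
    far <- nearest_distance(centers, sites) >= clearance
    dom_id <- integer(n_bins)
    for (k in seq_len(nrow(dom)))
      dom_id[dom$start_bin[k]:dom$end_bin[k]] <- k
    site_bins <- pos_to_bin(sites, bin_size)
    site_bins <- site_bins[site_bins <= n_bins]
    site_cum <- cumsum(tabulate(site_bins, nbins = n_bins))
    k_cap <- 6L
    kx_of <- function(b1, b2)
      pmin(site_cum[pmax(b2 - 1L, b1)] - site_cum[b1], k_cap)
    cache <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(p))) {
      db <- p$bin2[r] - p$bin1[r]
      kt <- kx_of(p$bin1[r], p$bin2[r])
      key <- paste(db, p_intra[r], p_class[r], sep = "_")
      ent <- cache[[key]]
      if (is.null(ent)) {
        x_all <- seq_len(n_bins - db)
        ok <- far[x_all] & far[x_all + db]
        rel <- if (p_intra[r]) dom_id[x_all] == dom_id[x_all + db]
               else dom_id[x_all] != dom_id[x_all + db]
        ok <- ok & rel
        if (has_class && p_intra[r])
          ok <- ok & dom$class[dom_id[x_all]] == p_class[r]
        xs <- x_all[ok]
        ent <- list(xs = xs, kx = kx_of(xs, xs + db))
        cache[[key]] <- ent
      }
      if (!length(ent$xs)) next
      dk <- abs(ent$kx - kt)
      sel <- which(dk == min(dk))          # exact k, else nearest available
      xs <- ent$xs[sel]
      pick <- xs[unique(round(seq(1L, length(xs),
                                  length.out = min(n_per, length(xs)))))]
      ctrl_list[[r]] <- data.table(bin1 = pick, bin2 = pick + db, pair_id = r)
      keep[r] <- TRUE
    }
  }
  ctrl <- data.table::rbindlist(ctrl_list)
  if (!nrow(ctrl)) stopf("no matched control pairs found")
  test <- p[keep]
  ctrl[, pair_id := match(pair_id, which(keep))]
  list(test = test, control = ctrl)
}

# per-pair observed/expected sums over the center block (2*center_cells+1)^2
center_sums <- function(enrich, pairs, center_cells = 1L) {
  p <- as.data.table(pairs)
  offs <- (-center_cells):center_cells
  n_off <- length(offs)
  n <- enrich$n_bins
  q <- data.table(
    pair_id = rep(seq_len(nrow(p)), each = n_off * n_off),
    i = rep(p$bin1, each = n_off * n_off) + rep(rep(offs, each = n_off), nrow(p)),
    j = rep(p$bin2, each = n_off * n_off) + rep(rep(offs, n_off), nrow(p)))
  q <- q[i >= 1L & j <= n & i < j]
  q[, expd := expected_at(enrich, i, j)]
  q <- q[is.finite(expd)]
  q[, cnt := contact_lookup(enrich$counts, i, j)]
  q[, .(obs = sum(cnt), expd = sum(expd)), by = pair_id]
}

#' Matched-control center fold of a pair set
#'
#' The loop-specific fold of a set of test pairs against their matched
#' controls, with the local context cancelled per pair: each test pair's
#' expected center signal is scaled by the observed/expected ratio of its own
#' controls (same separation, same domain class), and the fold is the ratio
#' of summed observed to summed context-adjusted expected center counts.
#' This removes the distance and domain-context drift that a global
#' background cannot.
#'
#' @param enrich a [compute_enrichment()] object.
#' @param mc a [matched_control_pairs()] result.
#' @param center_cells half-width (cells) of the center block.
#' @return list with `fold`, `n_pairs`, `n_controls`.
#' @export
matched_center_fold <- function(enrich, mc, center_cells = 1L) {
  ts <- center_sums(enrich, mc$test, center_cells)
  cs <- center_sums(enrich, mc$control[, .(bin1, bin2)], center_cells)
  cs[, pid := mc$control$pair_id[pair_id]]
  ctx <- cs[, .(obs = sum(obs), expd = sum(expd)), by = pid]
  ctx <- ctx[expd > 0 & obs > 0]
  ctx[, ctx := obs / expd]
  m <- merge(ts, ctx[, .(pair_id = pid, ctx)], by = "pair_id")
  if (!nrow(m)) stopf("no test pairs with usable controls")
  list(fold = sum(m$obs) / sum(m$expd * m$ctx),
       n_pairs = nrow(m), n_controls = nrow(mc$control))
}

#' Loop-specific fold enrichment of anchor pairs
#'
#' Builds matched zero-crossing controls for the anchor pairs in the stratum
#' (same separation, same domain class, clear of binding sites) and reports
#' the per-pair context-matched center fold ([matched_center_fold()]) — the
#' loop-specific contact enrichment with domain context and distance effects
#' cancelled. Pooled matrices of the test pairs and controls are returned
#' for inspection.
#'
#' @param enrich a [compute_enrichment()] object.
#' @param pairs anchor pairs (`bin1`, `bin2`), e.g. the generator's
#'   `anchor_pairs` or [site_pairs()] output.
#' @param sites COH site positions (bp).
#' @param domains `domain_set` or generator domains table.
#' @param stratum separation range in bp (default 100-200 Kb).
#' @param half_width pooled submatrix half-width (bp).
#' @param n_per,clearance control matching parameters
#'   (see [matched_control_pairs()]).
#' @param zero_crossing control crossing-count matching.
#' @param pool also build the full pooled matrices (for display/inspection).
#' @return list with `fold`, `n_pairs`, `n_controls`, and (with
#'   `pool = TRUE`) `pooled`, `pooled_control`.
#' @export
anchor_pair_fold <- function(enrich, pairs, sites, domains,
                             stratum = c(1e5, 2e5), half_width = 4e4,
                             n_per = 8L, clearance = 5e3,
                             zero_crossing = TRUE, pool = FALSE) {
  stopifnot(inherits(enrich, "hic_enrichment"))
  p <- as.data.table(pairs)
  bs <- enrich$bin_size
  sep <- (p$bin2 - p$bin1) * bs
  p <- p[sep >= stratum[1] & sep <= stratum[2]]
  if (!nrow(p)) stopf("no pairs in stratum")
  mc <- matched_control_pairs(p, sites, domains, bs, enrich$n_bins,
                              clearance = clearance, n_per = n_per,
                              zero_crossing = zero_crossing)
  out <- matched_center_fold(enrich, mc)
  if (pool) {
    out$pooled <- pool_pair_submatrices(enrich, mc$test,
                                        half_width = half_width,
                                        stratum = stratum, relation = "test")
    out$pooled_control <- pool_pair_submatrices(enrich, mc$control,
                                                half_width = half_width,
                                                relation = "control")
  }
  out
}

#' Relative enrichment of paired loci versus distance
#'
#' For each separation stratum, pairs of loci are assembled under a pairing
#' rule — both loci within `near_dist` of a COH site, or exactly one — with
#' the requested domain relation, pooled, and summarized as the log2
#' center-relative fold.
#'
#' @param enrich a [compute_enrichment()] object.
#' @param sites COH site positions (bp).
#' @param domains `domain_set` or generator domains table.
#' @param strata list of c(lo, hi) separation ranges (bp).
#' @param rule `"both"` (both loci near a COH site) or `"one"` (exactly one).
#' @param relation `"intra"` or `"inter"`.
#' @param near_dist proximity threshold to a COH site (bp, default 5 Kb).
#' @param min_pairs strata with fewer pairs error out.
#' @param max_pairs deterministic subsampling cap per stratum.
#' @param half_width pooled submatrix half-width (bp).
#' @param n_per control pairs per test pair (matched on separation, relation
#'   and domain class; see [matched_control_pairs()]).
#' @return object of class `enrichment_curve`: data.table with `stratum_lo`,
#'   `stratum_hi`, `value` (log2 fold over matched controls), `n_pairs`.
#' @export
enrichment_vs_distance <- function(enrich, sites, domains, strata,
                                   rule = c("both", "one"),
                                   relation = c("intra", "inter"),
                                   near_dist = 5e3, min_pairs = 30L,
                                   max_pairs = 2000L, half_width = 4e4,
                                   n_per = 3L) {
  rule <- match.arg(rule)
  relation <- match.arg(relation)
  stopifnot(inherits(enrich, "hic_enrichment"))
  bs <- enrich$bin_size
  n <- enrich$n_bins
  sites <- sort(sites)
  out <- data.table(stratum_lo = vapply(strata, `[`, 0, 1),
                    stratum_hi = vapply(strata, `[`, 0, 2),
                    value = NA_real_, n_pairs = 0L)
  if (rule == "one") {
    # loci far from any COH site, on a regular grid for determinism
    centers <- (seq_len(n) - 0.5) * bs
    far <- centers[nearest_distance(centers, sites) > 2 * near_dist]
    far <- far[seq(1, length(far), by = 5)]  # thin the grid 5x
  }
  for (q in seq_along(strata)) {
    st <- strata[[q]]
    pr <- if (rule == "both") {
      site_pairs(sites, NULL, domains, st, relation, bs, n,
                 max_pairs = max_pairs)
    } else {
      site_pairs(sites, far, domains, st, relation, bs, n,
                 max_pairs = max_pairs)
    }
    if (nrow(pr) < min_pairs)
      stopf("stratum %g-%g: only %d pairs (need >= %d)",
            st[1], st[2], nrow(pr), min_pairs)
    mc <- matched_control_pairs(pr, sites, domains, bs, n,
                                clearance = near_dist, n_per = n_per,
                                zero_crossing = FALSE)
    mf <- matched_center_fold(enrich, mc)
    out[q, `:=`(value = log2(mf$fold), n_pairs = mf$n_pairs)]
  }
  structure(out[], class = c("enrichment_curve", class(out)))
}

#' Contact-preference grid between element classes
#'
#' Center-relative fold enrichment for every pair of element classes (e.g.
#' COH, CTCF-only, active/silent TSSs, enhancers) at one separation stratum
#' and domain relation.
#'
#' @param enrich a [compute_enrichment()] object.
#' @param class_sets named list of position vectors (bp).
#' @param domains `domain_set` or generator domains table.
#' @param stratum c(lo, hi) separation range (bp).
#' @param relation `"intra"` or `"inter"`.
#' @param sites COH site positions for control clearance (defaults to the
#'   `COH` class set if present, else the union of all classes).
#' @param max_pairs,half_width,n_per as in [enrichment_vs_distance()].
#' @return symmetric matrix of folds (class x class) over matched controls.
#' @export
class_contact_grid <- function(enrich, class_sets, domains, stratum,
                               relation = c("intra", "inter"), sites = NULL,
                               max_pairs = 2000L, half_width = 4e4,
                               n_per = 3L) {
  relation <- match.arg(relation)
  stopifnot(inherits(enrich, "hic_enrichment"))
  if (!length(class_sets) || any(!vapply(class_sets, length, 0L)))
    stopf("every class set must be non-empty")
  if (is.null(sites))
    sites <- class_sets[["COH"]] %||% sort(unlist(class_sets))
  cls <- names(class_sets)
  bs <- enrich$bin_size
  n <- enrich$n_bins
  g <- matrix(NA_real_, length(cls), length(cls), dimnames = list(cls, cls))
  for (a in seq_along(cls)) {
    for (b in a:length(cls)) {
      pr <- site_pairs(class_sets[[a]],
                       if (a == b) NULL else class_sets[[b]],
                       domains, stratum, relation, bs, n,
                       max_pairs = max_pairs)
      if (!nrow(pr)) next
      mc <- matched_control_pairs(pr, sites, domains, bs, n,
                                  n_per = n_per, zero_crossing = FALSE)
      g[a, b] <- g[b, a] <- matched_center_fold(enrich, mc)$fold
    }
  }
  g
}
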
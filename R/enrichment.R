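#' Observed/expected contact enrichment
#'
#' Combines counts, decay expectation and bias factors into the corrected
#' contact enrichment `e_ij = log2((c_ij + psi) / (b_i b_j f(d_ij) + psi))`.
#' Values are materialized on demand (per cell set or per distance band), so
#' chromosome-length grids never require a dense matrix.
#'
#' @param counts a [contact_counts()] object.
#' @param decay matching [estimate_distance_decay()] curve (estimated from
#'   these counts, or a shared reference curve for differential maps).
#' @param biases matching [estimate_bin_biases()] result.
#' @param pseudocount pseudocount `psi` added to observed and expected;
#'   stabilizes the log at sparse long-range cells.
#' @return object of class `hic_enrichment`.
#' @export
compute_enrichment <- function(counts, decay, biases, pseudocount = 1) {
  stopifnot(inherits(counts, "contact_counts"),
            inherits(decay, "decay_curve"),
            inherits(biases, "bias_vector"))
  if (decay$n_bins != counts$n_bins || decay$bin_size != counts$bin_size)
    stopf("decay curve and counts are on different bin grids")
  if (length(biases$b) != counts$n_bins)
    stopf("bias vector and counts are on different bin grids")
  structure(list(counts = counts, decay = decay, biases = biases,
                 pseudocount = pseudocount,
                 bin_size = counts$bin_size, n_bins = counts$n_bins),
            class = "hic_enrichment")
}

#' Convenience wrapper: decay + bias + enrichment from raw counts
#' @inheritParams compute_enrichment
#' @inheritParams estimate_bin_biases
#' @export
normalize_contacts <- function(counts, pseudocount = 1, mask_frac = 0.2) {
  decay <- estimate_distance_decay(counts)
  biases <- estimate_bin_biases(counts, decay, mask_frac = mask_frac)
  compute_enrichment(counts, decay, biases, pseudocount = pseudocount)
}

#' @export
print.hic_enrichment <- function(x, ...) {
  cat(sprintf("<hic_enrichment> %d bins @ %g Kb, psi=%g, %d bins masked\n",
              x$n_bins, x$bin_size / 1e3, x$pseudocount, sum(x$biases$mask)))
  invisible(x)
}

#' Expected and enrichment values at cells
#'
#' Vectorized accessors; `i`, `j` are 1-based bin indices (any order). `NA`
#' where either bin is masked or `i == j`.
#'
#' @param enrich a [compute_enrichment()] object.
#' @param i,j bin indices.
#' @return numeric vector.
#' @export
expected_at <- function(enrich, i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  d <- hi - lo
  out <- rep(NA_real_, length(d))
  ok <- d > 0 & !enrich$biases$mask[lo] & !enrich$biases$mask[hi]
  out[ok] <- enrich$biases$b[lo[ok]] * enrich$biases$b[hi[ok]] *
    enrich$decay$f_dist[d[ok]]
  out
}

#' @rdname expected_at
#' @export
enrichment_at <- function(enrich, i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  expd <- expected_at(enrich, i, j)
  cnt <- contact_lookup(enrich$counts, lo, hi)
  log2((cnt + enrich$pseudocount) / (expd + enrich$pseudocount))
}

# Banded representation: matrix B with B[i, d] = e_{i, i+d}, d = 1..max_d.
# Shared workhorse for insulation tracks and distance-stratified statistics.
enrichment_band <- function(enrich, max_d, what = c("enrichment", "obs", "exp")) {
  what <- match.arg(what)
  n <- enrich$n_bins
  max_d <- min(max_d, n - 1L)
  b <- enrich$biases$b
  mask <- enrich$biases$mask
  psi <- enrich$pseudocount
  cnt <- matrix(0, n, max_d)
  ent <- enrich$counts$entries[j - i <= max_d & j > i]
  if (nrow(ent)) cnt[cbind(ent$i, ent$j - ent$i)] <- ent$count
  if (what == "obs") out <- cnt
  else {
    expd <- matrix(NA_real_, n, max_d)
    for (d in seq_len(max_d)) {
      idx <- seq_len(n - d)
      expd[idx, d] <- b[idx] * b[idx + d] * enrich$decay$f_dist[d]
    }
    out <- if (what == "exp") expd else log2((cnt + psi) / (expd + psi))
  }
  for (d in seq_len(max_d)) {
    bad <- which(mask | c(mask[-seq_len(d)], rep(TRUE, d)))
    out[bad, d] <- NA_real_
  }
  out
}

#' @describeIn compute_enrichment dense symmetric enrichment matrix (small
#'   grids only; `NA` on the diagonal and masked bins).
#' @param x a `hic_enrichment` object.
#' @param ... unused.
#' @export
as.matrix.hic_enrichment <- function(x, ...) {
  n <- x$n_bins
  if (n > 3000) stopf("refusing to densify %d bins", n)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  e <- enrichment_at(x, idx[, 1], idx[, 2])
  m <- matrix(NA_real_, n, n)
  m[idx] <- e
  m[idx[, c(2, 1)]] <- e
  m
}

#' Differential contact map
#'
#' Normalized enrichment difference between two conditions sharing one
#' reference expectation. Condition B's counts are scaled to condition A's
#' total; each condition gets its own bias vector, but both are normalized
#' against a shared decay curve so that genuine redistribution of contacts
#' (rather than the global decay change) shows up in the difference
#' `delta_ij = e_B - e_A`.
#'
#' @param counts_A,counts_B [contact_counts()] on the same bin grid
#'   (A = control/reference).
#' @param reference `"A"` (decay estimated from condition A; the control
#'   defines the expectation) or `"pooled"` (decay from the cell-wise mean of
#'   both scaled maps; makes the difference exactly antisymmetric under
#'   swapping).
#' @param pseudocount,mask_frac as in [compute_enrichment()] /
#'   [estimate_bin_biases()].
#' @return object of class `delta_map` with elements `en_A`, `en_B`.
#' @export
delta_matrix <- function(counts_A, counts_B, reference = c("A", "pooled"),
                         pseudocount = 1, mask_frac = 0.2) {
  reference <- match.arg(reference)
  stopifnot(inherits(counts_A, "contact_counts"),
            inherits(counts_B, "contact_counts"))
  if (counts_A$n_bins != counts_B$n_bins ||
      counts_A$bin_size != counts_B$bin_size)
    stopf("contact maps are on different bin grids")
  if (counts_A$total <= 0 || counts_B$total <= 0)
    stopf("both conditions need non-zero totals")
  common <- sqrt(counts_A$total * counts_B$total)
  tot_ref <- if (reference == "A") counts_A$total else common
  sA <- tot_ref / counts_A$total
  sB <- tot_ref / counts_B$total
  A2 <- if (sA == 1) counts_A else
    contact_counts(counts_A$entries[, .(i, j, count = count * sA)],
                   counts_A$bin_size, counts_A$n_bins)
  B2 <- contact_counts(counts_B$entries[, .(i, j, count = count * sB)],
                       counts_B$bin_size, counts_B$n_bins)
  decay <- if (reference == "A") {
    estimate_distance_decay(A2)
  } else {
    pooled <- contact_counts(
      rbind(A2$entries[, .(i, j, count = count / 2)],
            B2$entries[, .(i, j, count = count / 2)]),
      counts_A$bin_size, counts_A$n_bins)
    estimate_distance_decay(pooled)
  }
  bias_A <- estimate_bin_biases(A2, decay, mask_frac = mask_frac)
  bias_B <- estimate_bin_biases(B2, decay, mask_frac = mask_frac)
  structure(list(en_A = compute_enrichment(A2, decay, bias_A, pseudocount),
                 en_B = compute_enrichment(B2, decay, bias_B, pseudocount),
                 reference = reference,
                 bin_size = counts_A$bin_size, n_bins = counts_A$n_bins),
            class = "delta_map")
}

#' @export
print.delta_map <- function(x, ...) {
  cat(sprintf("<delta_map> %d bins @ %g Kb, reference=%s\n",
              x$n_bins, x$bin_size / 1e3, x$reference))
  invisible(x)
}

#' @rdname expected_at
#' @param delta a [delta_matrix()] object.
#' @export
delta_at <- function(delta, i, j) {
  enrichment_at(delta$en_B, i, j) - enrichment_at(delta$en_A, i, j)
}

# banded delta values (B minus A)
delta_band <- function(delta, max_d) {
  enrichment_band(delta$en_B, max_d) - enrichment_band(delta$en_A, max_d)
}

#' Mean enrichment difference over a cell group
#'
#' Average `delta_ij` over intra-domain cells or over inter-domain cells of
#' adjacent domains. Because the two cell groups have very different
#' separation compositions (intra-domain cells concentrate below the domain
#' scale, adjacent-domain cells above it) and the per-cell difference is a
#' distance-sensitive quantity, the mean is computed per log2-spaced
#' separation stratum and the strata are averaged with equal weight —
#' the group mean is distance-controlled, like every other contact statistic
#' here. `stratified = FALSE` gives the raw per-cell mean.
#'
#' @param delta a [delta_matrix()] object.
#' @param domains a `domain_set` or the generator's `domains` table
#'   (`start_bin`, `end_bin`).
#' @param relation `"intra"` (both bins in one domain) or `"inter_adjacent"`
#'   (bins in adjacent domains).
#' @param max_sep maximum separation (bp) of included cells.
#' @param min_sep minimum separation (bp); the default 10 Kb excludes the
#'   very-short-range cells that are artifact-dominated in real libraries.
#' @param stratified average per-octave stratum means (default) or all cells.
#' @return mean delta over the selected cells.
#' @export
delta_group_mean <- function(delta, domains, relation = c("intra", "inter_adjacent"),
                             max_sep = 2e6, min_sep = 1e4,
                             stratified = TRUE) {
  relation <- match.arg(relation)
  dom <- domain_table(domains)
  n <- delta$n_bins
  dom_id <- integer(n)
  for (k in seq_len(nrow(dom))) dom_id[dom$start_bin[k]:dom$end_bin[k]] <- k
  max_d <- min(n - 1L, floor(max_sep / delta$bin_size))
  min_d <- max(1L, ceiling(min_sep / delta$bin_size))
  dl <- delta_band(delta, max_d)
  edges <- unique(pmin(ceiling(min_d * 2^(0:40)), max_d))
  edges <- edges[edges >= min_d]
  lo <- min_d
  strata_means <- numeric(0)
  tot <- 0; cnt <- 0
  for (hi in edges) {
    s <- 0; k <- 0
    for (d in lo:hi) {
      idx <- seq_len(n - d)
      rel <- dom_id[idx + d] - dom_id[idx]
      sel <- if (relation == "intra") rel == 0L else rel == 1L
      v <- dl[idx, d][sel]
      v <- v[is.finite(v)]
      s <- s + sum(v); k <- k + length(v)
    }
    if (k > 0) strata_means <- c(strata_means, s / k)
    tot <- tot + s; cnt <- cnt + k
    lo <- hi + 1L
    if (lo > max_d) break
  }
  if (cnt == 0) return(NA_real_)
  if (stratified) mean(strata_means) else tot / cnt
}
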
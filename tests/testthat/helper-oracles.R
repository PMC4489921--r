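# Independent dense brute-force recomputations used as oracles. These mirror
# the definitions, not the package code paths (dense matrices and explicit
# loops; no FFT, no banded cumulative sums, no data.table joins).

oracle_decay_fdist <- function(counts, shell_ratio = 2^0.25) {
  m <- as.matrix(counts)
  n <- nrow(m)
  bs <- counts$bin_size
  max_dist <- (n - 1) * bs
  n_edges <- ceiling(log(max_dist / bs) / log(shell_ratio)) + 1
  edges <- bs * shell_ratio^(0:max(n_edges, 1))
  edges[length(edges)] <- max(edges[length(edges)], max_dist + bs)
  shell_of <- findInterval((1:(n - 1)) * bs, edges, rightmost.closed = TRUE)
  f_dist <- numeric(n - 1)
  for (k in seq_len(max(shell_of))) {
    ds <- which(shell_of == k)
    tot <- 0; np <- 0
    for (d in ds) {
      for (i in seq_len(n - d)) tot <- tot + m[i, i + d]
      np <- np + (n - d)
    }
    f_dist[ds] <- tot / np
  }
  f_dist
}

oracle_biases <- function(counts, f_dist, mask_frac = 0.2, tol = 1e-4,
                          max_iter = 200, damp = 0.5, detrend_window = 1e5) {
  m <- as.matrix(counts)
  n <- nrow(m)
  marg <- rowSums(m)
  mask <- marg < mask_frac * median(marg)
  b <- rep(1, n); b[mask] <- 0
  for (it in seq_len(max_iter)) {
    expd <- numeric(n)
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(n)) if (j != i) s <- s + b[j] * f_dist[abs(i - j)]
      expd[i] <- b[i] * s
    }
    bn <- b
    ok <- !mask & expd > 0
    bn[ok] <- b[ok] * (marg[ok] / expd[ok])^damp
    gm <- exp(mean(log(bn[!mask & bn > 0])))
    bn[!mask] <- bn[!mask] / gm
    delta <- max(abs(bn[!mask] - b[!mask]) / pmax(b[!mask], 1e-12))
    b <- bn
    if (delta < tol) break
  }
  braw <- b; braw[mask] <- NA_real_
  w_bins <- max(1, round(detrend_window / counts$bin_size))
  half <- w_bins %/% 2
  lb <- log(braw)
  sm <- vapply(seq_len(n), function(i) {
    wnd <- lb[max(1, i - half):min(n, i + half)]
    mean(wnd[is.finite(wnd)])
  }, 0)
  bout <- exp(lb - sm)
  bout[!mask] <- bout[!mask] / exp(mean(log(bout[!mask])))
  list(b = bout, mask = mask)
}

oracle_dense_e <- function(counts, f_dist, b, psi = 1) {
  m <- as.matrix(counts)
  n <- nrow(m)
  e <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (is.na(b[i]) || is.na(b[j])) next
      expd <- b[i] * b[j] * f_dist[j - i]
      e[i, j] <- e[j, i] <- log2((m[i, j] + psi) / (expd + psi))
    }
  }
  e
}

# mean-statistic band insulation by explicit double loop
oracle_insulation <- function(e_dense, k, min_pairs = 10) {
  n <- nrow(e_dense)
  out <- rep(NA_real_, n)
  for (x in (k + 1):(n - k + 1)) {
    vals <- c()
    for (i in (x - k):(x - 1)) {
      for (j in x:(x + k - 1)) vals <- c(vals, e_dense[i, j])
    }
    vals <- vals[is.finite(vals)]
    if (length(vals) >= min_pairs) out[x] <- mean(vals)
  }
  out
}

oracle_pool <- function(e_dense, pairs, hw_bins) {
  n <- nrow(e_dense)
  n_off <- 2 * hw_bins + 1
  M <- matrix(NA_real_, n_off, n_off)
  cnt <- matrix(0, n_off, n_off)
  sums <- matrix(0, n_off, n_off)
  for (ui in seq_len(n_off)) {
    for (vi in seq_len(n_off)) {
      u <- ui - hw_bins - 1; v <- vi - hw_bins - 1
      for (r in seq_len(nrow(pairs))) {
        i <- pairs$bin1[r] + u; j <- pairs$bin2[r] + v
        if (i < 1 || j > n || i >= j) next
        val <- e_dense[i, j]
        if (!is.finite(val)) next
        sums[ui, vi] <- sums[ui, vi] + val
        cnt[ui, vi] <- cnt[ui, vi] + 1
      }
      if (cnt[ui, vi] > 0) M[ui, vi] <- sums[ui, vi] / cnt[ui, vi]
    }
  }
  list(M = M, n = cnt)
}

oracle_sliding_median <- function(v, half_bins) {
  n <- length(v)
  vapply(seq_len(n), function(x) {
    median(v[max(1, x - half_bins):min(n, x + half_bins)])
  }, 0)
}

oracle_intervening <- function(e_dense, site_bins, d_lo, d_hi, cap = 6) {
  n <- nrow(e_dense)
  site_cum <- cumsum(tabulate(site_bins, nbins = n))
  es <- c(); ks <- c()
  for (d in d_lo:d_hi) {
    for (i in seq_len(n - d)) {
      val <- e_dense[i, i + d]
      if (!is.finite(val)) next
      k <- site_cum[i + d - 1] - site_cum[i]
      es <- c(es, val); ks <- c(ks, min(k, cap))
    }
  }
  gm <- mean(es)
  agg <- tapply(es, ks, mean) - gm
  data.frame(k = as.integer(names(agg)), relative_e = as.numeric(agg))
}
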
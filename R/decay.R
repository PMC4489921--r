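#' Distance-decay curve
#'
#' Mean contact count per bin pair as a function of genomic separation,
#' estimated in log-spaced distance shells. This is the expectation term used
#' to control for the characteristic decrease of contact probability with
#' genomic distance.
#'
#' @param counts a [contact_counts()] object.
#' @param shell_ratio multiplicative spacing of shell edges (default
#'   `2^0.25`, i.e. four shells per distance doubling).
#' @return object of class `decay_curve`: list with `edges` (shell edges, bp),
#'   `mid` (geometric mean shell distance, bp), `f` (mean count per pair in
#'   shell), `f_dist` (per-bin-distance lookup, length `n_bins - 1`),
#'   `bin_size`, `n_bins`.
#' @export
estimate_distance_decay <- function(counts, shell_ratio = 2^0.25) {
  stopifnot(inherits(counts, "contact_counts"))
  if (!nrow(counts$entries)) stopf("empty contact counts")
  n <- counts$n_bins
  bs <- counts$bin_size
  max_dist <- (n - 1) * bs
  n_edges <- ceiling(log(max_dist / bs) / log(shell_ratio)) + 1L
  edges <- bs * shell_ratio^(0:max(n_edges, 1L))
  edges[length(edges)] <- max(edges[length(edges)], max_dist + bs)

  d_bins <- seq_len(n - 1L)
  shell_of_d <- findInterval(d_bins * bs, edges, rightmost.closed = TRUE)
  npairs_d <- n - d_bins
  sum_d <- numeric(n - 1L)
  ent <- counts$entries[j > i]
  if (nrow(ent)) {
    agg <- ent[, .(s = sum(count)), by = .(d = j - i)]
    sum_d[agg$d] <- agg$s
  }
  K <- max(shell_of_d)
  sum_shell <- vapply(seq_len(K), function(k) sum(sum_d[shell_of_d == k]), 0)
  np_shell <- vapply(seq_len(K), function(k) sum(npairs_d[shell_of_d == k]), 0)
  f <- ifelse(np_shell > 0, sum_shell / np_shell, NA_real_)
  mid <- sqrt(edges[seq_len(K)] * edges[seq_len(K) + 1L])
  f_dist <- f[shell_of_d]
  structure(list(edges = edges[seq_len(K + 1L)], mid = mid, f = f,
                 f_dist = f_dist, bin_size = bs, n_bins = n),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> %d shells over [%g, %g] bp\n",
              length(x$f), x$edges[1], x$edges[length(x$edges)]))
  invisible(x)
}

#' Fit a power-law exponent to a decay curve
#'
#' Log-log regression of the shell means against shell distance. The default
#' range (4-100 Kb) targets the regime where cis decay is locally power-law:
#' above bin-level noise and below the domain scale, where border effects
#' bend the curve away from a power law.
#'
#' @param decay a [estimate_distance_decay()] result.
#' @param fit_range distance range (bp) used for the fit.
#' @return fitted exponent (slope of log f vs log d).
#' @export
fit_decay_exponent <- function(decay, fit_range = c(4e3, 1e5)) {
  stopifnot(inherits(decay, "decay_curve"))
  use <- decay$mid >= fit_range[1] & decay$mid <= fit_range[2] &
    is.finite(decay$f) & decay$f > 0
  if (sum(use) < 3) stopf("fewer than 3 usable shells in fit range")
  x <- log(decay$mid[use]); y <- log(decay$f[use])
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
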
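# Shared fixtures, built lazily and cached for the whole test run.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

# small, fast simulation (12 Mb, 2.5M reads) for unit tests
small_config <- function(...) {
  sim_config(chromosome_length = 1.2e7, n_domains = 12, depth = 2.5e6,
             gene_density = 12, seed = 11, ...)
}

small_genome <- function() fixture("small_genome", function() {
  build_genome(small_config())
})

small_wt <- function() fixture("small_wt", function() {
  simulate_contacts(small_genome(), "wt", small_config())
})

small_en <- function() fixture("small_en", function() {
  normalize_contacts(small_wt())
})

# structure-off configuration: pure power-law decay + biases
flat_config <- function(depth = 2.5e6, ...) {
  sim_config(chromosome_length = 1.2e7, n_domains = 12, depth = depth,
             active_intensity_ratio = 1, border_attenuation_wt = 1,
             site_attenuation_wt = 1, anchor_enrichment_wt = 1,
             seed = 12, ...)
}

# default-size genome (annotation only, no contact map): cheap to build
big_genome <- function() fixture("big_genome", function() {
  build_genome(sim_config(seed = 1))
})

# default-scale fixtures for the acceptance tests (built once; several
# criteria share them)
default_config <- function() sim_config(seed = 1)

default_fixture <- function() fixture("default_fixture", function() {
  t0 <- proc.time()[["elapsed"]]
  cfg <- default_config()
  g <- build_genome(cfg)
  wt <- simulate_contacts(g, "wt", cfg)
  ko <- simulate_contacts(g, "ko", cfg)
  en <- normalize_contacts(wt)
  enk <- normalize_contacts(ko)
  list(cfg = cfg, g = g, wt = wt, ko = ko, en = en, enk = enk,
       coh = sort(g$sites[g$sites$class == "COH", ][["pos"]]),
       build_seconds = proc.time()[["elapsed"]] - t0)
})

# dense contact_counts from a symmetric matrix (upper triangle, 1-based)
toy_counts <- function(mat, bin_size = 2e3) {
  n <- nrow(mat)
  idx <- which(upper.tri(mat) & mat != 0, arr.ind = TRUE)
  contact_counts(data.frame(i = idx[, 1], j = idx[, 2],
                            count = mat[idx]),
                 bin_size = bin_size, n_bins = n)
}

# hand-made decay curve with a constant (or supplied) per-distance value
toy_decay <- function(n_bins, f_dist, bin_size = 2e3) {
  if (length(f_dist) == 1) f_dist <- rep(f_dist, n_bins - 1)
  structure(list(edges = c(bin_size, n_bins * bin_size),
                 mid = sqrt(bin_size * n_bins * bin_size),
                 f = mean(f_dist), f_dist = f_dist,
                 bin_size = bin_size, n_bins = n_bins),
            class = "decay_curve")
}

toy_biases <- function(b, mask = rep(FALSE, length(b))) {
  bb <- b
  bb[mask] <- NA_real_
  structure(list(b = bb, mask = mask, converged = TRUE, n_iter = 0L,
                 marginal = rep(1, length(b))),
            class = "bias_vector")
}

# enrichment object with constant e == value everywhere (f and b flat)
constant_enrichment <- function(n_bins, value = 0, bin_size = 2e3,
                                f0 = 4, psi = 1) {
  cnt <- 2^value * (f0 + psi) - psi
  mat <- matrix(cnt, n_bins, n_bins)
  diag(mat) <- 0
  cc <- toy_counts(mat, bin_size)
  compute_enrichment(cc, toy_decay(n_bins, f0, bin_size),
                     toy_biases(rep(1, n_bins)), pseudocount = psi)
}

# random sparse toy map with planted decay, for oracle comparisons
random_toy_map <- function(n_bins = 150, seed = 42, bin_size = 2e3,
                           mean_count = 8) {
  set.seed(seed)
  mat <- matrix(0, n_bins, n_bins)
  ut <- which(upper.tri(mat), arr.ind = TRUE)
  d <- ut[, 2] - ut[, 1]
  lam <- mean_count / d
  mat[ut] <- rpois(nrow(ut), lam)
  mat <- mat + t(mat)
  toy_counts(mat, bin_size)
}
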
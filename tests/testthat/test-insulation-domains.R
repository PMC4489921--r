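test_that("insulation track: constant input, brute-force oracle, guards", {
  en <- constant_enrichment(60, value = 0.7, f0 = 10)
  tr <- band_insulation_track(en, w = 1e4)   # k = 5 bins
  vals <- tr$values[!is.na(tr$values)]
  expect_true(all(abs(vals - 0.7) < 1e-12))
  expect_true(all(is.na(tr$values[1:5])))    # undefined near the ends

  expect_error(band_insulation_track(en, w = 5e3), "multiple|at least")
  expect_error(band_insulation_track(en, w = 6e3), "at least 5")

  # 30-bin toy, w = 5 bins: equality with the explicit double loop
  cc <- random_toy_map(30, seed = 9, mean_count = 15)
  dec <- estimate_distance_decay(cc)
  bv <- estimate_bin_biases(cc, dec)
  en2 <- compute_enrichment(cc, dec, bv)
  tr2 <- band_insulation_track(en2, w = 1e4, min_pairs = 1L)
  e_dense <- oracle_dense_e(cc, dec$f_dist, bv$b)
  io <- oracle_insulation(e_dense, k = 5, min_pairs = 1)
  expect_equal(tr2$values, io, tolerance = 1e-12)
})

test_that("tracks and profiles shift with an added constant (affine behaviour)", {
  en_a <- constant_enrichment(200, value = 0.2, f0 = 10)
  en_b <- constant_enrichment(200, value = 1.2, f0 = 10)
  ta <- band_insulation_track(en_a, 2e4)
  tb <- band_insulation_track(en_b, 2e4)
  keep <- !is.na(ta$values)
  expect_equal(tb$values[keep] - ta$values[keep], rep(1, sum(keep)),
               tolerance = 1e-9)
  # peak-to-trough is invariant to the constant
  sites <- seq(1e5, 3.5e5, by = 2e4)
  pa <- cohesim:::meta_profile_from_track(ta, sites, min_sites = 5)
  pb <- cohesim:::meta_profile_from_track(tb, sites, min_sites = 5)
  expect_equal(pa$peak_to_trough, pb$peak_to_trough, tolerance = 1e-9)
})

test_that("meta profile equals the mean of per-site insulation vectors", {
  en <- small_en()
  g <- small_genome()
  coh <- g$sites[g$sites$class == "COH", ][["pos"]]
  tr <- band_insulation_track(en, 4e4)
  mp <- cohesim:::meta_profile_from_track(tr, coh)
  # independent per-site recomputation
  k <- 4e4 / en$bin_size
  offs <- (-2 * k):(2 * k)
  s_bins <- cohesim:::pos_to_bin(coh, en$bin_size)
  V <- sapply(offs, function(o) {
    idx <- s_bins + o
    idx[idx < 1 | idx > en$n_bins] <- NA
    tr$values[idx]
  })
  usable <- rowSums(is.finite(V)) > 0
  expect_equal(mp$P, colMeans(V[usable, ], na.rm = TRUE), tolerance = 1e-12)
  expect_equal(mp$n_sites, sum(usable))
  # too few usable sites errors, naming the band
  expect_error(cohesim:::meta_profile_from_track(tr, coh[1:3], min_sites = 50),
               "usable sites")
})

test_that("site grouping by insulation: ranking and partition arithmetic", {
  tr <- structure(list(values = c(NA, 0.4, 0.1, 0.9, 0.3, NA),
                       w = 1e4, bin_size = 2e3, n_bins = 6,
                       n_cells = rep(100, 6), min_pairs = 10,
                       statistic = "mean"),
                  class = "insulation_track")
  sites <- c(3000, 5000, 7000, 9000)   # bins 2..5
  grp <- group_sites_by_insulation(tr, sites, min_defined_frac = 0.5)
  expect_equal(grp$group, c("middle", "bottom", "top", "middle"))
  # sizes differ by <= 1 from n/4, n/2, n/4
  g2 <- small_genome()
  coh <- g2$sites[g2$sites$class == "COH", ][["pos"]]
  tr2 <- band_insulation_track(small_en(), 8e4)
  grp2 <- group_sites_by_insulation(tr2, coh)
  tab <- table(grp2$group)
  nk <- nrow(grp2)
  expect_lte(abs(tab[["bottom"]] - nk / 4), 1)
  expect_lte(abs(tab[["top"]] - nk / 4), 1)
  expect_lte(abs(tab[["middle"]] - nk / 2), 1)
})

test_that("border calling: monotone input yields none, planted borders found", {
  mono <- structure(list(values = seq(-1, 1, length.out = 3000),
                         w = 6.4e5, bin_size = 2e3, n_bins = 3000,
                         n_cells = rep(100, 3000), min_pairs = 10,
                         statistic = "ratio"),
                    class = "insulation_track")
  expect_equal(length(call_domains(mono)$borders), 0L)

  en <- small_en()
  g <- small_genome()
  tr <- band_insulation_track(en, 6.4e5, statistic = "ratio")
  ds <- call_domains(tr)
  truth <- g$domains$start_bin[-1]
  hits <- vapply(truth, function(b) min(abs(ds$borders - b)), 0)
  expect_gte(mean(hits <= 2), 0.8)
  # domains partition the bin range
  expect_equal(ds$domains$start_bin[1], 1L)
  expect_equal(ds$domains$end_bin[nrow(ds$domains)], g$n_bins)
})

test_that("domain classification recovers planted classes and flags degeneracy", {
  en <- small_en()
  g <- small_genome()
  dcl <- classify_domain_activity(en, g$domains, g$genes$tss)
  expect_false(attr(dcl, "degenerate"))
  expect_gte(mean(dcl$domains$class == g$domains$class), 0.9)
  # order invariance of the labels
  perm <- sample(nrow(g$domains))
  dperm <- g$domains[perm, ]
  dcl2 <- classify_domain_activity(en, dperm, g$genes$tss)
  expect_equal(dcl2$domains$class, dcl$domains$class[perm])
  # identical features -> degenerate flag
  enc <- constant_enrichment(400, value = 0, f0 = 10)
  domc <- data.frame(start_bin = seq(1, 400, by = 100),
                     end_bin = c(seq(100, 300, by = 100), 400))
  dclc <- classify_domain_activity(enc, domc, tss = numeric(0))
  expect_true(attr(dclc, "degenerate"))
})

test_that("adjacent-spacing KS: exact degenerate values and planted contrast", {
  two_dom <- data.frame(start_bin = c(1L, 501L), end_bin = c(500L, 1000L),
                        class = c("active", "passive"))
  grid_sites <- function(spacing_active, spacing_passive) {
    data.frame(pos = c(seq(5e3, 9.9e5, by = spacing_active),
                       seq(1.005e6, 1.99e6, by = spacing_passive)),
               class = "COH")
  }
  # identical spacing lists -> D = 0
  sc0 <- suppressWarnings(
    adjacent_spacing_ks(grid_sites(2e4, 2e4), two_dom, bin_size = 2e3))
  expect_equal(sc0$D, 0)
  # disjoint spacing supports -> D = 1
  sc1 <- suppressWarnings(
    adjacent_spacing_ks(grid_sites(1e4, 4e4), two_dom, bin_size = 2e3))
  expect_equal(sc1$D, 1)

  g <- big_genome()
  sc <- adjacent_spacing_ks(g$sites, g$domains, bin_size = 2e3)
  expect_gt(sc$D, 0)
  expect_lt(sc$p_value, 0.01)
  expect_true(sc$D >= 0 && sc$D <= 1)
})

test_that("intervening-site curve: centering, oracle equality, trend", {
  en <- small_en()
  # no sites -> single k = 0 group centred at zero
  ic0 <- intervening_site_curve(en, numeric(0), list(c(4e4, 8e4)))
  expect_equal(nrow(ic0), 1L)
  expect_equal(ic0$k, 0L)
  expect_equal(ic0$relative_e, 0)

  # 100-bin toy equals the brute-force recomputation
  cc <- random_toy_map(100, seed = 13, mean_count = 12)
  dec <- estimate_distance_decay(cc)
  bv <- estimate_bin_biases(cc, dec)
  en2 <- compute_enrichment(cc, dec, bv)
  sites <- c(2.1e4, 6.3e4, 1.01e5, 1.55e5)
  ic <- intervening_site_curve(en2, sites, list(c(2e4, 6e4)))
  e_dense <- oracle_dense_e(cc, dec$f_dist, bv$b)
  io <- oracle_intervening(e_dense, cohesim:::pos_to_bin(sites, 2e3),
                           d_lo = 10, d_hi = 30)
  expect_equal(ic$relative_e, io$relative_e, tolerance = 1e-12)
  expect_equal(ic$k, io$k)

  # planted structure: enrichment decreases with the intervening count
  g <- small_genome()
  coh <- g$sites[g$sites$class == "COH", ][["pos"]]
  icd <- intervening_site_curve(en, coh, list(c(6e4, 1.8e5)))
  expect_lt(cor(icd$k, icd$relative_e, method = "spearman"), 0)
})
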
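test_that("pooling: constant input, errors, brute-force oracle", {
  en <- constant_enrichment(120, value = 0.4, f0 = 10)
  pairs <- data.frame(bin1 = c(30L, 50L, 70L), bin2 = c(60L, 90L, 100L))
  pm <- pool_pair_submatrices(en, pairs, half_width = 1e4)
  expect_true(all(abs(pm$M[!is.na(pm$M)] - 0.4) < 1e-12))
  # constant matrix -> ring-background fold is exactly 1
  expect_equal(center_relative_enrichment(pm, background = "ring",
                                          space = "log2", ring_min = 4e3), 1,
               tolerance = 1e-12)
  expect_equal(center_relative_enrichment(pm, background = "ring",
                                          space = "linear", ring_min = 4e3), 1,
               tolerance = 1e-12)
  expect_error(pool_pair_submatrices(en, pairs[0, ]), "empty")

  # 5 hand-placed pairs on a 300-bin toy: equality with the explicit loops
  cc <- random_toy_map(300, seed = 17, mean_count = 10)
  dec <- estimate_distance_decay(cc)
  bv <- estimate_bin_biases(cc, dec)
  en2 <- compute_enrichment(cc, dec, bv)
  p5 <- data.frame(bin1 = c(40L, 80L, 120L, 31L, 200L),
                   bin2 = c(90L, 140L, 190L, 100L, 260L))
  pm2 <- pool_pair_submatrices(en2, p5, half_width = 2e4)
  e_dense <- oracle_dense_e(cc, dec$f_dist, bv$b)
  po <- oracle_pool(e_dense, p5, hw_bins = 10)
  expect_equal(unname(pm2$M), po$M, tolerance = 1e-12)
  expect_equal(unname(pm2$n), po$n)
})

test_that("pooling is linear: union equals the n-weighted average", {
  en <- small_en()
  g <- small_genome()
  ap <- g$anchor_pairs
  ap <- ap[(ap$bin2 - ap$bin1) >= 30 & (ap$bin2 - ap$bin1) <= 100, ]
  a <- ap[seq(1, nrow(ap), by = 2), ]
  b <- ap[seq(2, nrow(ap), by = 2), ]
  pa <- pool_pair_submatrices(en, a, half_width = 2e4)
  pb <- pool_pair_submatrices(en, b, half_width = 2e4)
  pu <- pool_pair_submatrices(en, rbind(a, b), half_width = 2e4)
  na <- pa$n; na[is.na(na)] <- 0
  nb <- pb$n; nb[is.na(nb)] <- 0
  sa <- pa$M * na; sa[is.na(sa)] <- 0
  sb <- pb$M * nb; sb[is.na(sb)] <- 0
  expected <- (sa + sb) / (na + nb)
  keep <- is.finite(pu$M)
  expect_equal(pu$M[keep], expected[keep], tolerance = 1e-12)
})

test_that("site_pairs respects separation range and domain relation", {
  g <- small_genome()
  coh <- sort(g$sites[g$sites$class == "COH", ][["pos"]])
  pr <- site_pairs(coh, NULL, g$domains, c(1e5, 2e5), "intra",
                   bin_size = 2e3, n_bins = g$n_bins)
  sep <- (pr$bin2 - pr$bin1) * 2e3
  expect_true(all(sep >= 1e5 & sep <= 2e5))
  d1 <- findInterval(pr$bin1, g$domains$start_bin)
  d2 <- findInterval(pr$bin2, g$domains$start_bin)
  expect_true(all(d1 == d2))
  pr2 <- site_pairs(coh, NULL, g$domains, c(1e5, 2e5), "inter",
                    bin_size = 2e3, n_bins = g$n_bins)
  d1 <- findInterval(pr2$bin1, g$domains$start_bin)
  d2 <- findInterval(pr2$bin2, g$domains$start_bin)
  expect_true(all(d1 != d2))
})

test_that("matched-control anchor fold recovers planted loop strength", {
  en <- small_en()
  g <- small_genome()
  cfg <- small_config()
  coh <- sort(g$sites[g$sites$class == "COH", ][["pos"]])
  af <- anchor_pair_fold(en, g$anchor_pairs, coh, g$domains,
                         stratum = c(6e4, 2e5))
  expect_gt(af$fold, 1.5)
  expect_lt(af$fold, 2.8)
  ko <- fixture("small_ko", function() simulate_contacts(g, "ko", cfg))
  enk <- fixture("small_enk", function() normalize_contacts(ko))
  afk <- anchor_pair_fold(enk, g$anchor_pairs, coh, g$domains,
                          stratum = c(6e4, 2e5))
  expect_lt(abs(afk$fold - 1), 0.25)
  expect_gt(af$fold, afk$fold)
})

test_that("pooled center cell is the matrix maximum over planted loops", {
  en <- small_en()
  g <- small_genome()
  ap <- g$anchor_pairs
  ap <- ap[(ap$bin2 - ap$bin1) * 2e3 >= 6e4 & (ap$bin2 - ap$bin1) * 2e3 <= 2e5, ]
  pm <- pool_pair_submatrices(en, ap, half_width = 4e4)
  ctr <- which(pm$offsets == 0)
  expect_equal(unname(which(pm$M == max(pm$M, na.rm = TRUE), arr.ind = TRUE)[1, ]),
               c(ctr, ctr))
})

test_that("null class grid on a structureless map stays near 1", {
  cfg <- flat_config()
  g <- build_genome(cfg)
  cc <- fixture("flat_wt", function() simulate_contacts(g, "wt", cfg))
  en <- fixture("flat_en", function() normalize_contacts(cc))
  set.seed(31)
  sets <- lapply(1:4, function(q) sort(runif(120, 1e5, cfg$chromosome_length - 1e5)))
  names(sets) <- c("A", "B", "C", "D")
  one_dom <- data.frame(start_bin = 1L, end_bin = g$n_bins, class = "active")
  gr <- class_contact_grid(en, sets, one_dom, c(1e5, 1.6e5), "intra",
                           sites = sets[["A"]])
  expect_true(all(gr[is.finite(gr)] >= 0.8 & gr[is.finite(gr)] <= 1.25))
  expect_equal(gr, t(gr))
  expect_error(class_contact_grid(en, c(sets, list(E = numeric(0))),
                                  one_dom, c(1e5, 1.6e5), "intra"),
               "non-empty")
})

test_that("enrichment-vs-distance: rules behave as planted", {
  fx <- default_fixture()
  strata <- list(c(1e5, 1.5e5), c(1.5e5, 2e5))
  cv_one <- enrichment_vs_distance(fx$en, fx$coh, fx$g$domains, strata,
                                   rule = "one")
  expect_true(all(abs(cv_one$value) < 0.3))
  cv_both <- enrichment_vs_distance(fx$en, fx$coh, fx$g$domains, strata,
                                    rule = "both")
  cv_both_ko <- enrichment_vs_distance(fx$enk, fx$coh, fx$g$domains, strata,
                                       rule = "both")
  expect_true(all(cv_both$value > cv_both_ko$value))
  expect_error(enrichment_vs_distance(fx$en, fx$coh, fx$g$domains,
                                      list(c(3e7, 3.5e7)), rule = "both"),
               "pairs")
})
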
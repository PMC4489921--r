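test_that("config validation rejects inconsistent setups", {
  expect_error(sim_config(chromosome_length = 1e6 + 1), "divide")
  expect_error(sim_config(active_fraction = 1.5), "active_fraction")
  expect_error(sim_config(border_attenuation_wt = 0), "multipliers")
  expect_error(sim_config(chromosome_length = 2e6, n_domains = 10,
                          min_domain_size = 5e5), "too short")
})

test_that("genome construction: partition, ordering, degenerate cases", {
  g <- small_genome()
  dom <- g$domains
  # domains partition the bin range without gaps or overlaps
  expect_equal(dom$start_bin[1], 1L)
  expect_equal(dom$end_bin[nrow(dom)], g$n_bins)
  expect_equal(dom$start_bin[-1], head(dom$end_bin, -1) + 1L)
  # site positions strictly increasing
  expect_true(all(diff(g$sites$pos) > 0))
  # every anchor pair lies within one domain
  ap <- g$anchor_pairs
  d1 <- findInterval(ap$bin1, dom$start_bin)
  d2 <- findInterval(ap$bin2, dom$start_bin)
  expect_true(all(d1 == d2))
  # single-domain degenerate partition
  g1 <- build_genome(sim_config(chromosome_length = 2e6, n_domains = 1,
                                min_domain_size = 5e5, seed = 2))
  expect_equal(nrow(g1$domains), 1L)
  expect_equal(g1$domains$end_bin, g1$n_bins)
})

test_that("genome and contact simulation are deterministic under the seed", {
  cfg <- small_config()
  g1 <- build_genome(cfg)
  g2 <- build_genome(cfg)
  expect_identical(g1$domains, g2$domains)
  expect_identical(g1$sites, g2$sites)
  expect_identical(g1$genes, g2$genes)
  cc1 <- simulate_contacts(g1, "wt", cfg)
  cc2 <- simulate_contacts(g2, "wt", cfg)
  expect_identical(cc1$entries, cc2$entries)
  # and the caller's RNG stream is untouched
  set.seed(99); before <- .Random.seed
  invisible(build_genome(cfg))
  expect_identical(before, .Random.seed)
})

test_that("adjacent COH spacing is tighter in active than passive domains", {
  g <- small_genome()
  st <- g$sites[g$sites$class == "COH", ]
  cls <- g$domains$class[st$domain]
  sp_by <- tapply(seq_len(nrow(st)), st$domain, function(ix) {
    if (length(ix) >= 2) diff(st$pos[ix]) else NULL
  })
  spac <- unlist(sp_by[!vapply(sp_by, is.null, TRUE)])
  dom_of <- rep(as.integer(names(sp_by)[!vapply(sp_by, is.null, TRUE)]),
                vapply(sp_by[!vapply(sp_by, is.null, TRUE)], length, 0L))
  act <- g$domains$class[dom_of] == "active"
  expect_lt(mean(spac[act]), mean(spac[!act]))
})

test_that("contact counts: symmetry convention, conservation, zero depth", {
  cfg <- small_config()
  g <- small_genome()
  cc <- small_wt()
  expect_true(all(cc$entries$i <= cc$entries$j))
  expect_false(anyDuplicated(cc$entries, by = c("i", "j")) > 0)
  expect_equal(cc$total, sum(cc$entries$count))
  expect_lt(abs(cc$total - cfg$depth), 4 * sqrt(cfg$depth))
  cc0 <- simulate_contacts(g, "wt", sim_config(chromosome_length = 1.2e7,
                                               n_domains = 12, depth = 0,
                                               seed = 11))
  expect_equal(nrow(cc0$entries), 0L)
  expect_equal(cc0$total, 0)
  expect_error(condition_params(cfg, "mut"), "unknown condition")
})

test_that("structure-off simulation matches the closed-form Poisson shell mean", {
  cfg <- flat_config(bias_sd = 0)
  g <- build_genome(cfg)
  cc <- simulate_contacts(g, "wt", cfg)
  s <- attr(cc, "truth")$scale
  n <- cc$n_bins
  # empirical mean count at a few distances vs s * d^exponent, within 3 SE
  for (d in c(10L, 40L, 150L)) {
    ent <- cc$entries[cc$entries$j - cc$entries$i == d, ]
    emp <- sum(ent$count) / (n - d)
    lam <- s * d^cfg$decay_exponent_wt
    se <- sqrt(lam / (n - d))
    expect_lt(abs(emp - lam), 3 * se)
  }
})

test_that("planted anchor loops are visible in raw counts", {
  g <- small_genome()
  cc <- small_wt()
  ap <- g$anchor_pairs
  sep <- ap$bin2 - ap$bin1
  keep <- sep >= 20 & sep <= 150
  anchors <- ap[keep, ]
  obs_anchor <- mean(cohesim:::contact_lookup(cc, anchors$bin1, anchors$bin2))
  # distance-matched non-anchor cells: same separations, shifted start
  set.seed(1)
  shift <- sample(300:600, nrow(anchors), replace = TRUE)
  i2 <- anchors$bin1 + shift
  j2 <- i2 + (anchors$bin2 - anchors$bin1)
  okc <- j2 <= cc$n_bins
  obs_bg <- mean(cohesim:::contact_lookup(cc, i2[okc], j2[okc]))
  expect_gt(obs_anchor, obs_bg)
})

test_that("4C simulation: bounds, determinism, zero depth, partner signal", {
  cfg <- small_config()
  g <- small_genome()
  expect_error(simulate_fourc(g, -5, "wt", cfg), "outside")
  expect_error(simulate_fourc(g, cfg$chromosome_length + 1, "wt", cfg),
               "outside")
  ap <- g$anchor_pairs
  ap <- ap[(ap$pos2 - ap$pos1) >= 8e4 & (ap$pos2 - ap$pos1) <= 2e5, ]
  vp <- ap$pos1[1]
  v1 <- simulate_fourc(g, vp, "wt", cfg)
  v2 <- simulate_fourc(g, vp, "wt", cfg)
  expect_identical(as.numeric(v1), as.numeric(v2))
  cfg0 <- small_config(fourc_depth = 0)
  expect_true(all(simulate_fourc(g, vp, "wt", cfg0) == 0))
  # mean coverage at the partner anchor beats distance-matched background
  pbin <- cohesim:::pos_to_bin(ap$pos2[1], cfg$bin_size)
  d <- ap$pos2[1] - vp
  bg_bins <- cohesim:::pos_to_bin(c(vp - d, vp + d + 4e4, vp + d - 4e4),
                                  cfg$bin_size)
  bg_bins <- bg_bins[bg_bins >= 1 & bg_bins <= g$n_bins]
  expect_gt(mean(v1[pbin + (-1:1)]), mean(v1[bg_bins]))
})

test_that("expression simulation: noise-free replicates, planted correlation", {
  cfg <- small_config(noise_sd = 0)
  g <- build_genome(cfg)
  ex <- simulate_expression(g, cfg)
  expect_equal(ex$wt[, 1], ex$wt[, 2])
  expect_equal(ex$wt[, 1], ex$wt[, 3])
  expect_error(simulate_expression(
    build_genome(sim_config(chromosome_length = 2e6, n_domains = 2,
                            min_domain_size = 5e5, gene_density = 0,
                            seed = 1)), cfg), "no genes")

  # planted structured shifts: same-interval pair correlation near the target,
  # and near zero when the target is zero (checked on a large gene set)
  same_interval_corr <- function(g) {
    gg <- g$genes[order(g$genes$tss), ]
    hi <- findInterval(gg$tss + 2e5, gg$tss)
    lo <- findInterval(gg$tss + 1e5, gg$tss) + 1L
    keep <- hi >= lo
    L <- rep(which(keep), pmax(hi - lo + 1L, 0L)[keep])
    R <- unlist(lapply(which(keep), function(q) lo[q]:hi[q]))
    same <- gg$interval[L] == gg$interval[R]
    cor(gg$response_structured[L[same]], gg$response_structured[R[same]])
  }
  cfg1 <- sim_config(gene_density = 40, seed = 21)
  r1 <- same_interval_corr(build_genome(cfg1))
  expect_lt(abs(r1 - cfg1$response_within_interval_corr), 0.1)
  cfg0 <- sim_config(response_within_interval_corr = 0, direct_frac = 0,
                     gene_density = 40, seed = 22)
  r0 <- same_interval_corr(build_genome(cfg0))
  expect_lt(abs(r0), 0.1)
})
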
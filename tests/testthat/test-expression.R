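make_response <- function(z, mean_wt = 100, tss = NULL) {
  # synthetic response table with prescribed z-scores
  out <- data.table::data.table(
    gene = seq_along(z), mean_wt = mean_wt, mean_ko = mean_wt,
    delta = z, z = z,
    label = ifelse(z > 2, "up", ifelse(z < -2, "down", "minimal")))
  class(out) <- c("response_table", class(out))
  out
}

test_that("response z-scores: identity, partition, location invariance", {
  set.seed(41)
  wt <- matrix(2^rnorm(900, 7, 1.5), 300, 3)
  rt0 <- response_zscores(wt, wt)
  expect_true(all(rt0$delta == 0))
  expect_true(all(rt0$label %in% c("minimal", "excluded")))
  expect_true(all(rt0$label[rt0$mean_wt >= 1] == "minimal"))

  ko <- wt * matrix(2^rnorm(900, 0, 0.5), 300, 3)
  rt <- response_zscores(wt, ko)
  expect_equal(sum(table(rt$label)), 300L)           # exhaustive partition
  expect_setequal(unique(rt$label),
                  intersect(c("up", "down", "minimal", "excluded"),
                            unique(rt$label)))
  # adding a constant to all log-expressions barely moves z (location invariance)
  rt2 <- response_zscores(wt * 2^3, ko * 2^3)
  keep <- is.finite(rt$z) & is.finite(rt2$z)
  expect_lt(max(abs(rt2$z[keep] - rt$z[keep])), 0.05)
  expect_error(response_zscores(wt, ko[1:10, ]), "differ")
})

test_that("null z calibration holds on a null simulation", {
  cfg <- sim_config(direct_frac = 0, response_sd = 0, seed = 51)
  g <- build_genome(cfg)
  rt <- response_zscores(simulate_expression(g, cfg))
  frac <- mean(abs(rt$z) > 2, na.rm = TRUE)
  expect_gte(frac, 0.025)
  expect_lte(frac, 0.075)
})

test_that("planted deregulation is recovered with the correct sign", {
  rec_n <- 0; rec_ok <- 0
  for (seed in 1:2) {
    cfg <- sim_config(seed = seed)
    g <- build_genome(cfg)
    rt <- response_zscores(simulate_expression(g, cfg))
    planted <- abs(g$genes$response_direct) > 0
    ok <- rt$label[planted] %in% c("up", "down") &
      sign(rt$delta[planted]) == sign(g$genes$response_direct[planted])
    rec_n <- rec_n + sum(planted); rec_ok <- rec_ok + sum(ok)
  }
  expect_gte(rec_ok / rec_n, 0.9)
})

test_that("TSS proximity enrichment: null is flat, planted association found", {
  # null: deregulation independent of site proximity
  set.seed(43)
  n <- 600
  z <- rnorm(n)
  z[sample(n, 60)] <- 5                       # random deregulated subset
  tss <- sort(runif(n, 0, 6e7))
  sites <- sort(runif(700, 0, 6e7))
  pe <- tss_proximity_enrichment(make_response(z, tss = tss), tss, sites)
  expect_true(all(abs(pe$enrichment_pct) < 35))
  expect_equal(sum(pe$frac_all), 1)
  expect_equal(sum(pe$frac_deregulated), 1)

  # direct effects concentrated at COH-proximal genes -> enrichment at the TSS
  cfg <- sim_config(direct_frac = 0.1, coh_proximal_weight = 25,
                    proximal_dist = 1e3, response_sd = 0.3, seed = 44)
  g <- build_genome(cfg)
  rt <- response_zscores(simulate_expression(g, cfg))
  coh <- sort(g$sites[g$sites$class == "COH", ][["pos"]])
  pe2 <- tss_proximity_enrichment(rt, g$genes$tss, coh)
  expect_gt(pe2$enrichment_pct[1], 0)
})

test_that("pair response correlation: null, planted contrast, replication", {
  # i.i.d. responses -> both correlations near zero
  set.seed(45)
  n <- 1500
  tss <- sort(runif(n, 0, 6e7))
  sites <- sort(runif(700, 0, 6e7))
  pr0 <- pair_response_correlation(make_response(rnorm(n)), tss, sites)
  expect_lt(abs(pr0$r_same), 0.12)
  expect_lt(abs(pr0$r_separated), 0.12)

  # planted interval sharing: same-interval exceeds separated, CI excludes 0
  # (three replicate genomes pooled on a concatenated coordinate system)
  rts <- list(); tsss <- c(); sitess <- c(); off <- 0
  for (seed in 1:3) {
    cfg <- sim_config(seed = seed)
    g <- build_genome(cfg)
    rts[[seed]] <- response_zscores(simulate_expression(g, cfg))
    tsss <- c(tsss, g$genes$tss + off)
    sitess <- c(sitess, g$sites[g$sites$class == "COH", ][["pos"]] + off)
    off <- off + cfg$chromosome_length + 1e6
  }
  rt <- data.table::rbindlist(rts)
  class(rt) <- c("response_table", class(rt))
  pr <- pair_response_correlation(rt, tsss, sitess)
  expect_gt(pr$r_same, pr$r_separated)
  expect_gt(pr$ci[1], 0)

  # duplicating every gene pair (a second identical chromosome) leaves r unchanged
  rt2 <- data.table::rbindlist(list(rts[[1]], rts[[1]]))
  class(rt2) <- c("response_table", class(rt2))
  cfg1 <- sim_config(seed = 1); g1 <- build_genome(cfg1)
  coh1 <- g1$sites[g1$sites$class == "COH", ][["pos"]]
  pr1 <- pair_response_correlation(rts[[1]], g1$genes$tss, coh1)
  pr2 <- pair_response_correlation(rt2, c(g1$genes$tss, g1$genes$tss + 1e9),
                                   c(coh1, coh1 + 1e9))
  expect_equal(pr2$r_same, pr1$r_same, tolerance = 1e-12)
  expect_equal(pr2$n_same, 2L * pr1$n_same)
})

test_that("baseline/response trend: null, planted, rank invariance", {
  set.seed(46)
  n <- 600
  rtn <- data.table::data.table(gene = 1:n, mean_wt = 2^rnorm(n, 7, 1.5),
                                mean_ko = 1, delta = rnorm(n), z = rnorm(n),
                                label = "minimal")
  class(rtn) <- c("response_table", class(rtn))
  tr0 <- baseline_response_trend(rtn)
  expect_lt(abs(tr0$rho), 0.1)
  # rank statistic: monotone transform of the baseline leaves rho unchanged
  rtm <- data.table::copy(rtn)[, mean_wt := mean_wt^3]
  class(rtm) <- c("response_table", class(rtm))
  expect_equal(baseline_response_trend(rtm)$rho, tr0$rho)

  cfg <- sim_config(baseline_trend = 0.5, seed = 47)
  g <- build_genome(cfg)
  rt <- response_zscores(simulate_expression(g, cfg))
  expect_lt(baseline_response_trend(rt)$rho, 0)
})
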
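# R-side mirror of the C++ structure weight, for small cell sets
# (anchor-loop corrections, 4C rows, tests). i, j are 1-based bins, i < j.
# Insulating sites count only when strictly between the bins (i < s < j) and
# only for separations within the site insulation range.
structure_weights <- function(tracks, b, i, j, params, cfg,
                              site_attenuation = TRUE) {
  w <- b[i] * b[j]
  same <- tracks$dom_id[i] == tracks$dom_id[j]
  w <- w * ifelse(same & tracks$dom_active[i], cfg$active_intensity_ratio, 1)
  nb <- tracks$border_cum[j] - tracks$border_cum[i]
  w <- w * ifelse(same, 1, params$border_attenuation^nb)
  if (!site_attenuation) return(w)
  ins <- pmin(tracks$ins_cum[pmax(j - 1L, i)] - tracks$ins_cum[i],
              cfg$max_site_crossings)
  in_range <- (j - i) <= floor(cfg$site_insulation_range / cfg$bin_size)
  w * ifelse(ins > 0 & in_range, params$site_attenuation^ins, 1)
}

# cells within +/-1 bin of each anchor pair, deduplicated
anchor_cells <- function(genome) {
  ap <- genome$anchor_pairs
  if (!nrow(ap)) return(data.table(i = integer(), j = integer()))
  off <- as.integer(c(-1, 0, 1))
  grid <- data.table::CJ(u = off, v = off)  # 9 offset combinations
  cells <- data.table(
    i = rep(ap$bin1, each = nrow(grid)) + rep(grid$u, nrow(ap)),
    j = rep(ap$bin2, each = nrow(grid)) + rep(grid$v, nrow(ap)),
    focal = rep(grid$u == 0L & grid$v == 0L, nrow(ap)))
  cells <- cells[i >= 1L & j <= genome$n_bins & i < j]
  cells[, .(focal = any(focal)), by = .(i, j)]
}

#' Simulate a Hi-C contact map
#'
#' Draws Poisson contact counts under the planted model: expected intensity
#' of a bin pair is `s * b_i * b_j * d^exponent * structure(i,j)` where the
#' structure term multiplies the active-domain intensity ratio, a border
#' attenuation per domain border crossed, a site attenuation per insulating
#' COH site crossed (capped), and the anchor-loop enrichment for cells within
#' one bin of a planted anchor pair. The scale `s` is set so the expected
#' total equals `config$depth`.
#'
#' @param genome a [build_genome()] result.
#' @param condition `"wt"` or `"ko"`.
#' @param config the [sim_config()] used to build the genome.
#' @return a [contact_counts()] object; the planted per-bin biases and scale
#'   are attached as `attr(, "truth")`.
#' @export
simulate_contacts <- function(genome, condition = c("wt", "ko"), config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  condition <- match.arg(condition)
  params <- condition_params(config, condition)
  tracks <- genome_bin_tracks(genome)
  n <- genome$n_bins

  with_seed(child_seed(config$seed, 2L, extra = (condition == "ko")), {
    b <- exp(rnorm(n, 0, config$bias_sd))
    b <- b / exp(mean(log(b)))

    if (config$depth <= 0) {
      cc <- contact_counts(data.table(i = integer(), j = integer(),
                                      count = numeric()),
                           genome$bin_size, n)
      attr(cc, "truth") <- list(biases = b, scale = 0, condition = condition,
                                params = params)
      return(cc)
    }

    max_ins_d <- as.integer(config$site_insulation_range / config$bin_size)
    S <- structure_sums_cpp(b, as.integer(tracks$dom_id),
                            as.integer(tracks$dom_active),
                            as.integer(tracks$border_cum),
                            as.integer(tracks$ins_cum),
                            params$decay_exponent, config$active_intensity_ratio,
                            params$border_attenuation, params$site_attenuation,
                            as.integer(config$max_site_crossings), max_ins_d)

    cells <- anchor_cells(genome)
    extra_mass <- 0
    if (nrow(cells)) {
      d <- cells$j - cells$i
      w_base <- structure_weights(tracks, b, cells$i, cells$j, params, config)
      # the loop footprint (3x3 around the anchor pair) is the loop's own
      # contact: the anchors' insulation does not apply there, and the exact
      # anchor-anchor cell peaks above its neighbourhood (m^focal_exp)
      w_clean <- structure_weights(tracks, b, cells$i, cells$j, params, config,
                                   site_attenuation = FALSE)
      m_eff <- ifelse(cells$focal,
                      params$anchor_enrichment^config$anchor_focal_exp,
                      params$anchor_enrichment)
      cells_lambda0 <- d^params$decay_exponent * (w_clean * m_eff - w_base)
      cells_lambda0 <- pmax(cells_lambda0, 0)
      extra_mass <- sum(cells_lambda0)
    }
    total_mass <- sum(S) + extra_mass
    if (total_mass <= 0) stopf("degenerate model: zero expected intensity")
    s <- config$depth / total_mass

    base <- sample_contacts_cpp(b, as.integer(tracks$dom_id),
                                as.integer(tracks$dom_active),
                                as.integer(tracks$border_cum),
                                as.integer(tracks$ins_cum),
                                params$decay_exponent,
                                config$active_intensity_ratio,
                                params$border_attenuation,
                                params$site_attenuation,
                                as.integer(config$max_site_crossings),
                                max_ins_d, s)
    entries <- data.table(i = base$i, j = base$j, count = as.numeric(base$count))
    if (nrow(cells) && extra_mass > 0) {
      extra <- rpois(nrow(cells), s * cells_lambda0)
      keep <- extra > 0
      if (any(keep)) {
        entries <- rbind(entries,
                         data.table(i = cells$i[keep], j = cells$j[keep],
                                    count = as.numeric(extra[keep])))
      }
    }
    cc <- contact_counts(entries, genome$bin_size, n)
    attr(cc, "truth") <- list(biases = b, scale = s, condition = condition,
                              params = params)
    cc
  })
}

#' Simulate a 4C-seq coverage profile
#'
#' Poisson coverage along the viewpoint's row of the planted contact model
#' (decay, domain structure, site insulation and anchor loops included),
#' zeroed inside the viewpoint exclusion zone and scaled to an expected total
#' of `config$fourc_depth`.
#'
#' @inheritParams simulate_contacts
#' @param viewpoint viewpoint position in bp (inside the chromosome).
#' @param exclusion half-width (bp) of the zeroed zone around the viewpoint.
#' @param anchor_enrichment optional override of the condition's anchor-loop
#'   multiplier (for simulated depletion time courses).
#' @return numeric vector of per-bin read counts with attributes `viewpoint`,
#'   `bin_size`, `condition`.
#' @export
simulate_fourc <- function(genome, viewpoint, condition = c("wt", "ko"), config,
                           exclusion = 1e4, anchor_enrichment = NULL) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  condition <- match.arg(condition)
  if (viewpoint < 0 || viewpoint > genome$chromosome_length)
    stopf("viewpoint %g outside chromosome [0, %g]",
          viewpoint, genome$chromosome_length)
  params <- condition_params(config, condition)
  if (!is.null(anchor_enrichment)) params$anchor_enrichment <- anchor_enrichment
  tracks <- genome_bin_tracks(genome)
  n <- genome$n_bins
  v <- pos_to_bin(viewpoint, genome$bin_size)
  v <- min(v, n)

  with_seed(child_seed(config$seed, 4L,
                       extra = floor(viewpoint) + (condition == "ko") * 7L), {
    b <- exp(rnorm(n, 0, config$bias_sd))
    b <- b / exp(mean(log(b)))
    j <- seq_len(n)[-v]
    lo <- pmin(v, j); hi <- pmax(v, j)
    w <- structure_weights(tracks, b, lo, hi, params, config)
    ap <- genome$anchor_pairs
    if (nrow(ap)) {
      # loop footprints around partners of this viewpoint: clean of the
      # anchors' own insulation, multiplied by the loop strength
      w_clean <- structure_weights(tracks, b, lo, hi, params, config,
                                   site_attenuation = FALSE)
      boost <- rep(NA_real_, n)
      m <- params$anchor_enrichment
      mf <- m^config$anchor_focal_exp
      for (r in seq_len(nrow(ap))) {
        if (abs(v - ap$bin1[r]) <= 1L) {
          rng <- pmax(1L, ap$bin2[r] - 1L):pmin(n, ap$bin2[r] + 1L)
          boost[rng] <- pmax(boost[rng], m, na.rm = TRUE)
          if (v == ap$bin1[r]) boost[ap$bin2[r]] <- max(boost[ap$bin2[r]], mf)
        }
        if (abs(v - ap$bin2[r]) <= 1L) {
          rng <- pmax(1L, ap$bin1[r] - 1L):pmin(n, ap$bin1[r] + 1L)
          boost[rng] <- pmax(boost[rng], m, na.rm = TRUE)
          if (v == ap$bin2[r]) boost[ap$bin1[r]] <- max(boost[ap$bin1[r]], mf)
        }
      }
      hit <- !is.na(boost[j])
      w[hit] <- w_clean[hit] * boost[j][hit]
    }
    lambda <- abs(j - v)^params$decay_exponent * w
    cov <- numeric(n)
    excl_bins <- abs((j - 0.5) * genome$bin_size - viewpoint) <= exclusion
    lambda[excl_bins] <- 0
    if (config$fourc_depth > 0 && sum(lambda) > 0) {
      lambda <- lambda * config$fourc_depth / sum(lambda)
      cov[j] <- rpois(length(j), lambda)
    }
    cov[pos_to_bin(viewpoint, genome$bin_size)] <- 0
    structure(cov, viewpoint = viewpoint, bin_size = genome$bin_size,
              condition = condition, exclusion = exclusion)
  })
}

#' Simulate an expression table
#'
#' Log-normal replicate noise around each gene's baseline; knockout
#' replicates are shifted by the gene's planted response (structured
#' interval-shared component plus direct effects). Values are expected
#' counts on the linear scale.
#'
#' @inheritParams simulate_contacts
#' @return object of class `expression_data`: list with matrices `wt`, `ko`
#'   (genes x replicates, linear scale) and the `genes` annotation table.
#' @export
simulate_expression <- function(genome, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  if (!nrow(genome$genes)) stopf("genome has no genes")
  g <- genome$genes
  n <- nrow(g)
  r <- config$n_replicates
  with_seed(child_seed(config$seed, 5L), {
    wt <- 2^(matrix(g$baseline, n, r) + matrix(rnorm(n * r, 0, config$noise_sd), n, r))
    ko <- 2^(matrix(g$baseline + g$planted_response, n, r) +
               matrix(rnorm(n * r, 0, config$noise_sd), n, r))
    colnames(wt) <- paste0("wt_", seq_len(r))
    colnames(ko) <- paste0("ko_", seq_len(r))
    structure(list(wt = wt, ko = ko, genes = g), class = "expression_data")
  })
}

#' @export
print.expression_data <- function(x, ...) {
  cat(sprintf("<expression_data> %d genes x %d+%d replicates\n",
              nrow(x$wt), ncol(x$wt), ncol(x$ko)))
  invisible(x)
}
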
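#' Build a synthetic genome model
#'
#' Draws the annotation layer the contact / 4C / expression simulators share:
#' a partition of the chromosome into active and passive domains, COH
#' (cohesin/CTCF co-occupied) sites with class-specific exponential spacing,
#' loop-free control site classes (`CTCF_only`, `COH_only`, `ENH`), intra-domain
#' anchor pairs (consecutive COH pairs plus each domain's border-most pair),
#' and genes with planted knockout responses.
#'
#' A random subset of COH sites is marked *insulating* (thinned to a uniform
#' genomic rate `insulator_rate` in both domain classes); only these attenuate
#' contacts crossing them. Gene TSSs are placed uniformly within domains, with
#' `active_gene_bias`-fold higher density in active domains. The planted
#' knockout response of a gene is a structured component shared within its
#' inter-COH-site interval (variance split to hit
#' `response_within_interval_corr`) plus, for a `direct_frac` subset chosen
#' preferentially among COH-proximal TSSs, a large direct effect of magnitude
#' `direct_effect`.
#'
#' @param config a [sim_config()].
#' @return an object of class `genome_model`: list with `bin_size`, `n_bins`,
#'   `chromosome_length`, `domains` (data.table: start_bin, end_bin, class),
#'   `sites` (data.table: pos, bin, class, insulating, domain),
#'   `genes` (data.table: tss, bin, strand, baseline, response_structured,
#'   response_direct, planted_response, interval, domain),
#'   `anchor_pairs` (data.table: pos1, pos2, bin1, bin2, domain, kind,
#'   multiplier).
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  n_bins <- as.integer(cfg$chromosome_length / cfg$bin_size)

  with_seed(child_seed(cfg$seed, 1L), {
    ## --- domains: min size + gamma-distributed excess, exact partition ----
    n_dom <- cfg$n_domains
    excess <- cfg$chromosome_length - n_dom * cfg$min_domain_size
    g <- rgamma(n_dom, shape = 2)
    len_bp <- cfg$min_domain_size + excess * g / sum(g)
    len_bins <- round(len_bp / cfg$bin_size)
    len_bins[n_dom] <- n_bins - sum(len_bins[-n_dom])
    if (any(len_bins < 1)) {          # pathological rounding on tiny setups
      len_bins <- pmax(len_bins, 1L)
      len_bins[n_dom] <- n_bins - sum(len_bins[-n_dom])
    }
    end_bin <- cumsum(len_bins)
    start_bin <- c(1L, head(end_bin, -1L) + 1L)
    n_active <- round(n_dom * cfg$active_fraction)
    cls <- rep("passive", n_dom)
    if (n_active > 0) cls[sample.int(n_dom, n_active)] <- "active"
    domains <- data.table(domain = seq_len(n_dom),
                          start_bin = as.integer(start_bin),
                          end_bin = as.integer(end_bin),
                          class = cls)

    ## --- COH sites: exponential spacing per domain class ------------------
    ## Every internal domain border carries an insulating COH site (binding
    ## sites are enriched at domain borders); interior sites follow.
    site_list <- vector("list", n_dom)
    for (k in seq_len(n_dom)) {
      d_start <- (domains$start_bin[k] - 1L) * cfg$bin_size
      d_end <- domains$end_bin[k] * cfg$bin_size
      spacing <- if (cls[k] == "active") cfg$site_spacing_active
                 else cfg$site_spacing_passive
      n_draw <- max(8L, ceiling((d_end - d_start) / spacing * 3))
      gaps <- rexp(n_draw, rate = 1 / spacing)
      pos <- d_start + cumsum(gaps)
      pos <- pos[pos < d_end]
      p_ins <- min(1, cfg$insulator_rate * spacing)
      ins <- runif(length(pos)) < p_ins
      if (k > 1L) {                 # border-resident site
        pos <- c(d_start + 1, pos)
        ins <- c(TRUE, ins)
      }
      if (length(pos)) {
        site_list[[k]] <- data.table(pos = pos, class = "COH",
                                     insulating = ins, domain = k)
      }
    }
    sites <- data.table::rbindlist(site_list)

    ## --- loop-free control classes: uniform placement ---------------------
    for (cl in c("CTCF_only", "COH_only", "ENH")) {
      n_cl <- max(1L, round(cfg$chromosome_length / cfg$other_site_spacing))
      pos <- sort(runif(n_cl, 0, cfg$chromosome_length))
      sites <- rbind(sites, data.table(pos = pos, class = cl,
                                       insulating = FALSE, domain = NA_integer_))
    }
    sites[, bin := pos_to_bin(pos, cfg$bin_size)]
    sites[bin > n_bins, bin := n_bins]
    data.table::setorder(sites, pos)
    # break (vanishingly rare) position ties so positions strictly increase
    while (anyDuplicated(sites$pos)) {
      dup <- duplicated(sites$pos)
      sites[dup, pos := pos + 0.5]
      data.table::setorder(sites, pos)
    }
    sites[is.na(domain), domain := findInterval(bin, domains$start_bin)]

    ## --- anchor pairs: consecutive + border-most COH pairs per domain -----
    coh <- sites[class == "COH"]
    pair_list <- vector("list", n_dom)
    for (k in seq_len(n_dom)) {
      sk <- coh[domain == k]
      if (nrow(sk) < 2) next
      i1 <- seq_len(nrow(sk) - 1L)
      p <- data.table(pos1 = sk$pos[i1], pos2 = sk$pos[i1 + 1L],
                      bin1 = sk$bin[i1], bin2 = sk$bin[i1 + 1L],
                      domain = k, kind = "consecutive")
      if (nrow(sk) >= 3) {
        p <- rbind(p, data.table(pos1 = sk$pos[1L], pos2 = sk$pos[nrow(sk)],
                                 bin1 = sk$bin[1L], bin2 = sk$bin[nrow(sk)],
                                 domain = k, kind = "span"))
      }
      pair_list[[k]] <- p
    }
    anchor_pairs <- data.table::rbindlist(pair_list)
    if (nrow(anchor_pairs)) {
      anchor_pairs <- anchor_pairs[bin2 > bin1]
      anchor_pairs[, multiplier := 1]
    } else {
      anchor_pairs <- data.table(pos1 = numeric(), pos2 = numeric(),
                                 bin1 = integer(), bin2 = integer(),
                                 domain = integer(), kind = character(),
                                 multiplier = numeric())
    }

    ## --- genes: uniform within domains, denser in active ------------------
    n_genes <- max(0L, round(cfg$chromosome_length / 1e6 * cfg$gene_density))
    genes <- data.table(tss = numeric(), bin = integer(), strand = character(),
                        baseline = numeric(), response_structured = numeric(),
                        response_direct = numeric(), planted_response = numeric(),
                        interval = integer(), domain = integer())
    if (n_genes > 0) {
      w_dom <- len_bins * ifelse(cls == "active", cfg$active_gene_bias, 1)
      dom_of_gene <- sample.int(n_dom, n_genes, replace = TRUE,
                                prob = w_dom / sum(w_dom))
      lo <- (domains$start_bin[dom_of_gene] - 1) * cfg$bin_size
      hi <- domains$end_bin[dom_of_gene] * cfg$bin_size
      tss <- sort(runif(n_genes, lo, hi))
      dom_of_gene <- findInterval(pos_to_bin(tss, cfg$bin_size),
                                  domains$start_bin)
      ## inter-COH intervals (0 = before the first site)
      interval <- findInterval(tss, coh$pos)
      rho <- cfg$response_within_interval_corr
      latent <- rnorm(max(interval) + 1L)
      structured <- cfg$response_sd *
        (sqrt(rho) * latent[interval + 1L] + sqrt(1 - rho) * rnorm(n_genes))
      baseline <- rnorm(n_genes, mean = 5, sd = 1.5)
      if (cfg$baseline_trend != 0) {
        structured <- structured -
          cfg$baseline_trend * cfg$response_sd *
            (baseline - mean(baseline)) / sd(baseline)
      }
      ## direct effects, biased towards COH-proximal TSSs
      direct <- numeric(n_genes)
      m <- round(cfg$direct_frac * n_genes)
      if (m > 0 && nrow(coh) > 0) {
        dist_coh <- nearest_distance(tss, coh$pos)
        w <- ifelse(dist_coh <= cfg$proximal_dist, cfg$coh_proximal_weight, 1)
        pick <- sample.int(n_genes, m, prob = w / sum(w))
        direct[pick] <- sample(c(-1, 1), m, replace = TRUE) * cfg$direct_effect
      }
      genes <- data.table(
        tss = tss,
        bin = pos_to_bin(tss, cfg$bin_size),
        strand = sample(c("+", "-"), n_genes, replace = TRUE),
        baseline = baseline,
        response_structured = structured,
        response_direct = direct,
        planted_response = structured + direct,
        interval = interval,
        domain = dom_of_gene)
    }

    structure(list(bin_size = cfg$bin_size,
                   n_bins = n_bins,
                   chromosome_length = cfg$chromosome_length,
                   domains = domains,
                   sites = sites,
                   genes = genes,
                   anchor_pairs = anchor_pairs),
              class = "genome_model")
  })
}

# distance from each query position to the nearest reference position
nearest_distance <- function(query, ref) {
  if (!length(ref)) return(rep(Inf, length(query)))
  ref <- sort(ref)
  idx <- findInterval(query, ref)
  lo <- ifelse(idx >= 1, ref[pmax(idx, 1L)], -Inf)
  hi <- ifelse(idx < length(ref), ref[pmin(idx + 1L, length(ref))], Inf)
  pmin(abs(query - lo), abs(hi - query))
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %.1f Mb, %d bins @ %g Kb, %d domains, %d sites (%d COH), %d genes, %d anchor pairs\n",
              x$chromosome_length / 1e6, x$n_bins, x$bin_size / 1e3,
              nrow(x$domains), nrow(x$sites), sum(x$sites$class == "COH"),
              nrow(x$genes), nrow(x$anchor_pairs)))
  invisible(x)
}

# per-bin helper vectors used by the contact model
genome_bin_tracks <- function(genome) {
  n <- genome$n_bins
  dom_id <- integer(n)
  dom_active <- logical(n)
  for (k in seq_len(nrow(genome$domains))) {
    idx <- genome$domains$start_bin[k]:genome$domains$end_bin[k]
    dom_id[idx] <- k
    dom_active[idx] <- genome$domains$class[k] == "active"
  }
  # border at the first bin of each domain except the first:
  # pair (i, j) crosses border t iff i < t <= j
  border_bins <- genome$domains$start_bin[-1L]
  border_cum <- cumsum(tabulate(border_bins, nbins = n))
  ins_bins <- genome$sites[class == "COH" & insulating == TRUE, bin]
  ins_cum <- cumsum(tabulate(ins_bins, nbins = n))
  list(dom_id = dom_id, dom_active = dom_active,
       border_cum = border_cum, ins_cum = ins_cum)
}
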
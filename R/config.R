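#' Simulation configuration
#'
#' Builds the configuration object driving the synthetic-data generator. The
#' defaults define a 60-Mb chromosome binned at 2 Kb with 60 megabase-scale
#' domains (half transcriptionally active), cohesin/CTCF (COH) sites placed
#' with exponential spacing (denser in active domains), chromatin loops
#' between intra-domain COH anchor pairs, per-bin log-normal technical
#' biases, and a cohesin-knockout condition with lost anchor loops, relaxed
#' domain borders and site insulation, and a sharper distance decay. The
#' planted effect sizes (two-fold active/passive intensity, two-fold anchor
#' enrichment, ~1.6-fold insulation peak-to-trough at the 80-Kb band) match
#' the magnitudes this kind of analysis reports on real data.
#'
#' @param chromosome_length chromosome length in bp.
#' @param bin_size bin width in bp; must divide `chromosome_length`.
#' @param n_domains number of topological domains to draw (mean size
#'   `chromosome_length / n_domains`).
#' @param active_fraction fraction of domains assigned the active class.
#' @param site_spacing_active,site_spacing_passive mean spacing (bp) between
#'   consecutive COH sites in active / passive domains.
#' @param decay_exponent_wt,decay_exponent_ko power-law exponent of the
#'   contact distance decay (negative).
#' @param anchor_enrichment_wt,anchor_enrichment_ko fold multiplier applied to
#'   contacts within one bin of a planted COH anchor pair.
#' @param anchor_focal_exp loops are focal: the exact anchor-anchor cell gets
#'   multiplier `anchor_enrichment^anchor_focal_exp` (> 1 peaks the loop at
#'   its focal point; 1 gives a flat 3x3 boost).
#' @param border_attenuation_wt,border_attenuation_ko fold multiplier in (0,1]
#'   applied once per domain border crossed by a contact.
#' @param site_attenuation_wt,site_attenuation_ko fold multiplier in (0,1]
#'   applied once per insulating COH site crossed (capped, see
#'   `max_site_crossings`); models the contact insulation cohesin/CTCF sites
#'   impose at their position.
#' @param insulator_rate genomic rate (per bp) of insulating COH sites. Kept
#'   uniform across domain classes (sites are marked by thinning), so the
#'   insulation load does not distort the active/passive intensity contrast.
#' @param max_site_crossings cap on the number of insulating-site crossings
#'   that attenuate a contact; keeps long-range decay power-law dominated.
#' @param site_insulation_range maximum contact separation (bp) at which site
#'   insulation acts. Site-level insulation is a local, loop-scale
#'   phenomenon (visible at the 10-80 Kb bands); megabase-scale insulation
#'   comes from domain borders.
#' @param active_intensity_ratio fold multiplier for contacts with both ends
#'   in the same active domain.
#' @param bias_sd standard deviation of per-bin log-normal technical biases.
#' @param depth expected total simulated read pairs.
#' @param fourc_depth expected total reads of a simulated 4C profile.
#' @param gene_density genes per Mb (genome-wide average).
#' @param active_gene_bias gene density ratio, active vs passive domains.
#' @param response_within_interval_corr target Pearson correlation of planted
#'   knockout responses for genes sharing an inter-COH-site interval.
#' @param response_sd standard deviation (log2) of the planted structured
#'   knockout response.
#' @param direct_frac fraction of genes given a large direct knockout effect.
#' @param direct_effect magnitude (|log2 fold change|) of direct effects.
#' @param coh_proximal_weight selection weight multiplier for direct-effect
#'   genes whose TSS lies within `proximal_dist` of a COH site.
#' @param proximal_dist distance (bp) defining COH-proximal TSSs.
#' @param baseline_trend weight of a mean-reverting component coupling the
#'   knockout response to baseline expression (0 disables it; positive values
#'   push highly expressed genes towards downregulation).
#' @param n_replicates expression replicates per condition.
#' @param noise_sd replicate noise sd (log2) of expression measurements.
#' @param min_domain_size minimum planted domain size in bp.
#' @param other_site_spacing mean spacing (bp) of the loop-free site classes
#'   (`CTCF_only`, `COH_only`, `ENH`), placed uniformly.
#' @param seed root seed; all generator outputs derive independent streams
#'   from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(chromosome_length = 6e7,
                       bin_size = 2e3,
                       n_domains = 60,
                       active_fraction = 0.5,
                       site_spacing_active = 6e4,
                       site_spacing_passive = 9e4,
                       decay_exponent_wt = -1.0,
                       decay_exponent_ko = -1.3,
                       anchor_enrichment_wt = 2.0,
                       anchor_enrichment_ko = 1.0,
                       anchor_focal_exp = 1.6,
                       border_attenuation_wt = 0.5,
                       border_attenuation_ko = 0.75,
                       site_attenuation_wt = 0.2,
                       site_attenuation_ko = 0.45,
                       insulator_rate = 1 / 9e4,
                       max_site_crossings = 3,
                       site_insulation_range = 3e5,
                       active_intensity_ratio = 2.0,
                       bias_sd = 0.3,
                       depth = 2e7,
                       fourc_depth = 1e6,
                       gene_density = 10,
                       active_gene_bias = 3,
                       response_within_interval_corr = 0.4,
                       response_sd = 0.8,
                       direct_frac = 0.02,
                       direct_effect = 4,
                       coh_proximal_weight = 4,
                       proximal_dist = 1e4,
                       baseline_trend = 0,
                       n_replicates = 3,
                       noise_sd = 0.2,
                       min_domain_size = 5e5,
                       other_site_spacing = 1.5e5,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (chromosome_length <= 0 || bin_size <= 0)
      stopf("chromosome_length and bin_size must be positive")
    if (chromosome_length %% bin_size != 0)
      stopf("bin_size must divide chromosome_length")
    if (active_fraction < 0 || active_fraction > 1)
      stopf("active_fraction must lie in [0, 1]")
    mult <- c(anchor_enrichment_wt, anchor_enrichment_ko,
              border_attenuation_wt, border_attenuation_ko,
              site_attenuation_wt, site_attenuation_ko,
              active_intensity_ratio)
    if (any(mult <= 0)) stopf("all fold multipliers must be > 0")
    if (any(c(border_attenuation_wt, border_attenuation_ko,
              site_attenuation_wt, site_attenuation_ko) > 1))
      stopf("attenuation multipliers must lie in (0, 1]")
    if (n_domains < 1) stopf("n_domains must be >= 1")
    if (chromosome_length < n_domains * min_domain_size)
      stopf("chromosome too short for %d domains of >= %g bp",
            n_domains, min_domain_size)
    if (depth < 0) stopf("depth must be non-negative")
    if (response_within_interval_corr < 0 || response_within_interval_corr > 1)
      stopf("response_within_interval_corr must lie in [0, 1]")
  })
  invisible(cfg)
}

# Condition-specific generator parameters.
condition_params <- function(cfg, condition) {
  if (!condition %in% c("wt", "ko"))
    stopf("unknown condition '%s' (expected 'wt' or 'ko')", condition)
  if (condition == "wt") {
    list(decay_exponent = cfg$decay_exponent_wt,
         anchor_enrichment = cfg$anchor_enrichment_wt,
         border_attenuation = cfg$border_attenuation_wt,
         site_attenuation = cfg$site_attenuation_wt)
  } else {
    list(decay_exponent = cfg$decay_exponent_ko,
         anchor_enrichment = cfg$anchor_enrichment_ko,
         border_attenuation = cfg$border_attenuation_ko,
         site_attenuation = cfg$site_attenuation_ko)
  }
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %.1f Mb @ %g Kb bins, %d domains (%.0f%% active), depth %.2g, seed %d\n",
              x$chromosome_length / 1e6, x$bin_size / 1e3, x$n_domains,
              100 * x$active_fraction, x$depth, as.integer(x$seed)))
  invisible(x)
}
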
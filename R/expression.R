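#' Knockout-response z-scores and deregulation calls
#'
#' Per gene: condition means, `delta = log2((ko + 1) / (wt + 1))`, a robust
#' z-score `z = (delta - median(delta)) / (1.4826 * MAD(delta))` over
#' expressed genes, and a label: `up` (z > 2), `down` (z < -2), `minimal`
#' otherwise; genes with both condition means below 1 are `excluded`.
#' Standardizing the log fold change with median/MAD makes the `|z| > 2`
#' tails hold their nominal ~4.6% rate under a null response distribution.
#'
#' @param expr_wt,expr_ko matrices or data.frames (genes x replicates,
#'   linear-scale expression; row order defines the shared gene order), or an
#'   `expression_data` object in place of `expr_wt`.
#' @param z_threshold deregulation threshold on |z|.
#' @return object of class `response_table` (a data.table): `gene`,
#'   `mean_wt`, `mean_ko`, `delta`, `z`, `label`.
#' @export
response_zscores <- function(expr_wt, expr_ko = NULL, z_threshold = 2) {
  if (inherits(expr_wt, "expression_data")) {
    expr_ko <- expr_wt$ko
    expr_wt <- expr_wt$wt
  }
  wt <- as.matrix(expr_wt); ko <- as.matrix(expr_ko)
  if (nrow(wt) != nrow(ko)) stopf("gene sets differ between conditions")
  if (ncol(wt) < 1 || ncol(ko) < 1) stopf("need >= 1 replicate per condition")
  mw <- rowMeans(wt); mk <- rowMeans(ko)
  delta <- log2((mk + 1) / (mw + 1))
  expressed <- !(mw < 1 & mk < 1)
  z <- rep(NA_real_, length(delta))
  med <- median(delta[expressed])
  scale <- mad(delta[expressed])  # 1.4826 * MAD by R's default constant
  if (scale <= 0) scale <- 1e-12
  z[expressed] <- (delta[expressed] - med) / scale
  label <- rep("excluded", length(delta))
  label[expressed] <- "minimal"
  label[expressed & z > z_threshold] <- "up"
  label[expressed & z < -z_threshold] <- "down"
  out <- data.table(gene = seq_along(delta), mean_wt = mw, mean_ko = mk,
                    delta = delta, z = z, label = label)
  class(out) <- c("response_table", class(out))
  out
}

#' COH-site proximity enrichment of deregulated genes
#'
#' Genes are categorized by the distance from their TSS to the nearest COH
#' site — at the TSS (< 1 Kb), near (< 10 Kb), away (> 10 Kb) — and the
#' fraction of deregulated genes in each category is compared to the
#' background fraction over all (expressed) genes:
#' `enrichment_pct = 100 * (fraction_deregulated / fraction_all - 1)`.
#'
#' @param response a [response_zscores()] table.
#' @param tss TSS positions (bp), aligned with the response rows.
#' @param sites COH site positions (bp).
#' @param breaks category edges in bp (default 1 Kb / 10 Kb).
#' @return data.table with `category`, `n_deregulated`, `frac_deregulated`,
#'   `n_all`, `frac_all`, `enrichment_pct`.
#' @export
tss_proximity_enrichment <- function(response, tss, sites,
                                     breaks = c(1e3, 1e4)) {
  stopifnot(inherits(response, "response_table"))
  if (length(tss) != nrow(response))
    stopf("tss and response tables differ in length")
  dereg <- response$label %in% c("up", "down")
  if (!any(dereg)) stopf("no deregulated genes")
  keep <- response$label != "excluded"
  d <- nearest_distance(tss, sort(sites))
  cats <- cut(d, c(-Inf, breaks, Inf),
              labels = c(sprintf("<%g Kb", breaks[1] / 1e3),
                         sprintf("<%g Kb", breaks[2] / 1e3),
                         sprintf(">%g Kb", breaks[2] / 1e3)))
  tab_all <- table(cats[keep])
  tab_der <- table(cats[dereg])
  frac_all <- as.numeric(tab_all) / sum(tab_all)
  frac_der <- as.numeric(tab_der) / sum(tab_der)
  data.table(category = names(tab_all),
             n_deregulated = as.integer(tab_der),
             frac_deregulated = frac_der,
             n_all = as.integer(tab_all),
             frac_all = frac_all,
             enrichment_pct = 100 * (frac_der / frac_all - 1))
}

#' Response correlation of gene pairs sharing a cohesin-delimited interval
#'
#' Pairs of genes with TSS separation in `sep_range` are split into
#' *same-interval* pairs (no COH site strictly between the TSSs) and
#' *separated* pairs (at least one site between them). The Pearson
#' correlation of the knockout-response z-scores (left vs right gene by
#' coordinate) is computed per set, with a bootstrap confidence interval for
#' the difference.
#'
#' @param response a [response_zscores()] table.
#' @param tss TSS positions (bp), aligned with the response rows.
#' @param sites COH site positions (bp).
#' @param sep_range TSS separation range in bp (default 100-200 Kb).
#' @param min_pairs error if either set has fewer pairs.
#' @param n_boot bootstrap replicates for the difference CI (0 disables).
#' @param conf confidence level.
#' @param boot_seed seed for the bootstrap resampling.
#' @return object of class `pair_correlation`: list with `r_same`,
#'   `r_separated`, `n_same`, `n_separated`, `diff`, `ci` (of
#'   `r_same - r_separated`).
#' @export
pair_response_correlation <- function(response, tss, sites,
                                      sep_range = c(1e5, 2e5),
                                      min_pairs = 30L, n_boot = 1000L,
                                      conf = 0.95, boot_seed = 1L) {
  stopifnot(inherits(response, "response_table"))
  if (length(tss) != nrow(response))
    stopf("tss and response tables differ in length")
  ok <- is.finite(response$z)
  pos <- tss[ok]
  z <- response$z[ok]
  ord <- order(pos)
  pos <- pos[ord]; z <- z[ord]
  idx_hi <- findInterval(pos + sep_range[2], pos)
  idx_lo <- findInterval(pos + sep_range[1], pos) + 1L
  keep <- idx_hi >= idx_lo
  reps <- pmax(idx_hi - idx_lo + 1L, 0L)
  left <- rep(which(keep), reps[keep])
  right <- unlist(lapply(which(keep), function(q) idx_lo[q]:idx_hi[q]),
                  use.names = FALSE)
  if (!length(left)) stopf("no gene pairs in separation range")
  sites <- sort(sites)
  n_between <- findInterval(pos[right] - 1e-9, sites) -
    findInterval(pos[left] + 1e-9, sites)
  same <- n_between == 0
  n_same <- sum(same); n_sep <- sum(!same)
  if (n_same < min_pairs || n_sep < min_pairs)
    stopf("need >= %d pairs per set (have %d same-interval, %d separated)",
          min_pairs, n_same, n_sep)
  r_same <- cor(z[left[same]], z[right[same]])
  r_sep <- cor(z[left[!same]], z[right[!same]])
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    diffs <- with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        bs1 <- sample.int(n_same, replace = TRUE)
        bs2 <- sample.int(n_sep, replace = TRUE)
        cor(z[left[same]][bs1], z[right[same]][bs1]) -
          cor(z[left[!same]][bs2], z[right[!same]][bs2])
      }, 0)
    })
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(diffs, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  structure(list(r_same = r_same, r_separated = r_sep,
                 n_same = n_same, n_separated = n_sep,
                 diff = r_same - r_sep, ci = ci, conf = conf),
            class = "pair_correlation")
}

#' @export
print.pair_correlation <- function(x, ...) {
  cat(sprintf("<pair_correlation> r(same-interval)=%.3f (n=%d), r(separated)=%.3f (n=%d), diff=%.3f [%.3f, %.3f]\n",
              x$r_same, x$n_same, x$r_separated, x$n_separated,
              x$diff, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Baseline-expression / response trend
#'
#' Spearman correlation between baseline (control) expression level and the
#' knockout log2 fold change. A negative value means highly expressed genes
#' tend to be downregulated (and lowly expressed genes upregulated) after
#' knockout.
#'
#' @param response a [response_zscores()] table.
#' @param min_genes minimum number of expressed genes.
#' @return list with `rho`, `p_value`, `n`, and `sign_convention`.
#' @export
baseline_response_trend <- function(response, min_genes = 100L) {
  stopifnot(inherits(response, "response_table"))
  keep <- response$label != "excluded"
  if (sum(keep) < min_genes) stopf("need >= %d expressed genes", min_genes)
  ct <- suppressWarnings(cor.test(response$mean_wt[keep],
                                  response$delta[keep], method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(keep),
       sign_convention = "negative rho = high baseline expression associates with downregulation")
}
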
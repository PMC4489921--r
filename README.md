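# cohesim

Quantitative analysis of cohesin/CTCF-dependent chromosome domain
architecture from binned chromosomal contact data, 4C-seq profiles and
expression tables — plus a calibrated synthetic-data generator that plants
the structure these analyses measure, so every estimator is validated by
parameter recovery.

## The problem

Interphase chromosomes fold into megabase-scale topological domains.
Cohesin/CTCF co-occupied sites ("COH" sites) anchor chromatin loops inside
domains and insulate contacts across their position; removing cohesin
relaxes this organisation — intra-domain contacts and anchor–anchor loops
are lost, inter-domain contacts gain, the contact-probability decay
steepens, and hundreds of genes deregulate, with correlated responses for
genes sharing a cohesin-delimited interval. `cohesim` implements the
statistics used to quantify all of this from sparse binned contact counts:

* **Normalization.** Distance decay `f(d)` in log-spaced shells;
  per-bin multiplicative technical biases by damped iterative proportional
  fitting (expected marginals via FFT convolution, high-pass detrended so
  domain-scale biology stays in the map); corrected contact enrichment
  `e_ij = log2((c_ij + ψ) / (b_i b_j f(d_ij) + ψ))`.
* **Insulation.** Band insulation tracks `I(x, w)` (mean enrichment of
  contacts crossing `x` within a `w × w` square), site-aligned meta
  profiles with peak-to-trough ratios, insulation-strength quartiles.
* **Domains.** Border calling from the 640-Kb band (count-weighted
  statistic, prominence-filtered minima), active/passive classification by
  deterministic 2-means on intra-domain intensity and TSS density.
* **Pair pooling.** 2-Kb pooled submatrices aligned on site pairs,
  loop-specific folds against per-pair matched controls (same separation,
  domain class and site-crossing count), enrichment-versus-distance curves
  and element-class contact grids.
* **Differential maps.** Knockout-vs-control `δ = e_B − e_A` against a
  shared (control) decay expectation, with distance-controlled group means.
* **4C-seq.** RPM normalization with viewpoint exclusion, 5-Kb sliding
  medians, 2–50-Kb multi-scale domainograms, condition comparisons for
  depletion time courses.
* **Expression.** Robust response z-scores `z = (Δ − median Δ)/(1.4826·MAD)`
  on `Δ = log2((ko+1)/(wt+1))` with up/down calls at |z| > 2, COH-proximity
  enrichment of deregulated genes, and the same-interval gene-pair response
  correlation.

The methods vignette (`vignettes/cohesin-domain-architecture.Rmd`) documents
the planted contact model, every estimator's assumptions and the design
decisions in detail.

## Worked example

```r
library(cohesim)

cfg    <- sim_config(seed = 1)          # 60 Mb, 2-Kb bins, 2e7 read pairs
genome <- build_genome(cfg)
wt     <- simulate_contacts(genome, "wt", cfg)
ko     <- simulate_contacts(genome, "ko", cfg)
en_wt  <- normalize_contacts(wt)
en_ko  <- normalize_contacts(ko)

coh <- sort(genome$sites[genome$sites$class == "COH", ][["pos"]])
peak_to_trough(meta_insulation_profile(en_wt, coh, bands = 8e4)[[1]])
anchor_pair_fold(en_wt, genome$anchor_pairs, coh, genome$domains)$fold
domain_intensity_ratio(en_wt, genome$domains)$ratio

track   <- band_insulation_track(en_wt, 6.4e5, statistic = "ratio")
domains <- classify_domain_activity(en_wt, call_domains(track),
                                    genome$genes$tss)
rt <- response_zscores(simulate_expression(genome, cfg))
```

Output (seed 1):

```
<genome_model> 60.0 Mb, 30000 bins @ 2 Kb, 60 domains, 2082 sites (882 COH), 600 genes, 871 anchor pairs
decay exponents (4-100 Kb fit): wt -1.30, ko -1.52
80-Kb insulation peak-to-trough: wt 1.55, ko 1.28
anchor-pair fold (100-200 Kb, intra-domain): wt 1.93, ko 0.97 (n = 145 pairs)
active/passive intensity ratio (60-180 Kb): 1.87
<domain_set> 60 borders, 61 domains (29 active / 32 passive)
deregulated genes: 20 up, 16 down of 600
```

Reading this: COH sites insulate crossing contacts ~1.5-fold at the 80-Kb
band in the wild type and visibly less after knockout; intra-domain anchor
pairs at 100–200 Kb contact each other about two-fold over matched control
chromatin in the wild type and not at all in the knockout (the planted loop
strengths are 2.0 and 1.0); active domains are about twice as contact-dense
internally as passive ones; the knockout decay is steeper; and the called
borders and classes recover the 60 planted domains.

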
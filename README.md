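# rgcmosaic

Spatial and size-distribution analysis of retinal ganglion cell (RGC)
populations in segmented retinal wholemounts, for researchers studying
glaucoma and other optic neuropathies in rodent models (ocular hypertension,
partial optic nerve transection, optic nerve crush).

The package starts where image segmentation ends: a table of cell centroids
and areas per marker channel, a binary retina mask, and the optic nerve head
(ONH) position. From these it provides

- **CN-ratio estimation** — cross nearest-neighbour matching of nuclear
  (Brn3a) and cytoplasmic (RBPMS) detections, with the contested-target
  exclusion rule, and estimation of the cytoplasmic-to-nuclear area ratio
  (mean per-cell ratio ± SE, plus the OLS regression slope) with Spearman
  correlation and Fisher-z confidence intervals. The CN ratio lets nucleus
  area act as a proxy for soma size.
- **Size distributions** — per-retina density histograms over nucleus-area
  bins (default 25 × 9.52 µm², spanning 0–238 µm²), probability distribution
  functions (PDFs), group means ± SE, difference-PDFs, and per-bin Welch
  comparisons with Bonferroni correction.
- **Spatial stratification** — concentric 0.3 mm eccentricity rings (A–O)
  centred on the ONH, and superior/inferior quadrant sectors, plus the
  size–eccentricity Spearman correlation.
- **Decay kinetics** — per-size-bin density time-courses fitted to the
  one-phase exponential decay with plateau,
  `Y = (Y0 − P)·exp(−k·x) + P`, reporting the half-life `ln(2)/k` of each
  RGC size class.
- **Spatial bootstrap diagnostic** — repeated random placement of 0.5 mm²
  observation windows (≥ 100 cells each, mimicking an AO-cSLO field of
  view), recording mean nearest-neighbour distance (NND), regularity index
  (RI = mean NND / SD NND), mean area, and mean absolute deviation (MAD) of
  area per window, with disease-vs-control separability summarised by
  rank-based ROC curves and AUC.
- **Synthetic retina generator** — hard-core sequential-inhibition mosaics
  on an annular wholemount with eccentricity-dependent log-normal nucleus
  areas, paired cytoplasm channel, and injury models combining
  size-dependent hazards with plateau, transient swelling, pre-death
  shrinkage and superior-biased sectorial loss, so every analysis stage is
  testable without microscopy data.

## Worked example

```r
library(rgcmosaic)

# a naive rat-scale wholemount: 4.5 mm radius, 2,200 RGC/mm^2
m <- generate_healthy(healthy_params(), seed = 1)
overall_density(m)
#> [1] 2200.033

size_eccentricity_correlation(m)$rho   # smaller RGCs sit nearer the ONH
#> [1] 0.268128

cn_ratio_for_mosaic(m)
#> CN ratio (mean of per-cell ratios): 2.430 +/- 0.001 (n = 135275)
#> OLS slope (cytoplasm ~ nucleus):    2.429
#> Spearman rho: 0.9601  [0.9597, 0.9606]
```

The density matches the configured mosaic intensity; the positive Spearman
correlation (~0.26 in naive tissue) reproduces the centripetal concentration
of small RGCs; and the mean cytoplasm/nucleus ratio recovers the rat CN
ratio (2.43) through the full match-then-estimate chain.

An injured cohort and the bootstrap diagnostic:

```r
pre <- mosaic_preset("rat-pont", n_replicates = 2)
ch  <- generate_cohort(pre$healthy, pre$injury, pre$design, seed = 1)
br  <- run_bootstrap(cohort_mosaics(ch, "naive"),
                     cohort_mosaics(ch, "pONT"),
                     bootstrap_config(n_draws = 2000, seed = 1))
br$auc
#>       nnd_um            ri mean_area_um2  mad_area_um2
#>    0.9755940     0.0532555     0.6294495     0.7057935
```

NND separates injured from naive retinas almost perfectly here (severe
transection-like loss); RI *decreases* under injury, so its orientation-free
separability is `br$roc$ri$discrimination = 0.9467`.

The full pipeline (simulate → CN ratio → distributions → stratify → decay →
bootstrap) with a hashed output manifest:

```r
man <- run_pipeline(run_config(preset = "rat-pont", seed = 1),
                    out_dir = "rgc-run")
```

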
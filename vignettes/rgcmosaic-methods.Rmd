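---
title: "Models and methods behind rgcmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rgcmosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcmosaic)
```

`rgcmosaic` treats a segmented retinal wholemount as a marked spatial point
pattern: each retinal ganglion cell (RGC) contributes a position (mm), a
nucleus area (µm²) from the nuclear marker channel (Brn3a) and, when a
cytoplasmic channel (RBPMS) was segmented, a cytoplasm area. This vignette
explains the models the package implements, the parameters that matter, what
the synthetic generator does and does not emulate, and the numerical choices
made where the design was genuinely open.

## Coordinate and unit conventions

Rasters store rows top-down, but retinal anatomy is described with superior
*up*. `read_mosaic()` therefore flips the y axis once at load
(`y = H − y_raster`); every analysis — quadrant sectors, ONH distances,
window placement — uses the flipped frame in which superior is +y.
Positions are carried in mm, areas in µm², densities in cells/mm², times in
days. Cells whose centre falls on a masked-out pixel are rejected with a
warning by default (`mask_policy = "reject"`); segmented artefacts outside
tissue are the main source of such cells, but the policy is a flag because
boundary-pixel quantisation can also put genuine cells one pixel outside.

## The synthetic retina

The generator exists so that every downstream stage has data with the
statistical structure the analyses assume. A healthy mosaic is built in
three steps.

**Positions.** Random sequential adsorption (RSA): candidate points are
drawn uniformly on the annulus between the optic nerve head (ONH) disc and
the retinal rim and accepted only if no accepted point lies within the
inhibition radius. RSA is the simplest generative model that yields the
quasi-regular ("mosaic") arrangement real RGC populations show; it does not
claim to be the developmental mechanism. Defaults: rat wholemount radius
4.5 mm, ONH radius 0.4 mm, 2,200 cells/mm², 9 µm hard core. The parameter
validator requires the hard core to stay below the mean Poisson
nearest-neighbour spacing `0.5/√λ`, which keeps the process at ≲ 36% of the
RSA jamming coverage, so packing always terminates within the default
proposal budget (200 attempts per cell); an exhausted budget raises an error
naming the bound.

**Nucleus areas.** Log-normal with shape `σ = 0.35` and a location tied
linearly to eccentricity: the arithmetic mean area at ONH distance `e` is
`base + slope·e` (defaults 60 + 8·e µm²). The linear-in-location coupling is
the simplest mechanism that produces the observed positive rank correlation
between nucleus area and eccentricity; the slope default was fixed once, by
simulating the area law over the annulus geometry, so that the naive
Spearman correlation lands near the reported naive-retina value of ~0.26.

**The cytoplasm channel.** Each Brn3a cell gets an RBPMS partner at the same
position plus Gaussian jitter (default SD 1 µm, a segmentation-registration
error scale), with `cytoplasm = cn_ratio_true × nucleus × (1 + ε)`,
`ε ~ N(0, 0.10)`. Defaults reproduce the rat CN ratio 2.43 (mouse preset:
2.00). A configurable fraction (default 3%) of RBPMS-only cells emulates the
Brn3a-negative RGC subpopulation (which includes melanopsin RGCs).

**Injury.** Each cell receives one latent uniform draw `u` shared with its
cytoplasmic partner; the cell's death time is where the survival curve

\[ S(t) = P_b + (1 - P_b)\,e^{-k_b m t} \]

crosses `u` (never, if `u < P_b`). `k_b` and the resistant plateau fraction
`P_b` are per-size-bin parameters; `m` is the superior-quadrant hazard
multiplier used to emulate sectorial injuries such as partial optic nerve
transection, where the dorsal cut concentrates primary degeneration in the
superior retina. With `m = 2` the superior quadrant carries `m/(m+1) ≈ 2/3`
of the superior+inferior losses, matching the reported ~67%/33% split.
Survivors selected for swelling (a transient injury response) have areas
multiplied by 1.3 while the observation day lies in the swelling window;
cells within the shrink lead time of their death are observed at 0.7 × their
area (pre-apoptotic atrophy). The swelling and shrinkage magnitudes are
placeholders — no quantitative estimates exist to calibrate them — and they
are deterministic multipliers on sampled subpopulations, not stochastic area
walks.

**What the generator does not emulate:** imaging noise, staining
variability, segmentation error beyond centroid jitter, displaced amacrine
contamination, density gradients with eccentricity, or inter-animal
variability in baseline density. Passing tests therefore demonstrate that
the *estimators* recover the structure the generator encodes; they do not
certify performance on real wholemounts, where biological heterogeneity
(notably inter-individual density variation) broadens every distribution.

**Reproducibility.** A cohort derives one L'Ecuyer-CMRG stream per retina
from the master seed (`parallel::nextRNGStream`), so any animal's data is
identical regardless of how many other animals are generated.

## Matching the two marker channels

Each RBPMS detection claims its nearest Brn3a detection (cross nearest
neighbour, computed by a plane-sweep that matches a brute-force all-pairs
scan exactly). Claims farther than `max_distance_um` (default 15 µm; no
published bound exists, but unbounded matching would pair across the retina)
are discarded first; then any Brn3a cell with two or more surviving
claimants is excluded together with all its claimants. The distance filter
runs first deliberately: an implausibly distant claim — typically from an
RBPMS-only cell with no true partner — should not invalidate a genuine
nearby pair. The headline `exclusion_fraction` counts contested claimants
over RBPMS detections, the quantity reported as "typically < 5%" for this
procedure; distance-discarded claims are tallied separately. On fully paired
channels (the situation of marker-seeded watershed segmentation, where every
cytoplasm detection originates from a nucleus marker) the contested fraction
at ≤ 2 µm jitter is ~0.6%.

The CN ratio is reported two ways, because both conventions are in use: the
mean of per-cell cytoplasm/nucleus ratios with its standard error (the
headline, matching the "2.43 ± 0.03" form) and the OLS slope of cytoplasm on
nucleus area with free intercept. They coincide only when the intercept is
zero; both are emitted, clearly labelled. Spearman correlations carry
Fisher-z confidence intervals with the rank-correlation variance adjustment
`1.06/(n−3)`, clipped to [−1, 1].

## Size distributions

The default binning is 25 bins of 9.52 µm² from 0 — the origin at zero is
not arbitrary: the quoted size-band boundaries 57, 105, 133 and 143 µm² are
the integer roundings of edges 6, 11, 14 and 15 of exactly this scheme.
Cells at or above 238 µm² are tallied as overflow and excluded from PDFs
(the 25-bin design implies truncation; the overflow count is reported so
nothing is silently lost). Histograms are per-bin counts over mask area;
PDFs normalise in-range counts; group means treat the animal as the unit of
replication (mean ± SE across retinas); difference-PDFs subtract mean PDFs
bin-wise with errors in quadrature and sum to zero by construction. The
per-bin group comparison is a Welch t test with Bonferroni threshold
`α/n_bins` — a deliberate, documented stand-in for omnibus two-way ANOVA
machinery, since the bespoke content here is the binning and difference
structure, not the omnibus test.

## Spatial stratification

Eccentricity rings are annuli of 0.3 mm *radial width* centred on the ONH,
labelled A–O; fifteen such rings span 4.5 mm, the rat wholemount radius
(0.3 mm radius increments would cover only 2.25 mm in 15 rings, inconsistent
with wholemount extent). Quadrants are 90° sectors about the ONH centred on
the vertical axis — sectors, not image halves, because all spatial analysis
is ONH-centred; the boundary angle is an assumption, as no published
definition exists.

## Decay kinetics

Per-size-bin density time-courses follow the one-phase exponential decay
with plateau,

\[ Y = (Y_0 - P)\,e^{-kx} + P, \qquad t_{1/2} = \ln 2 / k . \]

(The model is sometimes typeset with the plateau inside the exponent; that
form is dimensionally inconsistent, and the named model is the one above.)
The fit is Levenberg–Marquardt least squares (via `minpack.lm::nls.lm`) on
the reparameterisation `P = f·Y0`, `f ∈ [0,1]`, which turns the constraint
`0 ≤ P ≤ Y0` into a box; three rate initialisations (the log-linear slope of
the excess over the plateau estimate, ×1/3 and ×3) guard against the `k↔P`
ridge, keeping the lowest residual sum of squares. Parameter and function
tolerances are at machine epsilon, so noiseless model data invert to
machine precision. Replicate retinas enter as independent observations,
unweighted — no weighting scheme is documented for this analysis, and
per-retina-then-average fitting is available simply by fitting subsets. A
non-decreasing mean time-course pins `k` at 0 and flags the fit
non-identifiable rather than forcing a decay; all-zero bins are skipped with
an explicit reason.

## The spatial bootstrap

The diagnostic asks: can a single bounded field of view — the limitation of
adaptive-optics ophthalmoscopy — distinguish injured from healthy retina?
Per draw: a retina is sampled with replacement from its group; a square
window of side √0.5 ≈ 0.707 mm (a square is the symmetric choice; no aspect
ratio is specified anywhere) is placed uniformly over the image minus the
window size; placement repeats until the window holds ≥ 100 cells (the
documented filter — it removes background-only placements without biasing
against severely depleted tissue). The mask-coverage fraction of each window
is recorded per draw but not filtered on by default; a configurable
threshold exists (`min_retina_fraction`) for analyses, like the Clark–Evans
comparison below, whose sampling frame requires fully-on-retina windows.

Four statistics per window: mean nearest-neighbour distance (NND, µm),
regularity index (RI = mean NND / sample SD of NND), mean nucleus area, and
mean absolute deviation of nucleus area. NND is computed strictly within the
window with no edge correction — the window *is* the field of view being
emulated, and a clinical instrument has no access to neighbours outside it.
For a homogeneous Poisson pattern RI approaches the Clark–Evans value
`√(π/(4−π)) ≈ 1.913`; within-window truncation biases the observed mean
slightly below it (≈ 1.89 at ~1,100 cells per window), which is why the
acceptance band around the closed form is ±0.05. Regular (inhibited) mosaics
score far higher (≈ 3.7 at the rat preset).

ROC curves score disease draws as positives by the raw statistic value, with
AUC computed by midranks (the tie-corrected Mann–Whitney probability
`P(pos > neg) + ½P(pos = neg)`). Statistics that *decrease* under disease
(RI, typically) give AUC < 0.5 under this fixed orientation; the reflection
`max(AUC, 1−AUC)` is reported alongside as orientation-free discrimination,
making all four statistics comparable. Difference distributions pair draw
`i` of disease with draw `i` of reference (pooling is available by ignoring
the pairing; nothing downstream depends on the choice).

**A note on saturation.** At the rat density a 0.5 mm² window holds ~1,100
cells, so window means are extremely precise; without inter-animal
variability in the generator, even 25% uniform loss separates groups almost
perfectly and AUC estimates collide with 1.0 exactly. Resolving the strict
severity ordering 0% < 25% < 50% therefore needs enough draw pairs to
distinguish `1 − 10⁻⁶` from 1 (the package's ordering check uses 4,000
draws per group, i.e. 1.6 × 10⁷ score pairs). On real data this saturation
does not occur — reported AUCs of 0.56–0.97 reflect the biological
variability the generator deliberately omits.

## Problem sizes and defaults used in the checks

The package's own test suite and `scripts/acceptance.R` run on scaled
cohorts chosen as the smallest sizes at which each property is
statistically decisive: small-retina mosaics of ~10⁴ cells for estimator
recovery, full rat-scale mosaics (~1.4 × 10⁵ cells) where the naive
Spearman and CN-ratio values themselves are the target, 2,000 windows for
the Clark–Evans limit, 10,000 draws per group for AUC null calibration
(matching the `|AUC − 0.5| < 0.03` resolution), 100 simulations for
decay-rate recovery, and 4 well-populated 40 µm² bins for the
half-life-ordering check (the terminal bins of the 25-bin scheme hold too
few cells at small-retina scale for stable per-bin fits). The bootstrap
default of 100,000 draws per group remains the reference design for
full-scale use.

## Known limitations

- The generator's spatial intensity is homogeneous; real RGC density falls
  with eccentricity. Per-ring PDF homogeneity tests exploit this
  deliberately.
- Segmentation pathologies (tile-overlap duplicates, merged somata) are not
  modelled, and no deduplication is attempted at load.
- The Welch-per-bin comparison approximates, but is not, the two-way
  ANOVA + post-hoc machinery used with commercial statistics software.
- `fit_one_phase_decay` assumes monotone-in-mean decay; transient early
  *increases* (swelling) violate the model and show up as inflated residuals
  rather than being modelled explicitly.
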
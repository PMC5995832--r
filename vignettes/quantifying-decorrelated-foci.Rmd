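---
title: "Quantifying the decorrelation signal of hyperreflective foci in Henle's fiber layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the decorrelation signal of hyperreflective foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement

OCT angiography computes, for each voxel, the decorrelation between
repeated B-scans at the same position; flowing blood decorrelates, static
tissue does not. Hyperreflective foci — hard-exudate-like deposits — are
bright on structural OCT, and in Henle's fiber layer (HFL) some of them
carry genuine decorrelation signal. The confound is the *projection
artifact*: the flickering shadow of superficial vessels reproduces their
decorrelation on any bright material beneath them, so a naive average over
foci pixels mixes intrinsic signal with artifact.

The per-eye metric implemented here is the mean decorrelation grayscale
over HFL foci pixels *after* excluding vessel-projected pixels:

1. extract the structural and decorrelation en-face slabs of the HFL
   (91–100 µm above Bruch's membrane, `slab_preset("hfl")`) and the
   superficial decorrelation slab (3 µm below the ILM to 15 µm below the
   IPL/INL boundary, `slab_preset("superficial")`);
2. binarize the structural HFL slab and the superficial angiogram with an
   automatic global threshold (`global_threshold()`, `vessel_mask()`);
3. retain `foci ∧ ¬vessels` (`remove_projection()`) and average the HFL
   decorrelation grayscale over the retained pixels via a 256-bin histogram
   (`decorrelation_intensity()`).

The companion INL slab (38–47 µm below the IPL/INL boundary,
`slab_preset("inl")`) is used for foci-presence grading, and the central
subfield (CSF) thickness is the mean ILM-to-Bruch's distance over the
central 1 mm disc (`compute_csf_thickness()`).

## Geometry conventions

Slabs are defined in signed micrometres relative to named reference
surfaces (ILM, posterior IPL/INL boundary, Bruch's membrane), positive
toward Bruch's membrane: "91 µm above Bruch's membrane" is `bm, -91`.
Device software places thin slabs only approximately, so a rounding
convention must be chosen and frozen; ours is: voxel `k` spans the
half-open depth interval `[(k−1)·s, k·s)` for axial step `s`, and a slab
`[inner, outer)` µm selects every voxel row overlapping that interval
(`floor(inner/s)` through `ceiling(outer/s) − 1`, 0-based). With `s = 3` µm
a flat Bruch's membrane at 300 µm puts the HFL slab `[200, 209)` on rows
66–69 — four rows, guaranteed non-empty whenever `inner < outer`.

The per-A-scan projection statistic defaults to the **mean** for both
channels. Maximum projection, common for display angiography, is available
(`projection = "max"`), but the mean is the default of the quantification
path because the maximum of `k` noisy rows is upward-biased by roughly
`σ·E[max of k standard normals]` (about +0.85 σ at `k = 3`), which would
systematically inflate the intensity metric; the mean is unbiased and
averages axial noise down by `√k`.

The foveal center defaults to the lateral minimum of the inner retinal
thickness (IPL − ILM), the pit; explicit coordinates override it.

## Thresholding

`threshold_histogram()` operates on the 8-bit histogram only, so the
threshold is invariant to duplicating pixels. Grayscale is quantized to
integer levels by `round()` (half-to-even, R's convention); quantization by
rounding rather than truncation keeps slab means unbiased. Two methods:

* **isodata** (default, the classic iterative-intermeans selection):
  iterate `t ← ⌊(μ_below(t) + μ_above(t))/2⌋` from the midpoint of the
  occupied range; the update map is monotone on a finite lattice, so the
  iteration terminates at an exact fixed point.
* **otsu**: exhaustive maximization of between-class variance over all 255
  splits; ties take the lowest threshold.

Pixels *strictly above* the threshold are foreground; ties go to
background. Both choices are frozen and tested. No morphological cleanup is
applied by default; an optional minimum-component-size filter
(4-connectivity) exists for noisy data.

Projection removal is pure mask algebra — conjunction with the complement
of the vessel mask — rather than grayscale subtraction; a subtraction-based
image (`subtract_projection_image()`) is provided for display only, since
subtraction changes retained-pixel values and would bias the metric. An
optional vessel-mask dilation radius (default 0) widens the exclusion zone
where projection tails exceed vessel caliber. Eyes whose retained mask is
empty raise an error and are logged and excluded by the batch runner, never
scored zero.

## The phantom

`generate_phantom()` builds a paired volume with exact ground truth. What
it emulates: a 3 × 3 mm macular field (128×128 A-scans by default,
configurable — the algorithms are resolution-independent); 3 µm axial
sampling; a layered reflectance background with a Gaussian foveal pit in
the ILM; INL foci placed uniformly at random; HFL foci placed along rays
from the foveal center with angular jitter (the radial arrangement of
Henle-layer deposits); per-focus reflectance and intrinsic decorrelation
drawn once per focus; superficial vessels grown as random smooth paths to a
target density, carrying flow-level decorrelation; projection tails running
axially from each vessel pixel down to Bruch's membrane wherever structural
reflectance exceeds a gate (half the mean foci reflectance by default —
projection appears on hyperreflective material only); additive Gaussian
noise clipped to [0, 255].

Foci span their band's full axial extent and layer values are constant
along depth within a band, so the 2-D truth masks describe the en-face
slabs exactly and the noise-free pipeline identity
`intensity == true_intensity` holds to the last bit — the end-to-end test
the suite runs on 20 eyes. Focus discs that cannot be placed inside the
lateral field are resampled up to 200 times, then rejected with an error.

Decorrelation can be written directly (`decorr_mode = "direct"`, the
tested path) or via a simplified amplitude-frame surrogate
(`"frame_pair"`): the target decorrelation is inverted to a frame-amplitude
ratio, two noisy frames are synthesized, and
`d = 1 − A₁A₂ / (½(A₁² + A₂²))` is recomputed and scaled to 8-bit. The
surrogate reproduces the direct volume to within rounding when noise-free
and is intended for qualitative structure only — it does not model
split-spectrum averaging, speckle statistics, bulk motion, or shadowing.

What passing phantom tests do **not** show about real data: real foci have
irregular 3-D shapes crossing slab boundaries, segmentation errors displace
the reference surfaces, projection tails are wider than the vessel raster,
and decorrelation noise is neither Gaussian nor stationary. The phantom
validates the algebra and the estimator, not device physics.

All randomness flows from one integer seed through fixed per-component
sub-streams; identical configuration and seed give bit-identical volumes,
masks, and tables.

## The synthetic cohort

`generate_cohort()` emulates a 102-eye / 66-patient cohort: intensity is
drawn per ellipsoid-zone group (means 72.3 intact / 88.3 disrupted,
within-group SD 22, disrupted fraction 32/102); logMAR VA is
`intercept + b·intensity + c·EZ + ε` with `b = 0.00372` logMAR per
grayscale unit and `c = 0.163` logMAR; CSF thickness (320 ± 99 µm) is
correlated with intensity at 0.408; DR grade (8/47/23/24 per 102), DME
(42/102), SSI (68 ± 5.4) and axial length (23.8 ± 0.9 mm) are independent
covariates. The VA noise SD is not a free parameter: it is solved
analytically from the target intensity–VA correlation (default 0.553)
given the mixture variance of intensity,
`σ_ε² = (Cov(I,VA)/(r·σ_I))² − Var(signal)`; targets implying negative
noise variance are rejected. Calibration is verified by Monte Carlo: over
500 replicate cohorts the mean sample `r` sits within ±0.02 of the target
and the Fisher-z 95 % interval shows nominal coverage. Rater gradings
(`simulate_rater_gradings()`) flip the true foci status with a probability
solved numerically from a target population κ at a given prevalence.

Within-patient correlation between fellow eyes is deliberately *not*
modeled, and the statistics layer ignores eye clustering — the standard
(if imperfect) practice for this analysis family; confidence intervals are
therefore slightly anti-conservative for bilateral cohorts.

## Statistical choices

* **Eligibility**: axial length within [22.0, 26.0] mm (boundaries
  retained), SSI strictly greater than 60, foci present in both INL and
  HFL slabs; every exclusion is logged with its reason, and the filter is
  idempotent.
* **Two-group comparison**: Welch's unequal-variance t-test by default
  (robust to the unequal group sizes and variances typical here);
  Student's pooled test by flag.
* **ANOVA**: one-way, followed by *all* pairwise pooled-SD t-tests with
  p-values multiplied by the number of pairs and capped at 1 (Bonferroni).
  Under the null this controls the family-wise error at or below the
  nominal level, verified by 10,000-replicate simulation.
* **Regression**: forced entry — all predictors retained regardless of
  significance. Standardized β come from OLS on z-scored outcome and
  predictors; binary predictors are z-scored too (one of the common
  conventions; frozen and documented). Near-collinearity (condition number
  above 1e8) is an error rather than a silent drop.
* **κ**: marginal-product expected agreement; degenerate (both raters
  constant) tables are errors.
* **ICC**: two-way random-effects, absolute-agreement, single measures —
  ICC(2,1), the standard choice for method comparison of continuous
  measurements — with the F-based confidence interval.

## Problem sizes and numerical tolerances

The shipped test suite runs phantoms at 64–128 px lateral resolution, 20
noise-free eyes for the exact-identity check, 200 noisy replicates for
estimator recovery (assertion: within `3·SD/√n` of the generating mean in
≥99 % of replicates), 500 cohorts for correlation calibration, and 10,000
null replicates for family-wise error — a few minutes in total. Statistic
implementations are checked against independent from-scratch oracles
(exhaustive threshold search, contingency arithmetic, ANOVA sums of
squares, normal equations) at 1e-10 relative error. Exact identities
(noise-free recovery, histogram-mean equality, mask round-trips) are
asserted bit-for-bit, which the integer-valued noise-free phantom makes
possible.

## Known limitations

* Surfaces are inputs; no layer segmentation is performed, and segmentation
  error propagates directly into slab placement.
* The metric operates on the 8-bit en-face export scale, not the device's
  native decorrelation scale.
* Per-focus classification (which individual foci are
  reflectance-decorrelated) is out of scope; only the pooled per-eye mean
  is computed.
* The frame-pair surrogate is qualitative; quantitative claims should use
  direct mode or real device output.
* Three-dimensional foci analysis is not attempted; the procedure is
  inherently en-face.
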
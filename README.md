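# octafoci

Quantification of the **decorrelation signal intensity of hyperreflective
foci** in Henle's fiber layer (HFL) from paired structural OCT /
OCT-angiography (OCTA) volumes, with the cohort-level statistics used to
relate that metric to visual function in diabetic retinopathy, and a
synthetic phantom/cohort generator with exact ground truth for end-to-end
validation.

## The problem and who this is for

Hyperreflective foci — confluent, highly reflective deposits corresponding
to hard exudates — accumulate in the inner nuclear layer (INL) and in
Henle's fiber layer in diabetic retinopathy. On OCTA, some HFL foci carry
genuine decorrelation (flow-like) signal, but deep slabs are contaminated by
*projection artifacts*: flow signal from superficial vessels duplicated onto
any hyperreflective material beneath them. Separating intrinsic foci
decorrelation from projected artifact is the core measurement problem this
package addresses, for researchers quantifying en-face OCTA slabs.

The per-eye statistic is computed in three steps on micrometre-defined
en-face slabs:

1. **Foci segmentation.** The structural HFL slab (91–100 µm above Bruch's
   membrane) is binarized with an automatic global threshold (IsoData — the
   Ridler–Calvard fixed point `t = ⌊(μ₀(t) + μ₁(t))/2⌋` on the 8-bit
   histogram — or Otsu's between-class-variance maximum).
2. **Projection removal.** The superficial angiogram (ILM+3 µm → IPL+15 µm)
   is binarized the same way; retained foci pixels are the set difference
   `foci ∧ ¬vessels`.
3. **Intensity.** The HFL decorrelation grayscale is read at every retained
   pixel, accumulated into a 256-bin histogram, and averaged:
   `I = Σ g·h(g) / Σ h(g)` — the decorrelation signal intensity.

The statistics layer reproduces the standard cohort analyses on the per-eye
table: Pearson correlations (intensity vs logMAR VA and vs central subfield
thickness), one-way ANOVA across DR severity grades with all-pairs
Bonferroni correction, Welch comparison by ellipsoid-zone (EZ) status,
forced-entry multiple regression with standardized β, Cohen's κ for
presence/absence grading, and ICC(2,1) for manual-vs-automatic area
agreement.

Because patient OCTA volumes are rarely shareable, the package ships a
seeded phantom generator (layered retina, foveal pit, radially arrayed HFL
foci, superficial vessels with projection tails, additive noise) whose
ground truth — foci/vessel/projection masks and the exact retained-foci
intensity — makes every pipeline stage testable, plus a calibrated 102-eye
cohort generator with controllable effect structure.

## Worked example

```r
library(octafoci)

ph <- generate_phantom(phantom_config(seed = 7))   # 128x128x120 voxel pair
q  <- quantify_eye(ph$volume, ph$surfaces)
q$foci
#> binary_mask (isodata, t=122): 128 x 128 px, 435 foreground
q$vessels
#> binary_mask (isodata, t=101): 128 x 128 px, 2011 foreground
q$result
#> decorrelation signal intensity: 121.25 over 361 foci pixels
ph$truth$true_intensity
#> [1] 121.25
```

The structural HFL slab thresholds at grayscale 122, yielding 435 foci
pixels; 74 of them fall under superficial vessels and are excluded; the mean
decorrelation grayscale over the 361 retained pixels, 121.25, matches the
generator's ground truth (the phantom's intrinsic foci decorrelation is
drawn around 120).

```r
co <- generate_cohort(cohort_config(seed = 7))
run_stats(co)
#> Cohort statistics report
#>   eyes/patients: 102/66
#>   intensity: 76.9 ± 21.6; logMAR VA: 0.071 ± 0.192; CSF: 332 ± 91 um
#>   intensity vs logMAR VA:    R = 0.544, P < 0.001 (n = 102)
#>   intensity vs CSF:          R = 0.297, P = 0.002 (n = 102)
#>   intensity vs VA (DME):     R = 0.534, P < 0.001 (n = 45)
#>   intensity vs VA (no DME):  R = 0.548, P < 0.001 (n = 57)
#>   EZ disrupted vs intact: 85.2 ± 19.8 vs. 73.1 ± 21.5; P = 0.007
#>   DR grade ANOVA: F = 1.76, P = 0.159 (6 pairwise, Bonferroni)
#>   forced-entry regression (outcome logMAR VA):
#>     intensity      beta =  0.402, P < 0.001
#>     ez_disrupted   beta =  0.437, P < 0.001
#>     csf_thickness  beta =  0.097, P = 0.203
```

Higher foci decorrelation tracks worse acuity and thicker maculas, the
EZ-disrupted group carries higher intensity, and in the joint model
intensity and EZ status — but not CSF thickness — independently predict
logMAR VA.

A command-line front end over the same functions is installed at
`inst/cli/octafoci` (`simulate`, `quantify`, `stats`, `all` subcommands).

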
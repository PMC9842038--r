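---
title: "Quantifying calcification morphology and protein localization in valve micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying calcification morphology and protein localization in valve micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CalciMorph)
```

## The measurement problem

Aortic valve stenosis presents differently by sex: male valve tissue tends to
calcify in large mineral nodules, female tissue in many small micropunctae,
even when the *total* amount of mineral is similar. Total-staining measures
(integrated density of a thresholded Von Kossa image) therefore miss the
dimorphism; what differs is the *size distribution* of the deposits. A second
sex-linked observable is where the matricellular protein osteopontin (OPN)
sits: diffusely in the extracellular matrix, or concentrated in perinuclear
regions of valvular interstitial cells.

CalciMorph implements the three measurements this kind of study needs, each
behind a small S4 container type, plus a synthetic image generator with exact
ground truth so that every stage can be verified without any raw micrographs:

1. **Von Kossa quantification** — RGB histology is converted to 8-bit
   grayscale, binarized dark-side at one condition-uniform threshold, and
   summarized as integrated density (255 per foreground pixel), area
   fraction, and normalized density.
2. **Correlation length** — the radially averaged autocorrelation of the
   binary mask, integrated to its first zero crossing, yields a feature-size
   length scale in micrometers.
3. **Cell:ECM localization ratio** — nuclei segmented from a DAPI median
   z-projection are dilated into a "cellular" pixel set; the ratio of mean
   signal intensity over cellular pixels to the mean over all remaining
   "ECM" pixels summarizes perinuclear versus diffuse localization.

## The correlation-length statistic

A binary mask $m$ is mapped to $s = 2m - 1 \in \{-1, +1\}$, so a pixel pair
of equal value contributes $+1$ and an opposite pair $-1$. For a lag vector
$\Delta$,

$$ g(\Delta) \;=\; \frac{\langle s(x)\, s(x+\Delta) \rangle_{\text{valid}}
   - \bar s^2}{\operatorname{Var}(s)}, $$

where the average runs over valid (non-wrapped) pixel pairs only and
$\operatorname{Var}(s) = 1 - \bar s^2$. Three numerical choices matter:

* **Mean subtraction and variance normalization.** The raw $\pm 1$ pair
  average has a nonzero large-lag baseline of $(2p-1)^2$ at coverage $p$;
  subtracting $\bar s^2$ and dividing by the variance pins $g(0) = 1$ and
  makes $g$ decay to zero, so that its radial integral is a length. The raw
  profile remains exportable (`acf2d(..., normalize = FALSE)`) for
  comparison with conventions that skip mean subtraction.
* **Aperiodic boundaries.** Correlation is computed with zero padding and a
  per-lag valid-pair count correction rather than periodic wrap-around,
  because tissue sections are not periodic. This also removes border bias to
  first order: translating a feature changes the statistic by well under 1%.
* **Spectral computation with a brute-force oracle.** `acf2d()` evaluates
  the definition via FFT (Wiener–Khinchin with zero padding);
  `acf2dBruteforce()` is a direct pair-enumeration implementation of the
  identical definition, kept as an independent oracle. The suite requires
  agreement to $10^{-8}$ on random masks.

The lag field is averaged into 1-px annuli by Euclidean lag length (bin $b$
collects lengths in $[b - 0.5, b + 0.5)$; the lag $(3,4)$ lands in bin 5),
weighting by valid-pair counts. The correlation length is the trapezoidal
integral of $g(r)$ from zero to its first non-positive value, linearly
interpolating the crossing:

* integrating the noisy negative tail would make the result depend on the
  maximum lag, while the first crossing operationalizes the distance at
  which features stop being segregated from their surroundings;
* if $g$ never crosses zero within the profile the integral runs to the
  maximum lag and the result is flagged (`crossedZero = FALSE`) as a lower
  bound;
* the default maximum lag is a quarter of the smaller image dimension;
* masks with fewer than 10 foreground pixels are processed but flagged
  `lowSupport`;
* for pure noise (independent pixels), $g$ drops from 1 to about 0 at lag 1
  and the interpolated integral is 0.5 px — the "pure nugget" floor every
  report should be read against.

For a single disk of radius $R$ the statistic is proportional to $R$
(the suite checks strict monotonicity and a linear fit with $R^2 > 0.98$
over $R \in \{3, 6, 12, 24\}$ px), which is exactly the property that makes
it a feature-size measure.

## Von Kossa quantification choices

* **Grayscale conversion** uses the unweighted channel mean
  $(R + G + B)/3$, rounded half-up — the historical default of the common
  histology measurement software — with an optional ITU-R luminance switch.
  The rounding rule is stated because it changes counts near the threshold.
* **Polarity.** Mineral deposits are dark on a light counterstain, so
  foreground is `intensity <= threshold`; a polarity flag exists for
  fluorescence-derived masks.
* **The uniform threshold.** A study applies *one* threshold across all
  conditions. Because a manually chosen value is not reproducible, the
  default policy is Otsu's method on the pooled 256-bin histogram of all
  images (`autoThreshold()`), with a config override for a fixed integer;
  the value used is always recorded in the output. Ties in the
  between-class variance are broken at the midpoint of the maximizing set.
* **Normalized density.** The normalizer behind "normalized integrated
  density" is ambiguous in practice (tissue area vs. image area); here it
  is defined as integrated density divided by an explicit ROI pixel count,
  defaulting to the full image, and the ROI count is carried in the result.

## Localization choices

* **Median projection first.** Each channel is median-projected across z
  before segmentation or intensity measurement; even slice counts take the
  mean of the two central order statistics.
* **Segmentation recipe.** Otsu threshold on DAPI, hole filling, removal of
  components under 50 px (configurable), 8-connected labelling with labels
  ordered row-major by centroid. No watershed splitting of touching nuclei:
  the ratio only needs the union mask, not per-nucleus identity. Nuclei
  touching the border are retained — excluding them would bias the cellular
  fraction. A blank image yields 0 nuclei with a warning, not an error.
* **Dilation radius.** The "cellular" set is the nuclei dilated by an exact
  Euclidean disk, default radius 5 px (about 1.8 um at 2.73 px/um),
  always recorded in the output.
* **Degenerate partitions.** An empty or all-cellular mask errors; a zero
  ECM mean reports an `Inf` sentinel with a warning rather than dropping
  the image silently.

## What the synthetic generator emulates

`genPunctaField()` draws a Boolean (germ–grain) disk model: Poisson germ
count at intensity $\lambda$ per $\mu m^2$, uniform centers, lognormal radii
parameterized by the mean and sd of the radius itself, dark disks on a light
background, additive Gaussian noise. Coverage follows the closed form
$1 - \exp(-\lambda \pi E[R^2])$; germs are sampled in a border-padded window
so the field is stationary on the image and the closed form applies without
edge bias. The presets encode the study design: `female_CM`
(1.5 ± 0.5 um radii) and `male_CM` (6 ± 2 um) share one nominal area
fraction (8%) so that *only* feature size separates the groups — the
dissociation the correlation length is meant to detect — and `OM_control`
has $\lambda = 0$ (no staining).

`genIFScene()` renders two-channel z-stacks: non-overlapping elliptical
nuclei (semi-axes 5 × 3.5 um, random orientation, placed by rejection
sampling) blurred into a DAPI channel, and a signal channel with a diffuse
ECM level, an additive perinuclear halo, and an independent level inside
nuclei. The halo width default (1.5 um, 4 px at 2.73 px/um) keeps the halo
strictly inside the 5-px cellular dilation, so the measured ratio reflects
the scene rather than single-pixel segmentation jitter; the halo and ECM
levels of the `perinuclear_OPN` preset (205 over 25) are chosen to keep the
brightest pixels below the 8-bit clip while giving a cell:ECM ratio near 4.
`diffuse_OPN` (ECM 120, no halo, nuclear exclusion) gives a ratio near 0.5.
The ground truth carries the exact label mask and the analytic cell/ECM
means of the noiseless signal, so recovery can be asserted to $10^{-10}$
when the true mask is injected and to 15% for the full segmentation-driven
pipeline at a signal-to-noise ratio of 10 (noise sd = DAPI level / 10).

What the generator does **not** emulate: textured tissue background,
stain-specific color (scenes are born grayscale), uneven illumination,
spectral bleed-through, z-dependent attenuation, or clustered/overlapping
nuclei. Passing tests therefore demonstrate correctness of the
*computations* under controlled conditions, not robustness to every
real-micrograph artifact.

## Statistics

Group comparisons mirror standard practice in imaging studies: Welch's
unpaired $t$ (the default for all two-group contrasts — equality of
variances is rarely defensible for imaging measures), ordinary one-way
ANOVA with Dunnett many-to-one or Tukey HSD post hoc, and balanced two-way
ANOVA with post hoc on cell means. Dunnett adjustment is computed from the
multivariate-$t$ distribution of the simultaneous statistics
(`mvtnorm::pmvt` under a fixed, recorded integration seed) and is verified
in the suite against a $10^6$-draw Monte-Carlo max-$|t|$ null to within
0.005. Unbalanced two-way designs are rejected loudly rather than silently
re-weighted. Each image is treated as the experimental unit by default;
averaging to biological replicates first is a config choice the report
echoes.

## Orchestration and reproducibility

`runStudy()` takes one structured configuration (R list or YAML): groups
(synthetic presets or file globs), stages, threshold policy, dilation,
maximum lag, seed. It pools the Otsu threshold over *all* grayscale images
so one value is uniformly applied across conditions, computes per-image
measures, and runs the configured comparisons. Every derived per-image seed
is recorded; rerunning the same configuration is byte-identical, and
`writeStudyReport()` emits `per_image.csv`, `group_summaries.csv`,
`comparisons.csv` and `report.json` whose bytes reproduce exactly.

## Worked example

```{r example, eval = FALSE}
cfg <- list(
  seed = 1, stages = c("vk", "corrlength"),
  groups = list(
    list(label = "female_CM", preset = "female_CM", n_images = 7,
         condition = "CM", sex = "F"),
    list(label = "male_CM", preset = "male_CM", n_images = 7,
         condition = "CM", sex = "M")),
  comparisons = list(
    list(measure = "correlation_length_um", test = "welch",
         groups = c("male_CM", "female_CM")),
    list(measure = "integrated_density", test = "welch",
         groups = c("male_CM", "female_CM"))))
study <- runStudy(cfg)
study@groupSummaries
study@comparisons
```

Under these conditions the correlation-length contrast is significant in
every seed replicate while the integrated-density contrast is not — the
equal-coverage presets differ only in feature size, and only the
correlation length sees it.

## Problem sizes and limitations

The packaged experiments use 256 × 256 px fields (about 94 × 94 um at
2.73 px/um), 7 images per group and 10 seed replicates, and 512 × 512
fields for the noise floor; these sizes give stable Monte-Carlo behaviour
(coverage within three standard errors of the closed form, Welch type-I
error within [0.03, 0.07] over 2000 null draws) while keeping a full run in
the order of a minute. Known limitations: no color deconvolution (the
pipeline thresholds grayscale, not stain-separated channels), no
anisotropic or 3D autocorrelation, no per-cell quantification or
colocalization coefficients, and no proprietary microscope formats — TIFF
and PNG only, with calibration always an explicit input.
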
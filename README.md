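# CalciMorph

Image-analysis pipeline for sex-specific valve calcification studies.

Male and female aortic valves calcify differently: male tissue tends toward
large mineral nodules, female tissue toward many small micropunctae — often
with *similar total mineral*. Measures of total staining (integrated density
of thresholded Von Kossa histology) are therefore blind to the dimorphism;
the discriminating quantity is a *feature-size* statistic. CalciMorph
implements that statistic and the two companion measurements such a study
needs, for researchers quantifying mineralization and osteopontin (OPN)
localization in histology and immunofluorescence micrographs:

* **Von Kossa quantification** (`rgbToGray8`, `autoThreshold`,
  `binarizeDark`, `vkMeasure`) — 8-bit grayscale conversion, one
  condition-uniform threshold (pooled Otsu by default, always recorded),
  dark-side binarization, integrated density / area fraction / normalized
  density.
* **Correlation length** (`acf2d`, `radialAverage`, `correlationLength`,
  `maskCorrelationLength`) — the binary mask is mapped to s = 2m − 1 and its
  variance-normalized autocorrelation
  g(Δ) = (⟨s(x)s(x+Δ)⟩_valid − s̄²) / Var(s)
  is computed aperiodically (zero padding, per-lag valid-pair correction),
  radially averaged into 1-px annuli, and integrated by the trapezoid rule
  to its first zero crossing. The result L (reported in px and µm via the
  pixels-per-micrometer calibration, e.g. 2.73 px/µm) grows linearly with
  feature radius: large nodules correlate over long distances, micropunctae
  do not. A brute-force pair-enumeration implementation
  (`acf2dBruteforce`) is kept as an independent oracle.
* **Cell:ECM localization ratio** (`medianProjection`, `segmentNuclei`,
  `dilateNuclei`, `cellEcmRatio`, `localizeStack`) — DAPI median
  z-projection, Otsu segmentation, perinuclear dilation (5 px default),
  then mean signal over "cellular" pixels divided by mean over the
  remaining "ECM" pixels; distinguishes perinuclear from diffuse OPN.
* **Synthetic micrographs with ground truth** (`genPunctaField`,
  `genIFScene`, `presetSpec`) — a Boolean disk model (coverage follows
  1 − exp(−λπE[R²])) and nucleus/halo scenes, fully seeded; presets
  `female_CM` / `male_CM` share one area fraction and differ only in
  feature size, `perinuclear_OPN` / `diffuse_OPN` bracket the localization
  ratios.
* **Statistics and orchestration** (`welchT`, `oneWayAnova`, `twoWayAnova`,
  `runStudy`, `writeStudyReport`) — Welch t, ANOVA with Dunnett
  (multivariate-t adjustment) or Tukey post hoc, and a config-driven study
  runner whose outputs rerun byte-identically.

See the vignette (`vignettes/quantifying-calcification-morphology.Rmd`) for
the model details and design rationale.

## Worked example

Quantify one synthetic large-nodule field, one noisy fluorescence scene,
then run the two-group study:

```r
library(CalciMorph)

gen <- genPunctaField(presetSpec("male_CM", seed = 1))
thr <- autoThreshold(gen$image)          # pooled Otsu -> 127
mask <- binarizeDark(gen$image, thr)
vkMeasure(mask, thresholdUsed = thr, sourceId = sourceId(gen$image))
#> VKResult 'puncta-seed1': 2506 foreground px, integrated density 639030,
#>   area fraction 0.0382, normalized density 9.7508 (threshold 127)

maskCorrelationLength(mask)
#> CorrLengthResult: L = 5.956 um (16.259 px), integrated to lag 91.00 px
#>   [no zero crossing: lower bound]

sc <- genIFScene(presetSpec("perinuclear_OPN", seed = 1, noiseSd = 18))
localizeStack(sc$stack)
#> LocalizationResult 'ifscene-seed1': cell:ECM ratio 4.273
#>   (cell 107.24 / ECM 25.10)
#>   12 nuclei, cellular fraction 0.142, dilation 5 px
```

The single-image L of 5.96 µm is a *lower bound* (the profile never crossed
zero within the lag window — sparse nodule fields decay slowly), and the
recovered ratio 4.27 sits within 6% of the scene's analytic truth of 4.07.
The study runner aggregates 7 images per condition:

```r
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
study@groupSummaries[study@groupSummaries$measure ==
                       "correlation_length_um", ]
#>      group               measure     mean       sd n
#>  female_CM correlation_length_um 1.965967 0.718831 7
#>    male_CM correlation_length_um 6.021363 1.334877 7
study@comparisons
#> GroupComparisonResult [welch_t]: groups male_CM (n=7), female_CM (n=7)
#>   t=7.077 (p=5.171e-05)
#> GroupComparisonResult [welch_t]: groups male_CM (n=7), female_CM (n=7)
#>   t=0.2205 (p=0.8321)
```

Read: the two conditions are statistically indistinguishable in total
staining (p = 0.83) yet separate decisively in correlation length
(p = 5 × 10⁻⁵, male ≈ 3.1× female) — the dissociation between "how much
mineral" and "how large the deposits are" that motivates the feature-size
statistic.

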
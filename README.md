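# icdQuant

Quantification of immunogenic cell death (ICD) biosensor assays: a
Bioconductor-style R package for high-content screens that read the ICD
hallmarks from fluorescence microscopy, cytometry event tables and
stained tissue sections — with a seeded synthetic-data generator that
provides ground truth for validating every stage.

## Who this is for

Screening and imaging groups that quantify ICD biosensor cell lines:

* **CALR-GFP** — cytoplasmic calreticulin aggregation ("eat-me" signal),
* **quinacrine** — ATP-rich vesicles whose depletion reports ATP release,
* **HMGB1-GFP** — loss of nuclear fluorescence reports HMGB1 exodus,
* **MX1-GFP** — whole-cell reporter of type-1 interferon signalling,
* **surface CALR by cytometry** — positivity among viable, PI-excluding
  cells,
* **tissue sections** — hematoxylin/eosin de-coloration of necrosis,
  infiltrating leukocyte counts, percent marker-positive cells.

## The measurements at the core

**Granularity score.** For a cytoplasmic ROI *R* with mean intensity
*Ī<sub>R</sub>*, tile the ROI bounding box with non-overlapping *b* × *b*
pixel blocks (default 4 px, ≥ 50 % ROI coverage per block) and let
*m<sub>1</sub> … m<sub>k</sub>* be the block means over ROI pixels. Then

&nbsp;&nbsp;&nbsp;&nbsp;*G* = sd(*m<sub>1</sub> … m<sub>k</sub>*) / *Ī<sub>R</sub>*,

the standard deviation of means of adjacent pixel groups relative to the
ROI mean: 0 for diffuse signal, exactly scale-invariant, rising as
fluorescence concentrates into puncta. CALR aggregation scores **up**,
quinacrine vesicle depletion scores **down**; nuclear HMGB1 is read as
the nuclear mean (**down** on release) and MX1 as the whole-cell mean
(**up** on induction).

**Control-Gaussian thresholds.** Per-assay decision thresholds come from
Gaussian fits *N(μ₋, σ₋)*, *N(μ₊, σ₊)* to negative/positive control
values, thresholded at the equal-likelihood intersection (midpoint for
equal SDs), falling back to *μ₋ ± kσ₋* (k = 3) without a positive
control. Wells are summarized as the fraction of viable (PI-low) cells
positive, and conditions are compared with two-tailed Welch-corrected
t-tests (Satterthwaite df) against untreated wells, starred \*, \*\*,
\*\*\* at p < 0.05, 0.01, 0.001.

**Tissue.** Beer–Lambert colour deconvolution (OD = −log₁₀((I+1)/256)
projected on the standard H&E stain basis) yields hematoxylin/eosin
density maps, from which the package computes the eosin/hematoxylin
ratio map, the low-hematoxylin (necrotic) area fraction and size-banded
counts of hematoxylin-dense leukocyte puncta.

## Worked example

Simulate a small CALR-GFP plate (2 negative, 2 positive control wells,
2 doses × 2 wells; 3 view fields × 30 cells per well), run the full
pipeline, and inspect the calibration and well summaries:

```r
library(icdQuant)

lay <- defaultPlateLayout()[c(1, 2, 4, 5, 13, 14, 19, 20), ]
res <- runPlateAnalysis(runConfig(assay = "CALR_GFP", layout = lay,
                                  nCells = 30, fieldsPerWell = 3,
                                  calibration = list(minLive = 30),
                                  seed = 7))
res$model
#> ThresholdModel [CALR_GFP]
#>   method: intersection  direction: above is positive
#>   neg: N(0.01485, 0.00604)  pos: N(0.7379, 0.1903)
#>   threshold: 0.04204064

res$wells[, c("well", "role", "dose", "n_live", "fraction_positive")]
#>   well    role dose n_live fraction_positive
#> 1  A01     neg    0     80             0.000
#> 2  A02     neg    0     80             0.000
#> 3  A04     pos    0     81             1.000
#> 4  A05     pos    0     84             1.000
#> 5  C01 treated   50     77             0.182
#> 6  C02 treated   50     82             0.207
#> 7  D01 treated  200     73             0.767
#> 8  D02 treated  200     83             0.759

res$stats
#>          treatment dose n_wells  mean      sd     t df       p stars
#> 1             drug   50       2 0.195 0.01803  15.3  1 0.04166     *
#> 2             drug  200       2 0.763 0.00572 188.7  1 0.00337    **
#> 3 positive_control    0       2 1.000 0.00000   Inf  2 0.00000   ***
```

Reading the output: the untreated wells' granularity distribution
(mean 0.015) and the fully-granular positive controls (mean 0.74) place
the decision threshold at 0.042; at dose 50 about 20 % of viable cells
score granular, rising to ~76 % at dose 200, each significantly above
untreated controls by Welch's test. The per-cell table, thresholds,
well summaries, statistics and a run manifest are written as
CSV/JSON when `outDir` is set — byte-identical across reruns with the
same seed.

Lower-level building blocks are exported individually
(`generateField()`, `segmentNuclei()`, `filterDebris()`,
`buildCytoplasmROIs()`, `granularityScore()`, `fitThreshold()`,
`welchTTest()`, `gateLive()`, `markerPositiveFraction()`,
`deconvolveHE()`, `lowHematoxylinAreaFraction()`, `countLeukocytes()`,
`percentPositiveCells()`, …); see the methods vignette
(`vignettes/icd-quantification.Rmd`) for the model, parameter
conventions and the generator's study conditions. A thin command-line
wrapper lives at `inst/scripts/icd_profiler.R`
(`simulate | segment | gate | histo | run`).

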
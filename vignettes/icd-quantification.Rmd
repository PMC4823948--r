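---
title: "Quantifying immunogenic cell death biosensors with icdQuant"
author: "icdQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immunogenic cell death biosensors with icdQuant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measurement problem

Immunogenic cell death (ICD) is operationally defined by a small set of
hallmarks: calreticulin (CALR) translocation ("eat-me" signal), ATP
secretion with depletion of quinacrine-stained cytoplasmic vesicles,
exodus of nuclear HMGB1, and a type-1 interferon response read through a
GFP reporter under the MX1 promoter. High-content screens read these
hallmarks from fluorescence microscopy of biosensor cell lines: nuclei
are counterstained (Hoechst), a primary region of interest (ROI) is drawn
around each nucleus, debris is excluded, and a secondary cytoplasmic ROI
around each nucleus carries the biosensor readout. Surface CALR is
additionally read by cytometry restricted to viable, PI-excluding cells,
and in-vivo effects are quantified on stained tissue sections.

icdQuant reimplements this measurement chain as a tested, reusable R
package: segmentation, per-cell features, control-calibrated thresholds,
well summaries, group statistics, cytometry gating and tissue readouts,
plus a seeded synthetic-data generator that provides ground truth for
every stage.

# The granularity statistic

The central per-cell feature for CALR-GFP aggregation and quinacrine
vesicles is a texture score. For a cytoplasmic ROI $R$ with mean
intensity $\bar I_R$, partition the bounding box of $R$ into
non-overlapping $b \times b$ pixel blocks anchored at the bounding-box
origin, keep blocks with at least 50% of their pixels inside $R$, and
let $m_1, \dots, m_k$ be the mean intensities of the kept blocks over
their ROI pixels. The granularity score is

$$ G = \frac{\mathrm{sd}(m_1,\dots,m_k)}{\bar I_R}, $$

the standard deviation of the means of groups of adjacent pixels,
normalized by the ROI mean. $G = 0$ for a uniform ROI, $G$ is exactly
invariant under intensity scaling ($G(cI) = G(I)$), and $G$ grows as a
fixed amount of fluorescence concentrates into puncta.

Choices that the definition leaves open, and our defaults:

* **Block size** `blockPx = 4` px — comparable to the generated granule
  width (sigma 1.2–1.5 px), exposed as a parameter.
* **Sample SD** ($n-1$ denominator) — block counts per cell are small;
  the brute-force oracle in the tests uses the same convention.
* **Edge blocks** with under 50% ROI coverage are discarded, not
  partially weighted, to avoid edge-inflated variance (`minCoverage`).
* **Background**: the per-image median is subtracted from biosensor and
  PI channels (floored at 0) before feature computation, making SD/mean
  comparable across fields; `backgroundSubtract = FALSE` measures raw
  intensities. Whether the original instrument software corrected
  backgrounds is unknowable from outside, so both modes exist and the
  corrected mode is the documented default.

Cells for which the score is undefined (fewer than two valid blocks, or
a zero ROI mean) return an `NA` sentinel with a reason, are excluded from
summaries and are counted in the QC log.

# Segmentation

Nuclei are segmented from the median-filtered counterstain by Otsu's
threshold (the instrument's internal method is unpublished; Otsu is
parameter-free and standard), holes are filled, and touching nuclei are
split by a watershed on the distance transform (`minDistance` is the
merge tolerance). Objects touching the image border are excluded by
default because their cytoplasm would be truncated. Debris is excluded
by area and mean-intensity bounds (`filterDebris`); the defaults
(10–5000 px at the package's simulated scale) were calibrated on the
synthetic generator, not on any instrument data, and should be adapted
to real pixel sizes.

Cytoplasmic ROIs are fixed-width rings (`ringWidth = 4` px) around each
nucleus; contested pixels go to the nearest nucleus via seeded
propagation (a Voronoi-style partition), nuclear pixels are excluded,
and disjointness of cytoplasm regions is guaranteed by construction.
A ring was chosen over a second cytoplasm-channel threshold because the
biosensors are GFP-only — no dedicated cytoplasm stain exists in this
assay family.

Coordinates are pixel-centred, 1-based, row-major (R matrix
convention).

# Threshold calibration and statistics

Per-assay decision thresholds come from the Gaussian distributions of
negative and positive controls: fit $N(\mu_-, \sigma_-)$ and
$N(\mu_+, \sigma_+)$ to the control feature values and place the
threshold at the equal-likelihood intersection between the means (for
equal SDs, the midpoint). When no positive control exists the package
falls back to $\mu_- \pm k\sigma_-$ (default $k = 3$, oriented by the
assay direction) with a warning. Assay directions: CALR granularity
**up**, quinacrine granularity **down** (vesicles depleted), nuclear
HMGB1 **down** (released), MX1 **up** (induced).

Wells are summarized as the fraction of viable (PI-low), QC-passing
cells positive under the threshold. Wells with fewer than `minLive = 50`
viable cells are flagged "insufficient viable cells" and excluded —
with too few dye-excluding cells, positivity among them cannot be
appreciated.

Group comparisons use the two-tailed Welch-corrected t-test
(Satterthwaite degrees of freedom) against untreated reference wells,
with per-comparison significance stars (\*, \*\*, \*\*\* for p below
0.05, 0.01, 0.001). No multiple-testing correction is applied across
doses by default, matching per-comparison reporting conventions; a Holm
flag exists.

# Cytometry gating

Event tables (CSV schema: `event_id`, `PI`, `marker`) are gated to
viable cells (`PI < threshold`). The PI threshold can be calibrated
unsupervised: a two-component Gaussian mixture on log intensities
(cytometry intensities are approximately log-normal), thresholded at
the components' equal-likelihood intersection — the same rule as the
imaging assays. Marker positivity among live events is reported as a
fraction with an exact Clopper–Pearson 95% CI, together with the mean
marker intensity (both outputs are emitted because figure-level
conventions differ). FCS binary parsing, compensation and scatter
gating are out of scope.

# Tissue readouts

HE images are separated into hematoxylin and eosin density maps by
Beer–Lambert colour deconvolution with the standard published stain
basis (overridable): $OD = -\log_{10}((I+1)/I_0)$ with $I_0 = 256$,
least-squares projection onto the stain vectors, negative densities
clipped. The forward model `composeHE()` uses
$I = \mathrm{round}(I_0 10^{-OD} - 1)$, so composition and
deconvolution invert each other up to 8-bit rounding.

Necrosis appears as HE de-coloration: the per-pixel eosin/hematoxylin
ratio (masked where hematoxylin falls below a floor) and the fraction of
tissue area with low hematoxylin density (Otsu threshold on the
hematoxylin histogram within the tissue mask by default; the tissue mask
keeps pixels with total OD above a small floor so fractions are relative
to tissue, not glass). Infiltrating leukocytes are counted as small,
strongly hematoxylin-dense blobs within a region, detected in OD space
(hence invariant to uniform brightness changes) and banded by equivalent
diameter. Whether the original counts were manual or automated is not
stated anywhere; the automated counter is validated against synthetic
ground truth only.

Immunofluorescence sections are scored as percent marker-positive cells
per view field: nuclei from the DAPI channel, marker read as nuclear
mean (HMGB1 loss, direction below) or whole-cell mean (CASP-3a,
p-eIF2$\alpha$, CD3, F4/80, direction above) against a calibrated
threshold.

# The synthetic-data generator

No raw images or event data are publicly deposited for this assay
family, so validation rests on a seeded generator whose defaults define
the package's study conditions:

* **Fields**: 208 x 208 px, 50 cells (within the realistic 50–300 cells
  per field at screening magnification), nuclear radius 6 ± 0.8 px,
  cytoplasm ring 4 px, 10% dead cells, six view fields per well. The
  geometry is a scaled-down rendering of a 16-bit sCMOS field that
  preserves per-cell structure while keeping desk-scale runs fast.
* **Placement**: ellipses with jittered radii by rejection sampling
  (max 10^4 attempts per cell), minimum 6 px between nucleus
  boundaries. This keeps neighbouring cytoplasm regions from
  overlapping, so each rendered phenotype belongs unambiguously to one
  cell — the property that makes ground-truth recovery testable.
  Granule centres are additionally kept two spot-widths inside the
  cell's cytoplasm extent so puncta do not bleed into neighbours.
* **Phenotypes**: responders carry the treated phenotype — granular
  CALR-GFP (8 puncta), depleted quinacrine vesicles (30 puncta in
  untreated cells, none in responders), nuclear HMGB1 at 0.2x the
  retained level, MX1 reporter at 10x baseline. Granule-bearing cells
  redistribute a fixed per-granule intensity mass out of the diffuse
  cytoplasmic pool, approximately conserving total intensity across
  granule counts.
* **Noise**: Poisson shot noise on expected counts plus additive
  Gaussian read noise (SD 10 counts), qualitatively matching sCMOS
  acquisition; per-cell lognormal expression variability (CV 0.1).
  Dead cells render condensed (0.7x radius), brighter (2.2x) nuclei
  with elevated PI, so viability filters are exercised.
* **Plates**: well roles neg (responder fraction 0), pos (1) and
  treated (four-parameter logistic of dose, floor 0.02, ceiling 0.95,
  EC50 100, Hill 2). Per-field seeds derive from one master seed;
  every generator is bit-reproducible given its seed.
* **Events**: two log-normal PI components (live at meanlog log 50,
  dead at log 2000, sdlog 0.35) and two log-normal marker components
  (log 100 / log 1000, sdlog 0.4) among live events.
* **Tissue**: uniform stain densities with a central necrotic disc
  (hematoxylin 0.7 outside / 0.15 inside, eosin 0.45 / 0.75), planted
  leukocyte puncta (radius 2 px, +2.0 hematoxylin OD), Gaussian
  density noise (SD 0.02), composed through the standard stain basis.

What the generator does **not** emulate: optics (no PSF), 3-D structure,
cell crowding and touching cytoplasm, uneven illumination, photobleach,
autofluorescence, spectral bleed-through, or real stain variability.
Passing recovery tests therefore demonstrates the correctness of the
measurement chain under controlled conditions — not robustness to every
artefact of real microscopy. The debris and threshold defaults are
calibrated to this simulated scale and must be re-examined on real
pixels.

# Numerical choices and degenerate inputs

* Granularity: `NA` sentinel with reason for <2 valid blocks or zero
  ROI mean; empty ROI is an error.
* Threshold fit: at least 20 values per control group, SD 0 or equal
  means are errors; the intersection root is the one between the two
  means (unequal SDs give a quadratic with two roots; the far root
  lies outside the control range and is ignored).
* Welch test with zero variance in both groups and equal means returns
  t = 0, p = 1 by convention.
* All-zero images segment to an empty mask (not an error); NA/NaN
  pixels are errors.
* Tissue area fraction realized by disc rasterization is within 1% of
  the request; leukocyte puncta are placed with a minimum separation of
  four radii so each forms its own blob.

# Problem sizes in the test-suite and acceptance runs

Validation runs at desk scale, chosen as the package's own benchmark
conditions: 50 seeded fields of 40 cells for count recovery; 24-well
plates (3 neg / 3 pos / 6 doses x 3) at 6 fields x 50 cells per well for
the four end-to-end assay recoveries; 10^4-event tables for gating;
10^4 null replicates for the Welch type-I error; 512 x 512 or 256 x 256
px tissue images. A full 24-well plate analysis takes on the order of a
minute on one core.

# Known limitations

* Segmentation is classical (threshold + watershed); heavily confluent
  or overlapping nuclei are out of scope, as is any learned model.
* The cytoplasmic ring is geometric; it does not follow true cell
  borders.
* Spot-level vesicle counting is deliberately absent — vesicles are
  quantified through granularity, matching the assay definition.
* EC50 curve fitting, plate-effect normalization and mixed-effects
  models are out of scope; well summaries feed plain Welch tests.
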
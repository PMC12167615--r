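---
title: "Quantifying organ-at-risk uptake and the tumour sink effect in PSMA PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying organ-at-risk uptake and the tumour sink effect in PSMA PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmasink)
```

## Background

Radiolabelled PSMA ligands used for prostate-cancer imaging and radionuclide
therapy are not tumour-specific: the kidneys, liver, parotid glands and
spleen all accumulate tracer, and these organs at risk limit the activity
that can safely be administered therapeutically.  Two quantities matter for
individualized therapy planning: how variable healthy-organ uptake is across
patients, and whether a large tumour burden depresses healthy-organ uptake
by sequestering tracer — the *tumour sink effect*.  `psmasink` implements
the full quantification chain needed to study both on PET volumes with
co-registered organ and lesion segmentations, plus a digital-phantom
generator that provides ground truth where patient images cannot.

## The SUV model

A PET voxel stores an activity concentration $A_c$ (kBq/mL).  The
standardized uptake value normalizes it by injected activity per body mass:

$$\mathrm{SUV} = \frac{A_c}{A_i / w},$$

where $A_i$ is the administered activity decay-corrected to the start of
imaging, $A_i' = A_i \cdot 2^{-\Delta t / T_{1/2}}$ with
$T_{1/2} = 109.77$ min for F-18, and $w$ is body weight.  With $A_i$ in kBq,
$w$ in grams and tissue density taken as 1 g/cm³, SUV is unitless.
`decay_correct()` and `to_suv()` implement exactly this; decay *during* the
acquisition is ignored — the administered activity is corrected forward to
the scan start only, which is the convention the rest of the pipeline
assumes.  All internal units are mm, kBq, g and minutes; converters live at
the I/O boundary.

## Automated VOI placement

SUVmean in an organ at risk is read out in a spherical volume of interest
(VOI) placed automatically inside the segmentation: 30 mm diameter for the
liver, 15 mm for kidneys, parotid glands and spleen.  The placement
algorithm avoids metastases and edge effects in four steps:

1. **SUVpeak map** — for every voxel of the organ mask, the mean SUV in a
   1 cm³ sphere (diameter $2(3/(4\pi)\cdot 1000)^{1/3} \approx 12.407$ mm)
   centred at that voxel.  We read "SUVpeak" as the mean-in-sphere local
   average (the EANM convention); the kernel samples the image, not the
   mask, and is truncated to in-grid voxels at the image border.
2. **Candidates and scores** — a voxel is a valid sphere centre only if no
   part of the measurement sphere comes within 5 mm of the organ edge.  On
   voxel centres this is exactly the condition that the distance to the
   nearest background voxel centre is at least $r + 5$ mm, implemented as
   erosion of the mask by the open ball of that radius (with a fast
   separable-cross prefilter; an exact brute-force distance check backs it
   post hoc).  Each candidate is scored by the maximum plus the standard
   deviation of the SUVpeak values its measurement sphere covers; only
   in-mask SUVpeak values contribute, since SUVpeak is defined on the organ.
3. **Median score** — the standard median of all candidate scores (mean of
   the two central values for an even count).
4. **Selection** — the candidate whose score is closest to the median.
   Hot-spot-adjacent candidates have extreme scores and are never closest
   to the median, which is what produces the lesion-avoidance behaviour.

SUVmean is then measured on the SUV volume (not the SUVpeak map) over the
measurement sphere at the chosen centre.

### Numerical and convention choices

* **Sphere membership** is by voxel centre within the radius; no
  partial-volume weighting.  The discretized 1 cm³ kernel holds 123 voxels
  at 2 mm spacing (0.984 cm³); the deviation from 1 cm³ is bounded by the
  half-diagonal boundary shell and vanishes with finer grids.
* **Standard deviation** in the score is the population SD (divide by $N$);
  the sample/population choice is not dictated by the measurement
  definition, so it is fixed and documented here.
* **Tie-breaking.**  For an even candidate count the two central candidates
  are equidistant from the median up to floating-point rounding, so an
  exact argmin would be platform-dependent.  Distances within a $10^{-9}$
  relative tolerance count as tied and the smallest $(z, y, x)$-lexicographic
  voxel index wins — bit-for-bit reproducible across runs and platforms.
* **Paired organs** (kidneys, parotid glands) are pooled into one mask and
  receive a single sphere by default, matching a single reported value per
  organ; `per_component = TRUE` places one sphere per connected component
  and averages the SUVmeans.
* **Failed organs** (missing mask, organ too small for its sphere plus
  margin) are recorded as `NA` with a warning and the patient-level run
  continues.
* A placement whose sphere maximum exceeds a configurable multiple
  (default 2) of the organ's median SUV is flagged (`flagged_hot`),
  replacing a manual review step for high-burden patients with an
  automated report flag.

## Tumour-burden metrics

From the lesion segmentation: total lesion volume
$\mathrm{TLV} = \sum \text{voxels} \times \text{voxel volume}$ (cm³); total
lesion uptake $\mathrm{TLU} = \mathrm{TLV} \times \overline{\mathrm{SUV}}$
over the *union* of all lesion voxels (one global mean), which is
identically the voxelwise sum of SUV times voxel volume; and the percentage
of injected activity in tumour, $100 \cdot \mathrm{TLU} / (w\,[\mathrm{g}])$,
which follows from the SUV definition with density 1 g/cm³ and is verified
against the direct voxel-summed activity fraction to $10^{-9}$ on noiseless
phantoms.  TLU is reported in SUV·cm³ (numerically what is sometimes
printed with a bare cm³ unit).

## Cohort statistics

* **Spearman correlation** of TLV and TLU against each organ's SUVmean:
  tie-corrected rho (Pearson on average ranks), two-tailed p from the
  t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ — appropriate at
  cohort scale; an exact permutation p over all $n!$ orderings is available
  for $n \le 10$ and is used as the oracle in tests.  By default all
  patients enter the correlations (the large group of zero-burden patients
  becomes one average-rank tie); `tumour_only = TRUE` restricts to
  TLV > 0.  Missing organ values are removed pairwise per correlation.
* **Stratification** of TLV into six groups with half-open intervals:
  0, (0, 25], (25, 189], (189, 532], (532, 1355], (1355, ∞) cm³.
* **Summaries** are median and IQR with type-7 (linear interpolation)
  quartiles, recorded in the report metadata.
* **log10(x + 1)** is applied to TLV/TLU for scatter display only; rank
  statistics are invariant under it (asserted to $10^{-12}$ in tests), so
  the choice of base is cosmetic.

## The phantom generator

`generate_patient()` rasterizes ellipsoidal organs (kidneys and parotids as
bilateral pairs) and spherical lesions on a voxel grid, default
64³ at 2 mm.  Baselines default to the organ-median SUVs of a large
[18F]PSMA-1007 cohort (kidneys 13.1, liver 11.8, parotids 18.6,
spleen 11.3); organ centres sit on voxel centres so the smaller organs
retain their full discrete inscribed radius.  The SUV field is optionally
smoothed (separable Gaussian, FWHM in mm) and perturbed with Gaussian voxel
noise whose SD is a fraction of the local noiseless value — a desk-scale
stand-in for reconstructed-PET noise, *not* a physical noise model.  The
field is then converted to activity concentration through the inverse SUV
relation so the pipeline's own conversion round-trips, and the truth record
carries exact per-organ means, TLV, TLU and percentage of injected
activity.

`generate_cohort()` is the image-free fast path for cohort-level questions.
Per patient it draws:

* TLV: zero-inflated lognormal — point mass $157/1086 \approx 0.145$ at 0;
  among tumour-bearing patients lognormal with median 3.8 cm³ and
  $\sigma_{\log} = 2.0$, chosen so the upper tail reaches the observed
  ~2000 cm³ range at cohort size;
* lesion SUVmean: lognormal, median 8.2 ($\approx 31.2/3.8$, reproducing
  the observed median TLU), $\sigma_{\log} = 0.4$;
* organ baselines: $B_o \cdot \varepsilon_o$ with
  $\varepsilon_o \sim \mathrm{lognormal}(0, \sigma_o)$ and $\sigma_o$
  solved from the observed median/IQR of each organ
  ($\sigma_o = \mathrm{asinh}(\mathrm{IQR}/2\,\mathrm{median})/z_{0.75}$);
* weight $\sim N(87, 14^2)$ kg truncated to 48–146; injected activity
  $4.0 \pm 0.2$ MBq/kg.

The **sink coupling** is a saturating (Michaelis–Menten-like) suppression

$$\mathrm{SUV}_o = B_o \left(1 - \beta\,\frac{\mathrm{TLU}}{\mathrm{TLU} + K}\right)\varepsilon_o,$$

with $\beta \in [0, 1)$ the maximal fractional suppression and $K$ the
half-saturation burden in SUV·cm³.  The hypothesis being modelled gives no
functional form; this one is monotone in burden, saturates, produces
appreciable effects only at very high TLV when $K$ is large, and makes
parameter recovery well-posed.  $\beta = 0$ is the exact null.  All
randomness flows from one seed recorded in the output.

### What the phantoms do and do not show

The generator emulates heterogeneous baseline uptake, right-skewed burden,
multiplicative inter-patient variability, additive image noise and an
optional sink coupling.  It does **not** emulate realistic anatomy, scanner
physics (PSF, attenuation, reconstruction artefacts), respiratory motion,
partial-volume effects, or segmentation error.  Passing tests therefore
demonstrate that the *measurement chain* is correct and well calibrated —
not that the sink effect exists or is absent in any real cohort.

## Problem sizes and test design

The test suite exercises: placement equivalence against a monolithic
brute-force reference on 20 seeded 32³ single-organ phantoms; noiseless
recovery (error ≤ 1e-9) and 5%-noise recovery (within 2% of baseline in
≥ 95% of 50 × 4 organ placements, the 15 mm sphere averaging ~220 voxels at
2 mm spacing); lesion avoidance over 20 noisy phantoms with a 10× hot
lesion; exhaustive edge-margin re-checks by brute-force distance; mass
balance to 1e-9; and cohort calibration/detection over 20 replicates of
n = 500 (null: all eight |rho| < 0.1; sink at β = 0.6, K = 500: kidney rho
negative with p < 0.05 and stratified means non-increasing).  These sizes
were chosen so the whole suite runs comfortably on a single CPU while
keeping the sphere-statistics and sampling regimes representative.

## Known limitations

* Gaussian SUV-proportional noise is a convenience model; real
  reconstructed-PET noise is spatially correlated and non-Gaussian.
* Voxel-centre sphere membership makes small-sphere volumes grid-dependent
  (0.984 cm³ at 2 mm for the nominal 1 cm³ kernel).
* The t-approximation p-value is inaccurate below n ≈ 10; use the
  permutation method there.
* Organ masks are treated as given; segmentation itself, registration and
  partial-volume correction are out of scope.
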
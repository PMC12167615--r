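# psmasink

Quantification pipeline for [18F]PSMA-1007 PET studies of prostate cancer:
organ-at-risk uptake measurement, tumour-burden metrics, and cohort-level
tumour-sink analysis, with a digital-phantom generator providing ground
truth for every stage.

PSMA ligands accumulate not only in tumour but in the kidneys, liver,
parotid glands and spleen — the organs at risk that limit radionuclide
therapy dosing.  Whether a large tumour burden depresses healthy-organ
uptake (the *tumour sink effect*) matters for individualized dosimetry.
This package implements, for PET volumes with co-registered organ and
lesion segmentations:

* **SUV conversion** with radioactive-decay correction:
  `SUV = Ac / (Ai'/w)`, `Ai' = Ai · 2^(−Δt/T½)` (T½ = 109.77 min for F-18);
* **Automated VOI placement** inside each organ mask: an SUVpeak map
  (mean in a 1 cm³ sphere per voxel), candidate filtering so no part of the
  measurement sphere (30 mm liver, 15 mm others) comes within 5 mm of the
  organ edge, scoring of each candidate by max + SD of SUVpeak in the
  sphere, and selection of the candidate with score closest to the median —
  which deterministically avoids metastases and edge effects;
* **Tumour-burden metrics**: total lesion volume (TLV, cm³), total lesion
  uptake (TLU = TLV × lesion SUVmean), and the percentage of injected
  activity in tumour (TLU/weight);
* **Cohort statistics**: per-organ median/IQR summaries, tie-corrected
  Spearman correlations of TLV/TLU vs organ SUVmean with two-tailed tests,
  TLV stratification into six groups (0, ≤25, ≤189, ≤532, ≤1355,
  >1355 cm³), and log10(x+1) scatter data;
* **Digital phantoms**: single patients (ellipsoidal organs, spherical
  lesions, known truth) and whole cohorts with a parameterized saturating
  sink coupling `SUV_o = B_o (1 − β·TLU/(TLU+K)) ε_o`.

## Worked example

```r
library(psmasink)

# a noisy digital phantom with a known 30 SUV lesion
cfg <- phantom_config(noise_sd_frac = 0.05, seed = 7,
                      lesions = list(list(center = c(64, 64, 20),
                                          radius = 8, suv = 30)))
ph <- generate_patient(cfg)
pr <- run_patient(ph$pet, ph$organ_masks, ph$meta, lesions = ph$lesions)
print(pr)
#> Patient P0001
#>   kidneys    liver parotids   spleen  tlv      tlu pct_injected
#>  13.10527 11.79182  18.6673 11.27233 2.24 67.22775   0.07727328

# true baselines were kidneys 13.1, liver 11.8, parotids 18.6, spleen 11.3:
# each organ is recovered within a fraction of a percent at 5% voxel noise.
# tlv is the rasterized 8 mm sphere (2.24 cm3); pct_injected says 0.077%
# of the administered activity sits in the lesion.

# a synthetic cohort with a moderate sink coupling
co <- generate_cohort(cohort_config(n = 500, beta = 0.6, K = 500, seed = 3))
rep <- run_cohort(co)
print(rep)
#> Cohort report: 500 patients
#>
#> Organ-at-risk SUVmean, median (IQR):
#>   kidneys    12.2 (4.0)  n = 500
#>   liver      10.7 (4.6)  n = 500
#>   parotids   17.7 (7.6)  n = 500
#>   spleen     10.2 (5.5)  n = 500
#>
#> Spearman correlations vs organ SUVmean (two-tailed):
#>   TLV vs kidneys   rho =  -0.260, p = 3.75e-09 (n = 500)
#>   TLV vs liver     rho =  -0.348, p = 1.2e-15 (n = 500)
#>   ...
#> Patients per TLV stratum: zero = 67, very_low = 367, low = 55,
#>   moderate = 8, high = 1, very_high = 2

write_cohort_report(rep, "report/")   # tidy CSVs + JSON manifest
```

The negative rho with a small p detects the simulated sink; with
`beta = 0` the same analysis stays null-calibrated (all |rho| < 0.1).

A thin CLI over the same functions is installed at
`inst/cli/psma-sink.R` (`simulate-patient`, `simulate-cohort`, `measure`,
`analyze`).

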
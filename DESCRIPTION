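Package: psmasink
Title: Organ-at-Risk Uptake Quantification and Tumour-Sink Analysis for PSMA PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification pipeline for [18F]PSMA-1007 PET studies of
    prostate cancer: conversion of activity-concentration volumes to
    standardized uptake values (SUV) with radioactive-decay correction,
    automated placement of spherical measurement volumes of interest inside
    organ-at-risk segmentations (kidneys, liver, parotid glands, spleen)
    driven by an SUVpeak map with edge-margin and lesion-avoidance rules,
    tumour-burden metrics (total lesion volume, total lesion uptake,
    percentage of injected activity), and cohort-level statistics (Spearman
    correlations of burden versus organ uptake, TLV stratification,
    median/IQR summaries).  A digital-phantom generator produces single
    patients and whole cohorts with a parameterized tumour-sink coupling and
    known ground truth, so every pipeline stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
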
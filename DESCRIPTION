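Package: speechmvpa
Title: Multivoxel Pattern Analysis of Sparse-Sampled Speech-Production fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for decoding articulatory and
    phonatory conditions from sparse-sampled speech-production fMRI:
    single-trial response (beta-series) estimation from a nuisance-regressed
    general linear model, region-of-interest decoding with nested recursive
    feature elimination and a permutation-derived chance level, volumetric
    searchlight classification with contiguity-filtered sphere selection,
    beta-series seed connectivity with Fisher-z group inference, and
    acoustic (envelope, loudness, spectrogram, formant) and physiological
    (respiration, articulation) feature extraction. A synthetic-data
    generator plants known somatotopic multivoxel patterns, trial-gain
    couplings and a global respiratory response so that every stage of the
    pipeline is verifiable against ground truth without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    jsonlite,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    knitr
Config/testthat/edition: 3
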
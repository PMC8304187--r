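Package: petscore
Title: Integrated Tumor and Bone-Marrow FDG PET Prognostic Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation-driven pipeline for an FDG PET/CT prognostic score
    that combines primary-tumor radiomics with host bone-marrow uptake.
    Provides a synthetic phantom and survival-cohort generator, adaptive
    threshold (Nestle) tumor segmentation, six-vertebra 75 percent
    isocontour bone-marrow SUV quantification, a 41-parameter radiomic
    feature extractor (conventional, first-order and GLCM/NGLDM/GLRLM/GLZLM
    texture families after 64-level resampling), maximally selected
    chi-square cutpoint selection, Cox proportional-hazards modelling with
    Harrell's concordance index, Kaplan-Meier summaries, and the 0-4
    tumor-plus-host scoring system with prognostic-group stratification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
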
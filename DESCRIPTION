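Package: aquasem
Title: Aquaphotomics and Extracellular-Vesicle Proteomics of Seminal Plasma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-armed analysis of boar seminal plasma for semen-quality
    biosensing. The spectroscopy arm covers near-infrared first-overtone
    (1300-1600 nm) chemometrics: transmittance-to-absorbance conversion,
    grid harmonisation, PCA by singular value decomposition, linear
    discriminant classification with grouped cross-validation and
    confusion-matrix metrics, plus aquaphotomics summaries (WAMACS water
    band registry, WABS peak detection, barcodes and aquagrams against a
    distilled-water reference). The proteomics arm covers emPAI-based
    label-free abundance, shared/unique proteome partitioning, top-N
    abundance fractions and differential-protein calling between Passed
    and Failed groups. A seeded synthetic-data module emulates the study
    design (64 samples, 10 replicate spectra each, planted water-band
    shifts, planted differential proteins) so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
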
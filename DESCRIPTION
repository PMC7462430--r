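Package: connica
Title: Stability-Selected ICA of Hybrid EEG-fMRI Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds frequency-resolved EEG and fMRI functional connectomes
    (Pearson correlation for fMRI, band-limited imaginary coherency for EEG
    with a row-correlation range harmonization), stacks them into a hybrid
    (subject x band) by (fMRI || EEG) edge matrix, and extracts
    stability-selected independent connectivity components via repeated
    PCA+ICA runs. Components are characterized by intraclass correlation of
    their mixing weights, signed weighted modularity against a fixed
    intrinsic-connectivity-network partition with strength-preserving
    randomized nulls, cross-modal and cross-dataset edge correlations,
    motion associations, and top-edge network summaries. A synthetic-data
    generator plants ground-truth edge traits with subject- or
    frequency-tuned mixing so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
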
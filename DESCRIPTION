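Package: clonherit
Title: Broad-Sense Heritability of Cell Traits from Clonal Lineage Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the broad-sense heritability (H2) of
    single-cell traits such as curvilinear motility and generation time from
    time-lapse lineage-tracking data. Reads MTrackJ-style .mdf files and a
    plain tracking CSV dialect, reconstructs binary-division cell pedigrees,
    computes whole-lifetime traits with the cytokinesis-to-cytokinesis
    inclusion rules, and estimates H2 as the slope of a least-squares
    regression between trait values of related cells (sister-sister,
    mother-daughter and cousin-cousin), with auxiliary well-effect,
    family-size and off-screen checks. Includes a generative simulator of
    branching pedigrees with heritable, sister-shared and independent trait
    components realised as persistent-random-walk trajectories, with
    closed-form expected slopes for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
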
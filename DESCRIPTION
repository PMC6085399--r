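Package: fticrdom
Title: Molecular Formula Assignment, Fragmentation Analysis and
    Compositional Statistics for FT-ICR-MS of Dissolved Organic Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing ultrahigh-resolution mass spectra of
    natural dissolved organic matter (DOM). Implements internal mass
    calibration of centroided peak lists, constrained elemental formula
    assignment for singly charged [M-H]- ions with isotopologue
    verification, compound-class labelling via the modified aromaticity
    index, neutral-loss annotation of precursor-isolated fragmentation
    spectra, relative fragment-intensity statistics (paired regression
    slope deviation and Bray-Curtis dissimilarity at three compositional
    levels), and a carboxyl-group based estimator of minimum isomeric
    diversity. A seeded synthetic spectrum generator with full ground
    truth makes every pipeline stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tidyr,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
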
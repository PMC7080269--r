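Package: hybridbci
Title: Hybrid EEG-fNIRS Brain-Computer Interface Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for three-class hybrid EEG-fNIRS brain-computer
    interfaces discriminating mental arithmetic, motor imagery and an idle
    state. Provides a synthetic-participant generator with planted
    event-related desynchronization and hemodynamic responses, zero-phase
    Butterworth preprocessing, modified Beer-Lambert law conversion of optical
    densities to hemoglobin concentration changes, filter-bank common spatial
    pattern and temporal-window fNIRS features, shrinkage linear discriminant
    analysis with Ledoit-Wolf regularization, one-versus-one meta-classification
    with majority voting, repeated stratified cross-validation, and
    minimal-sensor selection (sequential backward selection of EEG channels and
    source-detector pair search for fNIRS).
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
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
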
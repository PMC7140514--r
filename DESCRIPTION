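Package: neurophenor
Title: Phenotyping Pipelines for Stem-Cell-Derived Neuronal Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification pipelines for functional phenotyping of human
    pluripotent stem cell (hPSC)-derived neuronal cultures: multielectrode
    array (MEA) spike, burst and network-burst analysis; GCaMP calcium
    transient (dF/F) analysis with photobleach correction; high-content
    image quantification (nuclear tracing, marker positivity, neurite
    length, synaptic puncta area); extracellular-flux respiration metrics;
    delta-delta-Ct relative expression and ELISA normalisation; and group
    statistics (Student's t, Tukey, Dunnett). Every input modality has a
    matching synthetic-data generator with recorded ground truth, so full
    analysis chains can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    EBImage,
    readr,
    yaml,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
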
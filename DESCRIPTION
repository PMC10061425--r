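Package: kitomeR
Title: Contamination Evidence and Exploration for Microbiome Count Tables
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes per-observation contamination evidence for microbiome
    studies from a raw observation-by-sample count table: frequency and
    prevalence scores against DNA concentration and negative controls,
    annotation against curated contaminant and human-related reference lists,
    biome-occurrence summaries, compositional transforms (relative, log,
    centered log-ratio), taxonomic rank decomposition, hierarchical
    clustering, and the symmetric proportionality (rho) coefficient.
    Assembles all evidence into a serializable bundle and renders a
    self-contained offline HTML report. Includes a seeded synthetic-study
    generator with planted contaminants for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    vegan,
    biomformat
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
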
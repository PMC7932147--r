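Package: posthypoxia
Title: Posthypoxic Immune Profiling and Retinal Structure Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the first 24 hours after severe systemic
    hypoxia in the mouse: ingestion and control-bead normalization of
    39-plex Luminex bead-array plates (plasma and retina), an exact
    small-sample permutation screen based on the minimal attainable
    p-value ("complete separation" of post-hypoxic and control groups),
    an exact Mann-Whitney / Benjamini-Hochberg secondary screen,
    hierarchical clustering of immune profiles with a group-segregation
    score, cross-tissue Venn partitioning of hits, and the companion
    optical-coherence-tomography and histology group statistics (layer
    derivations, paired t, one-way ANOVA with Tukey HSD including a
    summary-statistics reconstruction, two-way ANOVA, Pearson
    correlation). A seeded synthetic-data generator with known ground
    truth makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    jsonlite
Config/testthat/edition: 3
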
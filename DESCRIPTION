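Package: t4t5id
Title: Quantitative Subtype Identification of Drosophila T4/T5 Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to classify direction-selective T4/T5 neurons of the
    Drosophila optic lobe into their four subtypes (a-d) from morphology and
    gene expression: dendrite-orientation polar histograms around the
    dendrite's first branching point, an L1 similarity index between
    orientation histograms, normalized axon positions in the lobula plate
    with one-dimensional layer clustering, single-cell count QC and
    threshold-based differential-expression filtering with cross-stage
    consistency, marker-based cluster identity assignment, a combinatorial
    transcription-factor code (Dac/Ab class, Omb/Pros class, Grain) with
    gain- and loss-of-function perturbation maps, and a cell-body
    fluorescence enrichment score. A synthetic-data generator emulates the
    imaging and single-cell inputs these analyses assume, with ground-truth
    labels, so the full pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    methods,
    tools,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    png
Config/testthat/edition: 3
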
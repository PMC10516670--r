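Package: gonadfoci
Title: Quantification of Immunofluorescence Foci in C. elegans Germline Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying recombination-protein foci in 3D
    immunofluorescence image stacks of C. elegans gonads: 3D local-maxima
    focus detection with anisotropic neighborhoods, assignment of foci to
    manually segmented nucleus ROIs, object-based colocalization
    classification under diffraction-limit distance thresholds
    (0.61 lambda/NA), chromosome-axis association scoring through z-dilated
    axis masks, spatial staging of nuclei along the gonad (cell-row zones,
    peak-accumulation windows), crossover-position statistics on traced
    chromosomes, and brood-viability arithmetic. A synthetic-scene generator
    produces ground-truth-annotated image stacks, ROI sets and trace sets so
    that every stage of the pipeline can be validated without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
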
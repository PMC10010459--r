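Package: astroNVC
Title: Astrocyte Calcium, Neurovascular Coupling, and Synaptic Function
    Analysis for Awake Two-Photon Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for awake two-photon imaging of cortical
    astrocytes and microvessels, hippocampal field potentials, and Y-maze
    behavior. Detects astrocyte regions of interest with a local-maximum /
    size-filter segmentation, extracts calcium transients from dF/F traces
    and measures their amplitude and rise/decay kinetics, computes
    binarized-event pairwise correlations and weighted correlation
    coefficients for astrocyte network analysis, quantifies arteriole
    dilation responses and vessel leakiness, estimates red blood cell
    velocity from line-scan kymographs by the radon-transform method,
    fits three-parameter sigmoid synaptic strength curves and quantifies
    long-term potentiation, and scores spontaneous alternation. A
    synthetic-data module generates every input with known ground truth
    so the full pipeline is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    minpack.lm,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: CellBiology, Neuroscience, CalciumImaging, Software
RoxygenNote: 7.3.3
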
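Package: quamr
Title: Quantitative Automated Microscopy for Heterogeneous Primary Neuron Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Single-cell immunofluorescence quantification for heterogeneous
    primary sensory-neuron (DRG) cultures. Identifies neuron somata in a
    pan-neuronal marker channel by size, shape (Feret aspect ratio, convex-hull
    concavity depth) and contrast rules, rejects glia, debris, clustered and
    border-cut objects, and quantifies exposure- and area-normalized per-cell
    intensities on any number of channels. Marker-positive and
    stimulus-responsive subgroups are classified by the intersection of control
    and test intensity histograms, and measured cell numbers are translated
    into assay sensitivity by virtual-well resampling with finite-population
    correction. A ground-truthed synthetic culture generator and field renderer
    make every stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
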
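Package: theranosim
Title: Analysis Pipeline for Cell Networks, Drug Release, SERS Chemometrics
    and Nanoscale Surface Topography on Theranostic Silicon Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise cell-theranostic mesoporous silicon
    substrates from imaging and spectroscopy data. Converts fluorescence
    micrographs of DAPI-stained nuclei into spatial cell graphs via k-means
    segmentation and occupancy downsampling, connects cells with the Waxman
    distance rule and scores small-world-ness against an Erdos-Renyi null;
    fits first-order drug-release kinetics and derives release velocity,
    efficiency and drug efficacy from adhering-cell counts; normalises SERS
    hyperspectral maps, extracts principal components, clusters pixels and
    computes the integrin loading-ratio statistic at 1569 1/cm; estimates
    surface roughness, fractal dimension from the radially averaged power
    spectrum, porosity and particle sizes. A synthetic-data module generates
    every input with planted ground truth so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    minpack.lm,
    EBImage,
    jsonlite,
    withr,
    pracma,
    Matrix,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    png,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
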
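Package: macnet
Title: Quantitative Image Analysis of Membrane-Bound Actin Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify the architecture and myosin-driven
    contractility of minimal actin cortices: Hessian-eigenvalue tube
    filtering and skeletonization of fluorescence micrographs, skeleton
    network density, node detection, relative bundling factors, nematic
    order parameter maps from orientation fields, drift registration,
    frame correlation traces, particle image velocimetry, velocity
    magnitude distributions and three-way contraction classification,
    plus reflectometric-interference (optical thickness) and FRAP trace
    analysis. Includes a ground-truthed synthetic micrograph generator
    for filament fields, contraction time series, FRAP and binding
    traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    minpack.lm,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
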
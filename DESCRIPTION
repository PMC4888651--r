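Package: octspheroid
Title: Label-Free OCT Metrics of Treatment Response in 3D Tumor Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying treatment response of 3D tumor spheroid
    cultures from optical coherence tomography (OCT) intensity volumes.
    Reconstructs spectral-domain interferograms into intensity volumes,
    segments spheroid material per cross-sectional slice, and computes two
    label-free viability indices: a control-normalized global
    surface-area-to-volume disruption index, and an apoptotic density based
    on watershed-segmented hyperscattering bodies. Includes a synthetic
    phantom generator with known ground truth, a Live/Dead fluorescence
    benchmark, longitudinal group statistics with box-plot summaries and
    two-sample t-tests, and a per-day combination-therapy synergy table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
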
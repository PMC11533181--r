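Package: adrosys
Title: Relaxation-Ordered Deuterium NMR Spectroscopy: Processing, Inversion
    and Reverse-Micelle Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing and modelling toolkit for two-dimensional deuterium
    relaxation-ordered NMR spectroscopy (ADROSYS) of confined water.  Turns
    inversion-recovery FID series into 2D maps that correlate distributions of
    longitudinal relaxation times with chemical shift, using a regularized
    inverse Laplace transform with Butler-Reeds-Dawson (BRD) selection of the
    regularization parameter and truncated-SVD kernel compression.  Includes a
    full synthetic-data generator for multi-component inversion-recovery and
    T1-T2 relaxometry signals, direct-dimension spectral processing with
    1H-to-2H chemical-shift referencing, quadrupolar relaxation theory for
    spin-1 nuclei (correlation-time extraction, fast-exchange averaging), and
    reverse-micelle structural models (water-pool radius, aggregation number,
    water-loading algebra, core-shell trajectory models), together with a
    packaged table of correlation times for reverse-micelle samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
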
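Package: nchr
Title: Noise-Compensated Homotopic Non-Local Reconstruction for Rapid
    Spectral-Domain OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstruction of spectral-domain optical coherence tomography
    (SD-OCT) B-scans acquired at high A-scan rates, where the shortened
    detector exposure depresses the signal-to-noise ratio. Implements a
    homotopic non-local regularized reconstruction with modified James-Stein
    patch weights and a k-space data-consistency projection tied to the
    system noise floor, together with SNR/CNR image-quality metrics and a
    speckled layered-phantom simulator so the whole pipeline can be exercised
    without any real OCT data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    jsonlite,
    yaml,
    tiff,
    png,
    withr,
    optparse,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
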
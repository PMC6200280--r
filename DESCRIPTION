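Package: pd1sig
Title: Kinetic Modeling of PD-1/Shp2-Mediated Inhibition of Early TCR and
    CD28 Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic ordinary-differential-equation model of the
    proximal T-cell signaling network under inhibition by the immune
    checkpoint receptor PD-1. The model tracks phosphorylation of the
    CD3zeta and CD28 receptor tails by the kinase Lck, recruitment of
    Zap70, PI3K and the LAT-Gads-Slp76 adaptor module, and the
    recruitment of the phosphatase Shp2 to phosphorylated PD-1, whose
    PD-1-bound complexes dephosphorylate the receptors and Lck itself.
    Includes a catalogue of reconstitution-system simulation scenarios,
    PD-1 dose-response scans with Hill-function IC50 fitting, and a
    Latin-hypercube multi-parametric sensitivity analysis scored by
    two-sample Kolmogorov-Smirnov statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    lhs,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
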
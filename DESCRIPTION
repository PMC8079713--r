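Package: vercini
Title: Quantitative Analysis of FtsZ Treadmilling and Septal Constriction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bacterial cell-division imaging in the
    vertical-cell (VerCINI) geometry: sub-pixel septal ring fitting with a
    twelve-sector annulus signal model on a Gaussian-plus-Cauchy cytoplasmic
    background, circumferential kymograph extraction, Hessian ridge
    enhancement and filament-trace speed quantification, division-state
    classification and condensation step detection in axial-thickness time
    series, constant-synthesis septal constriction kinetics fitting, and
    bootstrap estimation statistics. Includes a synthetic-data generator
    emulating treadmilling filaments, camera noise and constriction
    trajectories for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
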
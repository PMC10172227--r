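Package: mtsens
Title: Musculotendon Parameter Derivation, Force Sensitivity and Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for Hill-type musculotendon parameters in musculoskeletal
    models. Derives the four classic parameters (maximal isometric force,
    optimal fiber length, optimal pennation angle, tendon slack length) from
    raw muscle-architecture measurements with every simplification made
    explicit and auditable; computes isometric rigid-tendon muscle force with
    pluggable, differentiable force-length curves; provides analytic partial
    derivatives of muscle force with respect to each parameter together with a
    finite-difference oracle, normalized-sensitivity sweeps and heatmap grids;
    uses those derivatives as the gradient for bounded parameter calibration
    against force observations; and grades dataset and model provenance against
    a taxonomy of nine common derivation simplifications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
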
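Package: mixinject
Title: Design and Diagnostics for Segmented-Droplet Mix-and-Inject Serial
    Crystallography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative design and diagnostics tools for segmented-droplet
    mix-and-inject serial femtosecond crystallography at X-ray free-electron
    lasers. Computes reaction time points from mixer/droplet-generator channel
    geometry and volumetric flow rates; solves the laminar advection-diffusion
    mixing problem in the mixer with an equimolarity mixing criterion and
    quantifies the mixing-time spread; models XFEL pulse-train timing and the
    train-spanning droplet-volume condition; simulates triggered droplet
    generation locked to a periodic reference with waterfall and lock-in
    diagnostics; and accounts for sample consumption of droplet versus
    continuous jet injection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
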
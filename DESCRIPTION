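Package: readry
Title: Reaction Engineering Approach Models for Continuous and
    Intermittent Grain Drying
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Lumped-parameter drying kinetics for grain batches using the
    reaction engineering approach (REA), in which evaporation is treated as
    an activated process and the surface relative humidity follows an
    Arrhenius-type law in an apparent activation energy. The package
    couples the REA mass balance to a batch energy balance, supports
    intermittent (drying/tempering) schedules with per-phase ambient
    switching, extracts the relative-activation-energy fingerprint from
    measured drying curves by inverse analysis, and ships a synthetic
    soybean drying experiment generator with known ground truth for
    end-to-end testing. Includes psychrometric helpers, Sherwood/Nusselt
    convective transfer correlations, schedule/intermittency accounting,
    cracking-ratio bookkeeping, and a small command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
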
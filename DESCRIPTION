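Package: sprgamma
Title: Interfacial Solute Enrichment from SPR Angle Scans and Density Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies interface-induced solute concentration
    enhancement in aqueous solutions, with glycine as the reference system.
    Forward-models p-polarized Kretschmann surface plasmon resonance (SPR)
    reflectivity with a transfer-matrix multilayer model, extracts the total
    internal reflection edge and plasmon coupling angle from angle scans,
    inverts paired (index-matched) scans to bulk and interfacial relative
    permittivities, and converts the permittivity contrast to an excess
    interfacial mass density via the Clausius-Mossotti relation and a
    literature-derived solution density model. Also analyzes species-resolved
    density profiles of solution films against a wall (binning, film width,
    interfacial averages, surface excess), and generates fully seeded
    synthetic scans, chips and profiles with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
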
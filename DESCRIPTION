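Package: redoxcolumn
Title: Coupled Hydrology and Redox Biogeochemistry of Arctic Soil Columns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates variably-saturated water flow, two-phase solute
    transport, and a Monod-kinetic microbial redox reaction network (aerobic
    respiration, fermentation, iron reduction and oxidation, acetoclastic and
    hydrogenotrophic methanogenesis) in one-dimensional Arctic soil columns
    subjected to drainage and saturation cycles.  Includes charge-balance pH
    speciation, a continuous stirred tank reactor (CSTR) headspace model with
    forward gas dynamics and flux inversion, saturated-hydraulic-conductivity
    sensitivity sweeps, a seeded generator of synthetic column observations
    (outflow, water content, oxygen, headspace gas, porewater chemistry, and
    sequential iron extractions), and the data-reduction operations used to
    summarise such experiments (phase flux statistics, rank correlations,
    dissolved organic carbon excursions, iron redistribution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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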
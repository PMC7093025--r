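Package: phytoalloc
Title: Coarse-Grained Macromolecular Allocation and Elemental
    Stoichiometry of Phytoplankton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A mechanistic, coarse-grained model linking phytoplankton
    macromolecular allocation (protein, chlorophyll, RNA, DNA, lipid,
    carbohydrate, and storage polymers) to cellular elemental
    stoichiometry (Chl:C, N:C, P:C, N:P), growth rate, and light and
    nutrient supply. Steady-state chemostat cultures are solved
    algebraically: photosynthesis saturates with irradiance, biosynthetic
    protein and RNA scale with growth rate, and the carbon budget closes
    through a storage pool, which also yields the light-dependent maximum
    growth rate. A culture-level layer determines the limiting nutrient
    and the luxury storage of the non-limiting one (cyanophycin,
    polyphosphate). Free parameters are calibrated against chemostat
    observations by a staged Metropolis-Hastings search, and a synthetic
    data generator emulating classic dilution-gradient chemostat designs
    makes the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
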
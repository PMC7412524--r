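Package: apisel
Title: Stochastic Simulation of Closed Honeybee Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-level, finite-locus simulation of closed honeybee
    (Apis mellifera) breeding populations under yearly BLUP-based
    truncation selection.  Queens are selected as dams via sister-group
    sizes and as dams of sires via mating-station counts; matings happen
    on isolated stations stocked by eight drone-producing sister
    colonies.  The package provides exact haplodiploid pedigree kinship,
    a bee-specific sparse relationship inverse with mating-station
    pseudo-sires, maternal/direct mixed-model evaluation with
    year-by-apiary fixed effects, five-yearly drone-based re-estimation
    of the genetic covariance, and scheme-level analysis of long-term
    genetic gain, loss of genetic variance, and generational inbreeding
    rates against FAO sustainability thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
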
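Package: phagemetrics
Title: Phage Infection Kinetics, Virulence Indices and CRISPR-Cas Protection Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of bacteriophage infection experiments from
    plate-reader and plaque-count data. Computes one-step growth metrics (burst
    size, adsorption fraction, eclipse period), dose-response virulence indices
    with a censoring rule against resistant-mutant regrowth, and area-under-
    growth-curve protection phenotypes for CRISPR-Cas interference assays across
    phage dose and nutrient condition, together with an entropy-based
    phylogenetic-signal screen for categorical traits and a mechanistic
    bacteria-phage-CRISPR population simulator that generates all test inputs
    synthetically with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
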
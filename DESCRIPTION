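Package: scatdiet
Title: Scat-Based Dietary Niche Analysis for Sympatric Carnivores
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative dietary ecology from carnivore scat
    (fecal) samples: frequency-of-occurrence diet profiles, biomass
    correction via linear feeding-trial correction factors, Pianka dietary
    overlap, Levins niche breadth with cluster-bootstrap confidence
    intervals and a permutation test for interspecific breadth differences,
    G-tests of prey use versus availability, and Manly selection ratios
    with Bonferroni-adjusted simultaneous confidence intervals. Includes a
    seeded synthetic scat-data generator so every analysis stage can be
    tested and calibrated without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
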
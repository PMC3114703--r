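Package: microloop
Title: Kinetics, Viral Production and Community Fingerprints for
    Predator-Manipulation Microcosms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis chain for size-fractionation microcosm experiments
    that separate the effects of viruses and flagellate grazers on lake
    bacterioplankton. Implements two-point exponential net growth and
    predator-attributable loss rates, viral production from 24-h dilution
    assays (regression slope corrected for host dilution) and its
    conversion to virus-induced mortality via an assumed burst size,
    leucine-to-carbon bacterial production, a treatment stimulation
    statistic with ANOVA / Fisher LSD and paired-t comparisons, and DGGE
    band-matrix analytics (relative intensities, commonality tables,
    Bray-Curtis similarity with UPGMA clustering). A synthetic microcosm
    generator with known ground truth drives parameter-recovery tests for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
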
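Package: secretrim
Title: Tripeptide-Processivity Modelling of Gamma-Secretase Cleavage of the
    APP Transmembrane Domain
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A rule-based simulator of processive intramembrane proteolysis of
    the amyloid precursor protein (APP) C99 substrate by gamma-secretase.
    Models weighted epsilon-site selection and sequential carboxy-terminal
    tripeptide trimming constrained by the three S' subsite pockets of
    presenilin (aromatic exclusion at S2', bulky preference at S1'/S3', no S4'
    contribution), site skipping, and Gly-Gly helix-lability at G38, yielding
    product distributions over amyloid-beta and AICD species and qualitative
    Abeta42/40 ratio predictions for mutant substrates. Also provides
    isotope-averaged mass prediction of FLAG-tagged AICD fragments for
    MALDI-TOF peak assignment, enzyme-inhibition kinetics (fractional IC50,
    global noncompetitive inhibition, Yonetani-Theorell mutual-exclusivity
    analysis) with simulation-based parameter-recovery checks, and seeded
    synthetic-data generators for velocity and ELISA-like readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
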
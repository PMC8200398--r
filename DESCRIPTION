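Package: teparypep
Title: In Silico Gastrointestinal Proteolysis and Bioactive Peptide
    Screening for Tepary Bean Lectin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates concerted gastrointestinal proteolysis of protein
    sequences with a configurable P1/P1' protease cleavage-rule engine
    (pepsin, trypsin, chymotrypsin by default), classifies released
    peptides by length and intestinal-transporter absorbability, screens
    externally scored peptide-receptor affinity and docking tables
    against the antiadipogenic binding site of PPAR-gamma, and computes
    protein nutritional-quality indices (FAO chemical score with
    limiting amino acid, Atwater energy, in vitro protein digestibility,
    and a calculated protein efficiency ratio). Bundles the tepary bean
    (Phaseolus acutifolius) lectin sequence and its published screening
    tables as fixtures, plus seeded synthetic-data generators with
    planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
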
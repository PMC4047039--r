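Package: peptigest
Title: In Silico Gastrointestinal Digestion and Bioactive Peptide Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based simulation of gastric and small-intestinal proteolysis
    (pepsin, trypsin, chymotrypsin specificity tables in the P1/P1' window
    nomenclature), matching of the resulting fragments against a reference
    database of known bioactive peptides, and the frequency statistics used to
    profile proteins as sources of bioactive peptides: the per-residue
    occurrence frequency of bioactive fragments in the intact chain (A_O), the
    relative frequency per activity category (Y, in percent), and the
    post-digestion release frequency (A_D).  Includes a registry of dietary and
    gut endogenous proteins with their secretion sites and digestion scenarios,
    a daily-quantity model converting per-molecule released-peptide counts into
    mg of bioactive peptide per g protein and per day under a model diet, and a
    synthetic-data generator that plants reference peptides with known
    releasability for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
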
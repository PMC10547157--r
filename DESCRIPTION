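Package: apkpath
Title: Design, Stoichiometry, and Kinetics of the Artificial Phosphoketolase Pathway
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the artificial phosphoketolase (APK) route that
    catabolizes C1-C6 carbon sources to acetyl-phosphate/acetyl-CoA.
    Generates the reaction network for any registered carbon source under a
    fixed routing policy with optional formaldehyde recycling (formolase or
    glycolaldehyde synthase), derives the exact overall reaction and carbon
    yield by rational flux analysis, simulates the in vitro multi-enzyme
    cascades with Michaelis-Menten kinetics, fits kinetic parameters from
    initial-rate assays and time courses, computes saturation-mutagenesis
    library sizes for NNK codons, generates synthetic assay and sequence
    data with declared noise models, and selects consensus-closest
    representative sequences from protein alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr
Config/testthat/edition: 3
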
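Package: ckyburden
Title: Missense-Variant Burden Around Chemoproteomic-Detected Cysteine,
    Lysine, and Tyrosine Residues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates residue-level chemoproteomics (reactive cysteine,
    lysine, and tyrosine sites detected by broad-spectrum covalent probes)
    with clinical missense variation. Provides peptide-level quality control
    and reactivity categorisation, mutually exclusive curation of pathogenic,
    benign/common, background, VUS and rare variant classes, gene-set
    enrichment with exact tests, linear-sequence window burden around
    detected residues, 3D structural-environment burden from terminal
    side-chain atom distances, CADD-based stratification of codons,
    candidate-protein prioritisation, and a seeded synthetic-data generator
    with planted enrichment for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
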
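Package: mitoscreen
Title: Candidate-Mutation Screening of Mitochondrial Genomes in Maternal Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Screens complete human mitochondrial genomes for candidate
    pathogenic point mutations. Extracts variants against a circular
    reference sequence, annotates them with a bundled gene map (including
    light-strand gene notation and coding-effect classification under the
    vertebrate mitochondrial genetic code), maps tRNA variants onto the
    cloverleaf secondary structure, computes a phylogenetic conservation
    index from multi-species tRNA alignments, and applies a three-criterion
    pathogenicity filter (control frequency, evolutionary conservation,
    structural location). Includes simplified haplogroup marker matching,
    clinical BMI and pedigree summaries, and seeded generators for every
    input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
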
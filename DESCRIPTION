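Package: vdjweave
Title: Full-Length T Cell Receptor Sequence Assembly from V/J/CDR3 Descriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs full-length, correctly spliced T cell receptor (TCR)
    coding nucleotide sequences from the minimal V gene / J gene / CDR3
    junction descriptions commonly used to report rearrangements. Junctions
    may be supplied as amino acids (non-templated residues back-translated
    from a species codon-usage table), as exact nucleotides, or as longer
    nucleotide reads for seamless integration. Includes a batch driver with
    bicistronic chain linking, a tiled-tag read annotator with allele-level
    V/J calling and novel-allele inference from recurrent two-tag match
    breaks, and a deterministic V(D)J recombination simulator that provides
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    methods,
    optparse,
    readr,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
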
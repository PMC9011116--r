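Package: codonforge
Title: Codon Optimization, Gene Construct Design and Global Alignment Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for synthetic gene design in heterologous expression hosts:
    expression-ranked codon-usage tables and codon adaptation index (CAI)
    scoring; a deterministic most-abundant-codon back-translator with
    constraint-aware repair (restriction-site avoidance, homopolymer caps,
    GC-content windows); protein engineering operators (N-terminal truncation,
    GSG-linker fusion, N-terminal transmembrane domain swap chimeras at codon
    boundaries); Needleman-Wunsch global DNA alignment with needle-convention
    percent identity and all-vs-all identity matrices; FASTA and GenBank CDS
    input; and a seeded fixture generator producing coding sequences with
    controlled codon bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
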
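Package: ampliclean
Title: Reference-Anchored Denoising of Pyrosequenced Protein-Coding Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Denoising pipeline for 454-style pyrosequences of protein-coding
    (indel-free) amplicons such as the mitochondrial COI barcode. Homopolymer
    insertion, deletion and compensated-indel read errors are corrected
    positionally against a consensus reference sequence over the IUPAC
    ambiguity alphabet; remaining PCR error, sequencing error and nuclear
    mitochondrial pseudogene (numt) artifacts are removed by consensus
    divergence and within-pool frequency filters, recovering inter- and
    intraspecific haplotypes without OTU clustering. Includes an IUPAC
    consensus builder, a seeded synthetic-read generator with a truth table
    for validation, per-step read accounting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
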
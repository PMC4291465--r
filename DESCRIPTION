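Package: barseqls
Title: Bar-Seq Lifespan and Growth Profiling of Pooled Deletion Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for parallel phenotyping of pooled deletion
    mutants by barcode sequencing (Bar-seq). Builds the barcode reference
    database (multiplex index + universal primer + tag + primer entries),
    assigns sequencing reads to mutants under a one-mismatch unique-hit rule,
    decodes barcodes from flanking genomic sequence, computes depth-normalized
    weighted tag fold-changes and per-gene chronological-lifespan and
    competitive-growth scores, calls long-lived mutants, analyzes
    colony-forming-unit viability curves, and ships a ground-truthed simulator
    of pooled-mutant time courses for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
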
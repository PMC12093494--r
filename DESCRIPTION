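Package: cazymeR
Title: Comparative CAZyme Genomics from HMMER Domain Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative genomics of carbohydrate-active enzymes
    (CAZymes). Reads HMMER3 hmmscan per-domain tables (--domtblout) produced
    against a dbCAN-style CAZyme HMM database, removes low-quality and
    overlapping/redundant domain hits, builds ordered per-protein domain
    architectures, maps CAZyme families to polysaccharide substrates
    (cellulose, xylan, lignin, starch, chitin, dextran, fructan, pectin),
    aggregates per-organism profiles (percent CAZyme CDS, category, family
    and substrate count vectors), and computes comparative statistics
    (group medians and standard deviations, pairwise Welch tests, ordinary
    least-squares regression, principal component analysis). A synthetic
    proteome simulator with known ground truth supports end-to-end
    validation without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
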
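Package: txsig
Title: Transcriptome Signature Analysis with Weighted Pathway Overrepresentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-condition replicate expression studies:
    per-probe Welch differential expression and significance filtering into a
    regulated-gene signature, pathway overrepresentation with inverse-membership
    gene weights and a binomial null, pathway-pair interconnectivity testing with
    tiered significance and Pajek network export, cross-platform signature mapping
    with Venn partitioning and direction-concordance analysis, and delta-delta-Ct
    qPCR concordance validation. Includes a synthetic-data generator with planted
    truth (signatures, enriched pathways, paired cross-platform signatures, qPCR
    panels) so that every stage of the pipeline can be verified against a known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    igraph,
    jsonlite
Config/testthat/edition: 3
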
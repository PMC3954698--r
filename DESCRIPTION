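Package: zfsig
Title: Cross-Species Tumor Signature Derivation and Single-Sample Enrichment
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives oncogene tumor gene signatures from zebrafish SAGE
    (serial analysis of gene expression) tag-count data and classifies
    individual human hepatocellular carcinoma samples against those
    signatures.  Implements TPM normalization, unreplicated and replicated
    differential-expression t-tests with fold-change/p-value/expression
    selection criteria, transcript/probe-to-gene collapsing and
    zebrafish-to-human homolog mapping, a weighted running-sum gene set
    enrichment engine with phenotype and gene-set permutation nulls
    (normalized enrichment scores, nominal p, permutation FDR), one-vs-rest
    per-sample cohort classification with representation and co-correlation
    summaries, signed log10-FDR pathway matrices with hierarchical
    clustering, and seeded synthetic-data generators with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
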
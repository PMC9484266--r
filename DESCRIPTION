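Package: epiorigin
Title: Cell-of-Origin Stratification of Keratinocyte Cancer Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stratifies bulk DNA methylomes of keratinocyte cancers
    (actinic keratosis and cutaneous squamous cell carcinoma) into
    epidermal-stem-cell-like and keratinocyte-like cell-of-origin
    subclasses using methylation at chromatin regions differentially
    accessible between undifferentiated and differentiated
    keratinocytes. Provides probe-level preprocessing for methylation
    arrays, probe-to-region summarisation and hierarchical subclass
    assignment, classification of external cohorts against a healthy
    reference, integration of sparse single-cell bisulfite methylomes
    with binarized bulk methylomes via classical multidimensional
    scaling, chromatin-state methylation summaries, differential
    accessibility and hypergeometric motif enrichment, a mitotic
    epigenetic clock for cumulative stem-cell division estimates, and
    simplified reference-based cell-type deconvolution. A synthetic
    data generator with known ground truth emulates the statistical
    structure of the cohorts so that every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
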
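Package: nohelpscore
Title: Helpless CD8 T Cell Signature Derivation and Nearest-Centroid Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a two-condition differential-expression signature from
    bulk RNA-seq counts with a negative-binomial common-dispersion exact test,
    scores query expression profiles against the two reference centroids by a
    difference of Pearson correlations (the "No Help score"), runs gene-set
    enrichment analysis with the weighted running-sum statistic and a
    permutation null, and provides the accompanying group-comparison
    statistics (pooled t-test, repeated-measures ANOVA with Tukey contrasts).
    Includes a negative-binomial count simulator that generates reference and
    graded-mixture query fixtures with known ground truth, so the whole
    pipeline is testable end-to-end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
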
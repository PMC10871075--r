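Package: wavecnv
Title: Genomic-Wave Correction and CNV Screening for SNP Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects chromosome-scale "genomic wave" artifacts in SNP-array
    log R ratio (LRR) signal by clustering wave patterns across a reference
    cohort (k-means with elbow-point model selection), assigning new samples
    to their wave cluster by k-nearest-neighbour classification, and
    re-expressing the signal as a per-marker Z-score rescaled back to the
    sample's original LRR moments (the modified LRR, mLRR). Around that core
    the package provides a complete copy-number screening pipeline: sample
    quality control, population B-allele-frequency tables, a distance-aware
    hidden Markov model segmenter, call merging, filtering and two-caller
    union, matching against a chromosomal-disorder region database, and a
    synthetic SNP-array cohort simulator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
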
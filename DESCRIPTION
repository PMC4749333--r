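Package: refstab
Title: Reference-Gene Stability Evaluation for qPCR Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates candidate qPCR reference genes from quantification-cycle
    (Cq) tables. Implements the five stability approaches used in plant
    reference-gene surveys: geNorm expression-stability M with stepwise gene
    exclusion and pairwise-variation analysis of the optimal reference-gene
    number, the NormFinder model-based intra/intergroup variance decomposition,
    the BestKeeper descriptive index, the comparative delta-Ct method, and a
    RefFinder-style comprehensive ranking by geometric mean of per-method
    ranks. Also provides standard-curve amplification-efficiency calibration,
    efficiency-corrected relative quantities, REST-style relative-expression
    ratios with a fixed-reallocation randomization test, a synthetic Cq data
    generator with known ground truth for method validation, and a pipeline
    that analyses overlapping sample sets end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
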
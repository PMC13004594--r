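Package: evmircq
Title: Differential Expression of Extracellular-Vesicle miRNAs from TaqMan
    Array Cq Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Turns raw TaqMan-array Cq measurements from extracellular-vesicle
    (EV) miRNA experiments into differentially expressed miRNA signatures.
    Implements well-level quality filtering on Cq, amplification score and Cq
    confidence; group expression-rate acceptance; media-control-referenced
    exclusion of serum-background assays; selection of endogenous normalizer
    miRNAs and global-mean delta-Cq normalization; matched-pairs delta-delta-Cq
    effect estimation with a Skillings-Mack rank test for incomplete block
    designs plus a grid of alternative tests; threshold-based signature
    selection with heatmap- and volcano-ready outputs; and a seeded synthetic
    experiment generator with ground truth for recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
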
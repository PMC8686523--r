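Package: qefs
Title: Quantitative Enhancer-FACS-Seq Library Design, Tag Counting, and
    Epistasis Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and analysis toolkit for barcoded combinatorial
    motif-mutant enhancer reporter assays read out by paired RNA-seq and
    DNA-seq of degenerate 3' UTR tags. Covers design of neutral 8-mer
    enhancer barcodes, PWM scanning with occupancy scoring and minimal
    binding-site-destroying mutagenesis, combinatorial allelic-series
    construction, tag-to-construct lookup-table building, UMI-based tag
    counting with mismatch-tolerant assignment, DNA-normalized expression
    quantification with quality-control filters, nonparametric allelic-series
    testing (Kruskal-Wallis omnibus, Conover-Iman post-hoc,
    Benjamini-Hochberg), multiplicative-model epistasis testing and
    classification, and a full synthetic-experiment simulator with ground
    truth for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
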
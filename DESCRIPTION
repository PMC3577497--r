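Package: lncscan
Title: Detection of Novel Long Non-Coding RNAs from Assembled Transcripts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects novel long non-coding RNA (lncRNA) candidates from
    genome-guided RNA-Seq transcript assemblies. Assembled transcripts (GTF
    with FPKM attributes) are classified against a merged reference annotation
    using cuffcompare-style class codes, low-quality assemblies are removed
    with an ROC-derived optimum expression threshold (closest-to-corner rule),
    and candidates are filtered by transcript length, longest putative open
    reading frame, PhyloCSF score and Pfam domain evidence. Includes a
    self-verifying synthetic fixture generator (toy genome, annotations,
    expression, coding-potential evidence with planted ground truth),
    per-step retention accounting, category summaries, feature comparisons
    (Welch t), fold changes and Benjamini-Hochberg adjusted significance
    calls, plus broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    methods,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
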
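Package: scentnet
Title: Organ-Comparison RNA-Seq Screening and Scent-Gene Co-Expression
    Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for comparing bulk RNA-seq expression across plant
    organs: RPKM quantification, a nonparametric noise-distribution
    differential-expression screen based on joint log-ratio (M) and
    absolute-difference (D) statistics, organ-unique gene detection,
    hypergeometric gene-set over-representation with multiple-testing
    correction, Pearson-correlation inference of transcription-factor to
    structural-gene co-expression networks, and 2^-ddCt relative
    quantification for qPCR concordance checks. Includes a negative
    binomial three-organ simulator with planted ground truth so every
    stage can be validated end to end without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
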
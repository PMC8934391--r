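Package: srnatlas
Title: Sequence-Level Analysis of Small RNA Tissue Atlases and Biofluids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sequence-level analysis of small RNA sequencing data
    across tissues and biofluids. Collapses adapter-trimmed reads into
    unique-sequence count tables with biotype assignment by a fixed priority
    order (miRNA, YRNA, tRNA, piRNA, protein coding, other), applies
    replicate-aware detection filters and median-of-ratios normalization,
    classifies sequences into the Human Protein Atlas tissue-specificity
    categories (tissue-enriched, group-enriched, tissue-enhanced), attributes
    sequences detected in biofluids to their tissues of elevated expression,
    and computes sequence/gene diversity and analytic rarefaction curves. A
    negative-binomial simulator with planted tissue-elevation and biofluid
    mixtures provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
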
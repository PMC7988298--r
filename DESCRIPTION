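Package: codonSDA
Title: Supply-to-Demand Adaptation of Translational Efficiency from
    tRNA and mRNA Abundances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes codon-level translational efficiency as the ratio of
    tRNA-derived decoding supply to transcriptome-weighted codon demand
    (supply-to-demand adaptation, SDA). Supply weights follow the tRNA
    adaptation index (tAI) convention with explicit, string-keyed
    codon-anticodon wobble pairing rules and configurable selective-constraint
    penalties; demand weights are expression-weighted codon usage over a
    coding-sequence set. Provides per-codon SDA weights (SDAw) with
    favored/balanced/disfavored classification, gene-level SDA scores
    (geometric means), differential SDA between conditions, per-gene relative
    codon usage, and cohort analyses: PCA of sample-by-codon SDAw matrices
    with marker correlation, per-codon rank-sum differential testing with
    Benjamini-Hochberg control, and a pre-ranked weighted Kolmogorov-Smirnov
    enrichment statistic with permutation p-values. Includes a synthetic
    cohort generator with planted supply/demand effects for end-to-end
    validation, plus readers and writers for FASTA, TSV and GMT formats and a
    subcommand-style command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    fgsea,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
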
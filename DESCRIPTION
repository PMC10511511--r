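Package: nascentfold
Title: Cotranscriptional RNA Folding, R-Loops and the Mutation-Rate Landscape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for structural probing of elongating
    transcripts (eSPET-seq-style paired reads in which the forward read marks
    a reverse-transcription stop at a chemically modified single-stranded
    base and the reverse read marks the transcription site). Computes
    per-nucleotide single-stranded scores from NAI-N3 versus DMSO RT-stop
    counts, per-intermediate RT-stop density matrices with an elongation
    complex footprint mask and winsorized normalization, sliding-window
    Wilcoxon detection of cotranscriptional structural transitions,
    DRIP-style R-loop log-enrichment scores, per-site relative mutation
    rates by maximum likelihood on a fixed phylogeny from the partition of
    branches into changed and unchanged sets, and the statistics linking
    folding, R-loops and mutation rate: Spearman and partial rank
    correlations, mediation fractions, within-gene odds ratios combined by
    the Cochran-Mantel-Haenszel procedure with gene-level bootstrap,
    within-gene permutation nulls, per-gene mutation-rate fold reductions
    and the mutation-rate-modifier selection-coefficient model. Ships a
    synthetic-data generator with planted ground truth so every stage has a
    parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
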
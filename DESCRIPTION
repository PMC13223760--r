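Package: utrintrons
Title: Detection, Classification and Splicing Statistics of 3' UTR Introns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects introns located downstream of stop codons (3' UTR
    introns, 3UIs) in assembled transcriptomes by intron-chain matching
    against a curated reference annotation, classifies them as exclusively
    UTR-located (e3UI) or CDS-overlapping (co3UI) and as annotated or
    novel, and records their spliced distance to the stop codon for
    comparison with the 55-nt nonsense-mediated decay rule. Includes the
    merge-stage assembly filters, sequence-level intron features (GC
    content, splice-site dinucleotides, DRACH motif counts),
    expression-based filters (TPM and transcript/gene fraction thresholds,
    broadly-expressed calls with junction coverage evidence), percent
    spliced out (PSO) summaries with per-gene Spearman correlation screens
    and Fisher-z comparison of conditions, and a seeded synthetic fixture
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    DESeq2,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    optparse,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
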
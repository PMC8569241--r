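Package: fusionforge
Title: Gene Fusion Detection for UMI-Tagged PCR Amplicon RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained workflow for detecting gene fusion transcripts in
    targeted, UMI-tagged PCR amplicon RNA sequencing panels. Reads are collapsed
    to molecular consensus sequences with Bayesian posterior base qualities,
    adapter trimmed, binned by best-hit gene against a longest-coding-transcript
    reference, assembled per gene with a greedy overlap-layout-consensus
    assembler, and split-aligned to the reference genome to discover breakpoint
    candidates. Candidates are screened for mononucleotide-repeat artifacts,
    blocklisted pairs and single-transcript events, annotated with exon and
    reading-frame context, and confirmed by realigning consensus reads to
    chimeric junction constructs; confirmed events are reported as paired VCF
    breakend records with an IGV review session. A deterministic amplicon read
    simulator generates panels, planted fusions and PCR duplicates so the whole
    pipeline is testable without external data, and benchmarking helpers
    compute accuracy, true-positive rate, MAPE and SMAPE against a truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    parallel,
    Rsamtools,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
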
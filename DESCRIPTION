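Package: splice2nmd
Title: Predict Nonsense-Mediated Decay from Differential Splicing Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs event-modified mature transcripts from Whippet
    differential-splicing calls, a genome FASTA and an Ensembl-dialect GTF
    restricted to canonical transcripts; predicts the reading frame of each
    modified transcript, enumerates premature termination codons (PTCs) per
    frame, and calls nonsense-mediated decay (NMD) by the 50-55 nt
    final-exon-junction rule. Includes cohort-level summaries (NMD rates,
    splicing-subtype breakdowns, PTC medians, psi-magnitude comparisons, a
    protein-direction rule combining expression, splicing and NMD), a
    synthetic toy-genome generator with known ground-truth NMD labels, and
    an independent brute-force translation oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomicRanges,
    jsonlite,
    nortest,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
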
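## Shared fixtures, built in code and memoized for the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

## A mixed synthetic cohort loaded once and reused across test files.
std_cohort <- function() {
  cached("std_cohort", {
    fx <- make_toy_genes(80, seed = 42, p_degenerate = 0.08,
                         p_not_on_canonical = 0.04,
                         p_transcription_related = 0.04)
    list(fx = fx,
         genome = load_genome(fx$fasta),
         annotation = load_canonical_annotation(fx$gtf),
         events = parse_diff_table(fx$diff))
  })
}

std_results <- function() {
  cached("std_results", {
    co <- std_cohort()
    run_pipeline(co$events, co$annotation, co$genome)
  })
}

## Write a minimal .diff file from a data.frame of raw Whippet columns.
write_raw_diff <- function(df, path = tempfile(fileext = ".diff")) {
  header <- c("Gene", "Node", "Coord", "Strand", "Type", "Psi_A", "Psi_B",
              "DeltaPsi", "Probability", "Complexity", "Entropy")
  lines <- c(paste(header, collapse = "\t"),
             apply(df, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  path
}

## Hand-built two-gene toy annotation on explicit sequences, used where
## exact, human-checkable values are wanted.
hand_toy <- function() {
  cached("hand_toy", {
    dir <- tempfile("handtoy")
    dir.create(dir)
    set.seed(99)
    chr <- paste(sample(c("A", "C", "G"), 400, replace = TRUE), collapse = "")
    ## plus-strand gene: exons [10,40) and [100,160); ATG at tx 6
    sub_in <- function(s, at, what) {                 # 0-based patch
      paste0(substr(s, 1, at), what, substr(s, at + nchar(what) + 1, nchar(s)))
    }
    chr <- sub_in(chr, 16, "ATGC")                    # start at tx 6 + guard
    chr <- sub_in(chr, 142, "TAA")                    # stop codon at tx 72
    fa <- file.path(dir, "hand.fa")
    writeLines(c(">chrH", chr), fa)
    gtf <- file.path(dir, "hand.gtf")
    attr1 <- 'gene_id "HG1"; transcript_id "HG1.t1"; tag "Ensembl_canonical";'
    writeLines(c(
      paste("chrH", "t", "transcript", 11, 160, ".", "+", ".", attr1, sep = "\t"),
      paste("chrH", "t", "exon", 11, 40, ".", "+", ".", attr1, sep = "\t"),
      paste("chrH", "t", "exon", 101, 160, ".", "+", ".", attr1, sep = "\t"),
      paste("chrH", "t", "CDS", 17, 40, ".", "+", "0", attr1, sep = "\t"),
      paste("chrH", "t", "CDS", 101, 142, ".", "+", "0", attr1, sep = "\t"),
      paste("chrH", "t", "stop_codon", 143, 145, ".", "+", "0", attr1, sep = "\t")
    ), gtf)
    list(fasta = fa, gtf = gtf, chrseq = chr)
  })
}
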
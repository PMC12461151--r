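## A small plus-strand scaffold used throughout: four exons of widths
## 150/100/200/120 with 80 nt introns, CDS from exon1 into exon4.
surgery_toy <- function() {
  cached("surgery_toy", {
    dir <- tempfile("surgery")
    dir.create(dir)
    set.seed(17)
    ex <- data.frame(start = c(100, 330, 510, 790),
                     end = c(250, 430, 710, 910))
    chr <- sample(c("A", "C", "G"), 1000, replace = TRUE)
    chr[(116 + 1):(116 + 4)] <- c("A", "T", "G", "C")    # start at tx 16
    chr[(851 + 1):(851 + 3)] <- c("T", "A", "A")         # stop in exon4, tx 511
    fa <- file.path(dir, "s.fa")
    writeLines(c(">chrS", paste(chr, collapse = "")), fa)
    a <- 'gene_id "SG1"; transcript_id "SG1.t"; tag "Ensembl_canonical";'
    ln <- function(type, s0, e0, fr = ".")
      paste("chrS", "t", type, s0 + 1, e0, ".", "+", fr, a, sep = "\t")
    gtf <- file.path(dir, "s.gtf")
    writeLines(c(ln("transcript", 100, 910),
                 ln("exon", 100, 250), ln("exon", 330, 430),
                 ln("exon", 510, 710), ln("exon", 790, 910),
                 ln("CDS", 116, 250, 0), ln("CDS", 330, 430, 0),
                 ln("CDS", 510, 710, 0), ln("CDS", 790, 851, 0),
                 ln("stop_codon", 851, 854, 0)), gtf)
    genome <- load_genome(fa)
    ann <- load_canonical_annotation(gtf)
    list(genome = genome, tx = ann$SG1,
         orig = assemble_mature(genome, ann$SG1))
  })
}

mk_event <- function(tx, type, s, e)
  list(gene_id = tx$gene_id, chrom = tx$chrom, start = s, end = e,
       strand = tx$strand, event_type = type, node = 1L,
       delta_psi = 0.3, probability = 0.95)

test_that("event placement identifies exons, introns and shifted edges", {
  st <- surgery_toy()
  ## exact internal exon
  p <- locate_event(mk_event(st$tx, "CE", 330, 430), st$tx)
  expect_equal(p$kind, "exact_exon")
  expect_equal(p$exon_index, 2L)
  expect_equal(p$net_length_change, -100L)
  ## intron between exons 1 and 2, both coordinate dialects
  for (coords in list(c(250, 330), c(100, 430))) {
    p <- locate_event(mk_event(st$tx, "RI", coords[1], coords[2]), st$tx)
    expect_equal(p$kind, "intron_between_exons")
    expect_equal(p$intron_index, 1L)
    expect_equal(p$net_length_change, 80L)
  }
  ## donor of exon1 extended 7 nt into intron 1
  p <- locate_event(mk_event(st$tx, "AD", 100, 257), st$tx)
  expect_equal(p$kind, "donor_shift")
  expect_equal(p$net_length_change, 7L)
  ## acceptor of exon2 shifted 5 nt into the exon
  p <- locate_event(mk_event(st$tx, "AA", 335, 430), st$tx)
  expect_equal(p$kind, "acceptor_shift")
  expect_equal(p$net_length_change, -5L)
  ## unplaceable coordinates and terminal exons raise notOnCanonical
  expect_error(locate_event(mk_event(st$tx, "CE", 331, 430), st$tx),
               class = "notOnCanonical")
  expect_error(locate_event(mk_event(st$tx, "CE", 100, 250), st$tx),
               class = "notOnCanonical")
  expect_error(locate_event(mk_event(st$tx, "TS", 100, 250), st$tx),
               class = "unsupportedType")
})

test_that("surgery rebuilds sequence, junctions and length as designed", {
  st <- surgery_toy()
  orig <- st$orig
  expect_equal(orig$junctions, c(150L, 250L, 450L))

  ## exon skipping drops one junction and the exon's bases
  p <- locate_event(mk_event(st$tx, "CE", 330, 430), st$tx)
  m <- apply_event(st$genome, st$tx, p, orig)
  expect_equal(nchar(m$seq), nchar(orig$seq) - 100)
  expect_equal(m$junctions, c(150L, 350L))
  expect_equal(length(m$junctions), length(orig$junctions) - 1L)

  ## retained intron fuses two exons: one junction fewer, +80 nt
  p <- locate_event(mk_event(st$tx, "RI", 250, 330), st$tx)
  m <- apply_event(st$genome, st$tx, p, orig)
  expect_equal(nchar(m$seq), nchar(orig$seq) + 80)
  expect_equal(m$junctions, c(330L, 530L))
  ## the fused stretch equals the literal genomic substring
  expect_equal(substr(m$seq, 1, 330),
               genome_fetch(st$genome, "chrS", 100, 430, "+"))

  ## acceptor shift 5 nt into the exon: junction count preserved
  p <- locate_event(mk_event(st$tx, "AA", 335, 430), st$tx)
  m <- apply_event(st$genome, st$tx, p, orig)
  expect_equal(nchar(m$seq), nchar(orig$seq) - 5)
  expect_equal(length(m$junctions), length(orig$junctions))
  ## brute-force string surgery oracle for the full sequence
  manual <- paste0(genome_fetch(st$genome, "chrS", 100, 250, "+"),
                   genome_fetch(st$genome, "chrS", 335, 430, "+"),
                   genome_fetch(st$genome, "chrS", 510, 710, "+"),
                   genome_fetch(st$genome, "chrS", 790, 910, "+"))
  expect_equal(m$seq, manual)

  ## zero-shift acceptor event is the identity on the sequence
  p <- locate_event(mk_event(st$tx, "AA", 330, 430), st$tx)
  m <- apply_event(st$genome, st$tx, p, orig)
  expect_equal(p$net_length_change, 0L)
  expect_equal(m$seq, orig$seq)
})

test_that("length conservation and junction arithmetic hold cohort-wide", {
  co <- std_cohort()
  for (i in seq_len(nrow(co$events))) {
    ev <- co$events[i, ]
    tx <- co$annotation[[ev$gene_id]]
    if (is.null(tx) || !tx$has_cds || !ev$event_type %in% SPLICING_TYPES) next
    orig <- assemble_mature(co$genome, tx)
    p <- tryCatch(locate_event(ev, tx), notOnCanonical = function(e) NULL)
    if (is.null(p)) next
    m <- apply_event(co$genome, tx, p, orig)
    expect_equal(nchar(m$seq) - nchar(orig$seq), p$net_length_change)
    dj <- length(orig$junctions) - length(m$junctions)
    expect_equal(dj, if (ev$event_type %in% c("CE", "RI")) 1L else 0L)
  }
})

test_that("skipping the start-codon exon is flagged start_lost", {
  fx <- make_toy_genes(1, seed = 23,
                       plans = list(list(event_type = "ES",
                                         scenario = "start_lost")))
  genome <- load_genome(fx$fasta)
  ann <- load_canonical_annotation(fx$gtf)
  ev <- parse_diff_table(fx$diff)[1, ]
  tx <- ann[[ev$gene_id]]
  p <- locate_event(ev, tx)
  m <- apply_event(genome, tx, p)
  expect_true(m$start_lost)
})
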
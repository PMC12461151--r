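#' Load a genome FASTA
#'
#' @param path FASTA path (optionally gzipped). Sequence names are truncated
#'   at the first whitespace, matching common chromosome naming.
#' @return A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Fetch a genomic interval, optionally reverse-complemented
#'
#' @param genome A DNAStringSet from [load_genome()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` returns the forward sequence, `"-"` its reverse
#'   complement.
#' @return Character scalar.
#' @export
genome_fetch <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome))
    stop("chromosome not in genome: ", chrom)
  L <- Biostrings::width(genome[match(chrom, names(genome))])
  if (start < 0 || end > L || start >= end)
    stop("interval out of bounds for ", chrom, ": [", start, ",", end,
         ") on length ", L)
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

## --- coordinate mapping between genomic and transcript space --------------
## blocks: data.frame(start, end), 0-based half-open, in transcription order
## (ascending genomic for "+", descending for "-").

block_widths <- function(blocks) blocks$end - blocks$start

genomic_to_tx <- function(blocks, strand, gpos) {
  cum <- 0L
  for (i in seq_len(nrow(blocks))) {
    s <- blocks$start[i]; e <- blocks$end[i]
    if (gpos >= s && gpos < e) {
      off <- if (strand == "+") gpos - s else e - 1L - gpos
      return(cum + off)
    }
    cum <- cum + (e - s)
  }
  NA_integer_
}

tx_to_genomic <- function(blocks, strand, tpos) {
  cum <- 0L
  for (i in seq_len(nrow(blocks))) {
    w <- blocks$end[i] - blocks$start[i]
    if (tpos < cum + w) {
      off <- tpos - cum
      return(if (strand == "+") blocks$start[i] + off
             else blocks$end[i] - 1L - off)
    }
    cum <- cum + w
  }
  NA_integer_
}

## Concatenate block sequences in transcription order.
assemble_blocks <- function(genome, chrom, strand, blocks) {
  seqs <- vapply(seq_len(nrow(blocks)), function(i)
    genome_fetch(genome, chrom, blocks$start[i], blocks$end[i], strand), "")
  w <- block_widths(blocks)
  list(seq = paste0(seqs, collapse = ""),
       junctions = if (nrow(blocks) > 1) as.integer(cumsum(w)[-length(w)])
                   else integer(0))
}

#' Load canonical transcript models from an Ensembl-dialect GTF
#'
#' One transcript is retained per gene: the one tagged `Ensembl_canonical`
#' when present, otherwise the transcript with the longest summed CDS (ties
#' broken by lexicographic transcript_id). Exons are stored in transcription
#' order with 0-based half-open coordinates. The CDS extent is normalized to
#' include the stop codon: `stop_codon` features extend it when present;
#' otherwise inclusion is resolved against the genome sequence at assembly
#' time.
#'
#' @param path GTF path (plain or gzip) with `exon` and `CDS` features
#'   carrying `gene_id` and `transcript_id` attributes.
#' @return Named list (by `gene_id`) of transcript models, class
#'   `"canonical_annotation"`. Genes whose selected transcript has no CDS are
#'   kept but flagged `has_cds = FALSE` (non-processable); their ids are in
#'   the `non_processable` attribute.
#' @export
load_canonical_annotation <- function(path) {
  if (!file.exists(path)) stop("GTF not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("malformed GTF: ", conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id) || is.null(md$transcript_id))
    stop("GTF lacks gene_id/transcript_id attributes")

  ## rtracklayer keeps only one value of the repeated `tag` attribute, so
  ## scan raw lines for the canonical tag as well.
  canonical_ids <- character(0)
  lns <- readLines(path, warn = FALSE)
  hit <- grepl("Ensembl_canonical", lns, fixed = TRUE)
  if (any(hit)) {
    m <- regmatches(lns[hit], regexpr('transcript_id "[^"]+"', lns[hit]))
    canonical_ids <- unique(sub('transcript_id "([^"]+)"', "\\1", m))
  }
  if (!is.null(md$tag))
    canonical_ids <- union(canonical_ids,
                           unique(md$transcript_id[!is.na(md$tag) &
                                                     md$tag == "Ensembl_canonical"]))

  keep <- md$type %in% c("exon", "CDS", "stop_codon")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  feat <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    stringsAsFactors = FALSE
  )

  models <- list()
  non_processable <- character(0)
  for (gid in unique(feat$gene_id)) {
    gf <- feat[feat$gene_id == gid, , drop = FALSE]
    txs <- sort(unique(gf$transcript_id))
    tx_has_exon <- vapply(txs, function(t)
      any(gf$type == "exon" & gf$transcript_id == t), TRUE)
    if (!any(tx_has_exon)) {
      warning("gene with zero exons skipped: ", gid)
      next
    }
    txs <- txs[tx_has_exon]
    tagged <- intersect(txs, canonical_ids)
    if (length(tagged)) {
      sel <- tagged[1]
    } else {
      cds_len <- vapply(txs, function(t) {
        cd <- gf[gf$type == "CDS" & gf$transcript_id == t, , drop = FALSE]
        sum(cd$end - cd$start)
      }, 0)
      sel <- txs[order(-cds_len, txs)][1]
    }
    tf <- gf[gf$transcript_id == sel, , drop = FALSE]
    ex <- tf[tf$type == "exon", c("start", "end"), drop = FALSE]
    strand <- tf$strand[1]
    ex <- ex[order(ex$start, decreasing = (strand == "-")), , drop = FALSE]
    rownames(ex) <- NULL
    if (nrow(ex) > 1) {
      srt <- sort(ex$start)
      ends <- ex$end[order(ex$start)]
      if (any(srt[-1] < ends[-length(ends)]))
        stop("overlapping exons in transcript ", sel)
    }
    cds <- tf[tf$type == "CDS", , drop = FALSE]
    stopc <- tf[tf$type == "stop_codon", , drop = FALSE]
    has_cds <- nrow(cds) > 0
    cds_g_start <- cds_g_end <- NA_integer_
    if (has_cds) {
      cds_g_start <- min(c(cds$start, stopc$start))
      cds_g_end <- max(c(cds$end, stopc$end))
    } else {
      non_processable <- c(non_processable, gid)
    }
    models[[gid]] <- list(
      gene_id = gid, transcript_id = sel, chrom = tf$chrom[1], strand = strand,
      exons = ex, cds_g_start = cds_g_start, cds_g_end = cds_g_end,
      has_cds = has_cds, has_stop_feature = nrow(stopc) > 0,
      canonical = sel %in% canonical_ids
    )
  }
  structure(models, class = "canonical_annotation",
            non_processable = non_processable)
}

#' Assemble the unmodified mature transcript of a transcript model
#'
#' Concatenates exon sequences in transcription order (reverse-complemented
#' for minus-strand genes), records exon-exon junction positions (transcript
#' coordinate of the first base of each downstream exon), and maps the start
#' codon and stop codon into transcript coordinates. Both GTF stop dialects
#' are accepted: if the annotated CDS extent does not end in a stop codon,
#' the next codon is checked (CDS-excludes-stop dialect).
#'
#' @param genome DNAStringSet from [load_genome()].
#' @param tx A transcript model from [load_canonical_annotation()].
#' @return A mature-transcript list with elements `seq`, `junctions`,
#'   `cds_offset`, `stop_offset` (transcript coordinate of the stop codon's
#'   first base), genomic anchor positions of the start/stop codons, and
#'   provenance fields.
#' @export
assemble_mature <- function(genome, tx) {
  if (!isTRUE(tx$has_cds)) stop("transcript has no CDS: ", tx$transcript_id)
  asm <- assemble_blocks(genome, tx$chrom, tx$strand, tx$exons)
  n <- nchar(asm$seq)

  start_first_g <- if (tx$strand == "+") tx$cds_g_start else tx$cds_g_end - 1L
  cds_last_g <- if (tx$strand == "+") tx$cds_g_end - 1L else tx$cds_g_start
  cds_offset <- genomic_to_tx(tx$exons, tx$strand, start_first_g)
  cds_last_tx <- genomic_to_tx(tx$exons, tx$strand, cds_last_g)
  if (is.na(cds_offset) || is.na(cds_last_tx))
    stop("CDS positions fall outside exons for ", tx$transcript_id)

  codon_at <- function(p) {
    if (is.na(p) || p < 0 || p + 3 > n) return(NA_character_)
    substr(asm$seq, p + 1, p + 3)
  }
  stops <- c("TAA", "TAG", "TGA")
  stop_offset <- NA_integer_
  cand1 <- cds_last_tx - 2L          # CDS extent already includes the stop
  cand2 <- cds_last_tx + 1L          # stop codon follows the CDS extent
  if (!is.na(codon_at(cand1)) && codon_at(cand1) %in% stops &&
      (cand1 - cds_offset) %% 3 == 0) {
    stop_offset <- cand1
  } else if (!is.na(codon_at(cand2)) && codon_at(cand2) %in% stops &&
             (cand2 - cds_offset) %% 3 == 0) {
    stop_offset <- cand2
  } else {
    ## fall back to the first in-frame stop downstream of the start
    p <- cds_offset
    while (p + 3 <= n) {
      if (codon_at(p) %in% stops) { stop_offset <- p; break }
      p <- p + 3L
    }
  }

  g_of <- function(tp) vapply(tp, function(q)
    tx_to_genomic(tx$exons, tx$strand, q), NA_integer_)
  list(
    seq = asm$seq, junctions = asm$junctions,
    cds_offset = cds_offset, stop_offset = stop_offset,
    start_g = g_of(cds_offset + 0:2),
    stop_g = if (!is.na(stop_offset)) g_of(stop_offset + 0:2) else rep(NA_integer_, 3),
    gene_id = tx$gene_id, transcript_id = tx$transcript_id,
    chrom = tx$chrom, strand = tx$strand, blocks = tx$exons,
    stop_is_normal = TRUE, start_lost = FALSE, cds_changed = FALSE,
    net_length_change = 0L, note = NA_character_
  )
}
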
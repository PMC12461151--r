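## Transcript surgery: apply one splicing event (ES/CE, RI, AA, AD) to the
## canonical transcript model, producing the event-modified mature transcript.

not_on_canonical <- function(msg) {
  stop(structure(class = c("notOnCanonical", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Locate a splicing event on a canonical transcript
#'
#' Determines which exon or intron the event modifies and how:
#' * `CE` must match one internal exon exactly (terminal exons belong to
#'   AF/AL/TS/TE territory and are rejected);
#' * `RI` must span an intron between consecutive exons, given either as the
#'   bare intron interval or as the exon-intron-exon span;
#' * `AA`/`AD` must share the fixed exon edge (donor side for AA, acceptor
#'   side for AD) with an annotated exon, the other boundary defining the
#'   shifted splice site.
#'
#' @param event One event (single-row data.frame or list) with fields
#'   `gene_id`, `chrom`, `start`, `end`, `event_type`.
#' @param tx Transcript model from [load_canonical_annotation()].
#' @return A placement list with elements `kind` (`exact_exon`,
#'   `intron_between_exons`, `acceptor_shift`, `donor_shift`), the target
#'   exon/intron index, the modified block list `new_blocks`,
#'   `net_length_change`, and the edit interval `edit_a`/`edit_b` in original
#'   transcript coordinates (`edit_a == edit_b` for pure insertions).
#'   Unplaceable events raise a `notOnCanonical` condition.
#' @export
locate_event <- function(event, tx) {
  ev <- as.list(event)
  if (!identical(as.character(ev$gene_id), tx$gene_id))
    stop("event gene_id does not match transcript model")
  if (!identical(as.character(ev$chrom), tx$chrom))
    not_on_canonical("event chromosome does not match annotation")
  blocks <- tx$exons
  n <- nrow(blocks)
  w <- block_widths(blocks)
  cumw <- cumsum(w)
  gs <- as.integer(ev$start); ge <- as.integer(ev$end)
  type <- as.character(ev$event_type)
  plus <- tx$strand == "+"

  if (type == "CE") {
    idx <- which(blocks$start == gs & blocks$end == ge)
    if (!length(idx)) not_on_canonical("CE coordinate matches no exon exactly")
    idx <- idx[1]
    if (idx == 1L || idx == n)
      not_on_canonical("CE matches a terminal exon (AF/AL/TS/TE territory)")
    new_blocks <- blocks[-idx, , drop = FALSE]
    rownames(new_blocks) <- NULL
    a <- if (idx == 1) 0L else cumw[idx - 1]
    return(list(kind = "exact_exon", exon_index = idx,
                new_blocks = new_blocks,
                net_length_change = -w[idx],
                edit_a = a, edit_b = a + w[idx],
                gene_id = tx$gene_id, event_type = type))
  }

  if (type == "RI") {
    if (n < 2) not_on_canonical("single-exon transcript has no intron")
    for (i in seq_len(n - 1)) {
      aB <- blocks[i, ]; bB <- blocks[i + 1, ]
      gap <- if (plus) c(aB$end, bB$start) else c(bB$end, aB$start)
      span <- c(min(aB$start, bB$start), max(aB$end, bB$end))
      if ((gs == gap[1] && ge == gap[2]) || (gs == span[1] && ge == span[2])) {
        merged <- data.frame(start = min(aB$start, bB$start),
                             end = max(aB$end, bB$end))
        new_blocks <- rbind(if (i > 1) blocks[seq_len(i - 1), ], merged,
                            if (i + 1 < n) blocks[seq(i + 2, n), ])
        rownames(new_blocks) <- NULL
        return(list(kind = "intron_between_exons", intron_index = i,
                    new_blocks = new_blocks,
                    net_length_change = gap[2] - gap[1],
                    edit_a = cumw[i], edit_b = cumw[i],
                    gene_id = tx$gene_id, event_type = type))
      }
    }
    not_on_canonical("RI coordinate spans no annotated intron")
  }

  if (type %in% c("AA", "AD")) {
    ## the fixed (shared) edge is the exon edge NOT being moved
    for (j in seq_len(n)) {
      s <- blocks$start[j]; e <- blocks$end[j]
      if (type == "AA") {
        if (j == 1L) next                       # first exon has no acceptor
        fixed_ok <- if (plus) ge == e else gs == s
        if (!fixed_ok) next
        new <- if (plus) c(gs, e) else c(s, ge)
        ## shifted acceptor must stay clear of the upstream exon
        lim_ok <- if (plus) gs >= blocks$end[j - 1] else ge <= blocks$start[j - 1]
        if (!lim_ok || new[1] >= new[2]) next
        kind <- "acceptor_shift"
      } else {
        if (j == n) next                        # last exon has no donor
        fixed_ok <- if (plus) gs == s else ge == e
        if (!fixed_ok) next
        new <- if (plus) c(s, ge) else c(gs, e)
        lim_ok <- if (plus) ge <= blocks$start[j + 1] else gs >= blocks$end[j + 1]
        if (!lim_ok || new[1] >= new[2]) next
        kind <- "donor_shift"
      }
      net <- (new[2] - new[1]) - w[j]
      new_blocks <- blocks
      new_blocks$start[j] <- new[1]; new_blocks$end[j] <- new[2]
      ## edit interval in original transcript coordinates
      edge <- if (type == "AA") (if (j == 1) 0L else cumw[j - 1]) else cumw[j]
      if (net >= 0) { a <- edge; b <- edge } else {
        if (type == "AA") { a <- edge; b <- edge - net }
        else { a <- edge + net; b <- edge }
      }
      return(list(kind = kind, exon_index = j, new_blocks = new_blocks,
                  net_length_change = net, edit_a = a, edit_b = b,
                  gene_id = tx$gene_id, event_type = type))
    }
    not_on_canonical(paste0(type, " coordinate shares no exon edge"))
  }

  stop(structure(class = c("unsupportedType", "error", "condition"),
                 list(message = paste0("event type out of surgery scope: ", type),
                      call = sys.call())))
}

#' Apply a located splicing event to the transcript
#'
#' Rebuilds the mature transcript from the modified exon block list and
#' remaps the annotated start and stop codons into the new coordinates.
#' When the start codon no longer maps contiguously the transcript is
#' flagged `start_lost` (the NMD call is then skipped). When the stop codon
#' no longer maps, or maps out of frame, `stop_is_normal` is `FALSE` and
#' every in-frame stop downstream of the start is a candidate PTC.
#'
#' @param genome DNAStringSet from [load_genome()].
#' @param tx Transcript model.
#' @param placement Result of [locate_event()].
#' @param orig Optional pre-assembled unmodified mature transcript
#'   ([assemble_mature()]); assembled on the fly when omitted.
#' @return Modified mature-transcript list (same shape as
#'   [assemble_mature()]), with `net_length_change`, `cds_changed`,
#'   `start_lost`, `stop_is_normal` and `note` filled in.
#' @export
apply_event <- function(genome, tx, placement, orig = NULL) {
  if (is.null(orig)) orig <- assemble_mature(genome, tx)
  blocks_m <- placement$new_blocks
  if (is.null(blocks_m) || nrow(blocks_m) == 0L)
    stop("surgery produced an empty transcript")
  asm <- assemble_blocks(genome, tx$chrom, tx$strand, blocks_m)

  if (nchar(asm$seq) != nchar(orig$seq) + placement$net_length_change)
    stop("internal error: length change inconsistent with placement")

  map3 <- function(gpos3) {
    tp <- vapply(gpos3, function(g) genomic_to_tx(blocks_m, tx$strand, g),
                 NA_integer_)
    if (anyNA(tp) || !all(diff(tp) == 1L)) NULL else tp
  }
  start_tp <- map3(orig$start_g)
  start_lost <- is.null(start_tp)
  cds_offset <- if (start_lost) NA_integer_ else start_tp[1]

  note <- NA_character_
  stop_offset <- NA_integer_
  stop_is_normal <- FALSE
  stop_tp <- if (!anyNA(orig$stop_g)) map3(orig$stop_g) else NULL
  if (!is.null(stop_tp)) {
    stop_offset <- stop_tp[1]
    stop_is_normal <- !start_lost && ((stop_offset - cds_offset) %% 3 == 0)
  } else {
    note <- if (placement$kind == "exact_exon") "StopExonSkipped" else "StopDisrupted"
  }

  ## did the edit touch any base of the original CDS (start..stop codon)?
  o_cds <- orig$cds_offset
  o_stop_end <- if (!is.na(orig$stop_offset)) orig$stop_offset + 3L
                else nchar(orig$seq)
  a <- placement$edit_a; b <- placement$edit_b
  cds_changed <- if (a == b) (a > o_cds && a < o_stop_end)   # insertion point
                 else (b > o_cds && a < o_stop_end)          # deletion overlap
  if (start_lost) cds_changed <- TRUE

  list(
    seq = asm$seq, junctions = asm$junctions,
    cds_offset = cds_offset, stop_offset = stop_offset,
    start_g = orig$start_g, stop_g = orig$stop_g,
    gene_id = tx$gene_id, transcript_id = tx$transcript_id,
    chrom = tx$chrom, strand = tx$strand, blocks = blocks_m,
    stop_is_normal = stop_is_normal, start_lost = start_lost,
    cds_changed = cds_changed,
    net_length_change = placement$net_length_change, note = note
  )
}
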
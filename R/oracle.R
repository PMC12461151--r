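## Independent brute-force NMD oracle.
##
## A deliberately naive re-implementation used only for validation: it
## performs literal string surgery on the exon chain, builds a per-base
## genomic-position vector, translates codon-by-codon from the start codon,
## and measures the first-stop-to-last-junction distance. It shares no code
## with the surgery or classification modules.

oracle_rc <- function(s)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")

#' Brute-force NMD call for one event
#'
#' @param genome DNAStringSet (or named character vector) of chromosomes.
#' @param annotation Canonical annotation from [load_canonical_annotation()].
#' @param event One event row (`gene_id`, `chrom`, `start`, `end`,
#'   `event_type`).
#' @param threshold PTC-to-final-junction rule threshold in nt.
#' @return List with `nmd` (`TRUE`/`FALSE`, `NA` for skipped events),
#'   `first_stop` (transcript coordinate of the premature terminator or
#'   `NA`) and `last_junction`.
#' @export
oracle_nmd <- function(genome, annotation, event, threshold = 50) {
  ev <- as.list(event)
  skip <- list(nmd = NA, first_stop = NA_integer_, last_junction = NA_integer_)
  if (!as.character(ev$event_type) %in% c("CE", "RI", "AA", "AD")) return(skip)
  tx <- annotation[[as.character(ev$gene_id)]]
  if (is.null(tx) || !isTRUE(tx$has_cds)) return(skip)
  if (!identical(as.character(ev$chrom), tx$chrom)) return(skip)
  chrseq <- as.character(genome[[tx$chrom]])
  ex <- tx$exons
  n <- nrow(ex)
  plus <- tx$strand == "+"
  gs <- ev$start; ge <- ev$end
  type <- as.character(ev$event_type)

  ## --- place the event on the exon chain (naive search) ------------------
  pieces <- lapply(seq_len(n), function(i) c(ex$start[i], ex$end[i]))
  placed <- FALSE
  if (type == "CE") {
    for (i in seq_len(n))
      if (pieces[[i]][1] == gs && pieces[[i]][2] == ge) {
        if (i == 1 || i == n) return(skip)
        pieces[[i]] <- NULL; placed <- TRUE; break
      }
  } else if (type == "RI") {
    for (i in seq_len(n - 1)) {
      gap <- c(min(ex$end[i], ex$end[i + 1]), max(ex$start[i], ex$start[i + 1]))
      span <- c(min(ex$start[i], ex$start[i + 1]),
                max(ex$end[i], ex$end[i + 1]))
      if ((gs == gap[1] && ge == gap[2]) || (gs == span[1] && ge == span[2])) {
        pieces[[i]] <- span
        pieces[[i + 1]] <- NULL
        placed <- TRUE; break
      }
    }
  } else if (type == "AA") {
    for (i in seq_len(n)[-1]) {
      if (plus && ge == ex$end[i] && gs < ge && gs >= ex$end[i - 1]) {
        pieces[[i]] <- c(gs, ge); placed <- TRUE; break
      }
      if (!plus && gs == ex$start[i] && gs < ge && ge <= ex$start[i - 1]) {
        pieces[[i]] <- c(gs, ge); placed <- TRUE; break
      }
    }
  } else if (type == "AD") {
    for (i in seq_len(n - 1)) {
      if (plus && gs == ex$start[i] && gs < ge && ge <= ex$start[i + 1]) {
        pieces[[i]] <- c(gs, ge); placed <- TRUE; break
      }
      if (!plus && ge == ex$end[i] && gs < ge && gs >= ex$end[i + 1]) {
        pieces[[i]] <- c(gs, ge); placed <- TRUE; break
      }
    }
  }
  if (!placed) return(skip)

  ## --- literal reconstruction --------------------------------------------
  seq_of <- function(p) {
    s <- substr(chrseq, p[1] + 1, p[2])
    if (plus) s else oracle_rc(s)
  }
  pos_of <- function(p) if (plus) seq(p[1], p[2] - 1) else seq(p[2] - 1, p[1])
  mature <- paste0(vapply(pieces, seq_of, ""), collapse = "")
  posvec <- unlist(lapply(pieces, pos_of))
  w <- vapply(pieces, function(p) p[2] - p[1], 0)
  junctions <- if (length(w) > 1) cumsum(w)[-length(w)] else numeric(0)
  last_junction <- if (length(junctions)) junctions[length(junctions)]
                   else NA_integer_

  ## --- start and annotated stop, located independently --------------------
  unmod_pos <- unlist(lapply(seq_len(n), function(i)
    pos_of(c(ex$start[i], ex$end[i]))))
  unmod_seq <- paste0(vapply(seq_len(n), function(i)
    seq_of(c(ex$start[i], ex$end[i])), ""), collapse = "")
  start_g <- if (plus) tx$cds_g_start + 0:2 else tx$cds_g_end - 1 - 0:2
  cds_last_g <- if (plus) tx$cds_g_end - 1 else tx$cds_g_start
  u0 <- match(start_g[1], unmod_pos) - 1L
  clast0 <- match(cds_last_g, unmod_pos) - 1L
  if (is.na(u0) || is.na(clast0)) return(skip)
  stops3 <- c("TAA", "TAG", "TGA")
  codon_u <- function(p) substr(unmod_seq, p + 1, p + 3)
  stop0 <- NA_integer_
  for (cand in c(clast0 - 2L, clast0 + 1L))
    if (cand >= 0 && cand + 3 <= nchar(unmod_seq) &&
        codon_u(cand) %in% stops3 && (cand - u0) %% 3 == 0) {
      stop0 <- cand; break
    }
  if (is.na(stop0)) {
    p <- u0
    while (p + 3 <= nchar(unmod_seq)) {
      if (codon_u(p) %in% stops3) { stop0 <- p; break }
      p <- p + 3L
    }
  }
  stop_g <- if (!is.na(stop0)) unmod_pos[stop0 + 1:3] else NULL

  ## --- translate the modified transcript ----------------------------------
  st_idx <- match(start_g, posvec)
  if (anyNA(st_idx) || !all(diff(st_idx) == 1L))
    return(skip)                                    # start lost: call skipped
  start0 <- st_idx[1] - 1L
  normal0 <- NA_integer_
  if (!is.null(stop_g)) {
    sp_idx <- match(stop_g, posvec)
    if (!anyNA(sp_idx) && all(diff(sp_idx) == 1L) &&
        ((sp_idx[1] - 1L - start0) %% 3 == 0))
      normal0 <- sp_idx[1] - 1L
  }
  terminator <- NA_integer_
  p <- start0
  while (p + 3 <= nchar(mature)) {
    if (substr(mature, p + 1, p + 3) %in% stops3) { terminator <- p; break }
    p <- p + 3L
  }
  premature <- !is.na(terminator) &&
    !(!is.na(normal0) && terminator == normal0)
  first_stop <- if (premature) terminator else NA_integer_
  nmd <- premature && !is.na(last_junction) &&
    (last_junction - (terminator + 2) >= threshold) &&
    terminator < last_junction
  list(nmd = nmd, first_stop = first_stop,
       last_junction = as.integer(last_junction))
}

#' Oracle agreement over a full event set
#'
#' Runs [run_pipeline()] and [oracle_nmd()] over the same events and reports
#' the fraction of events on which the NMD calls agree (skips must agree as
#' `NA` on both sides).
#'
#' @param events,annotation,genome,config As for [run_pipeline()].
#' @return List with `agreement` (fraction in \[0,1\]), `n`, and the
#'   comparison data.frame.
#' @export
oracle_agreement <- function(events, annotation, genome,
                             config = nmd_config()) {
  res <- run_pipeline(events, annotation, genome, config)
  orc <- vapply(seq_len(nrow(events)), function(i)
    oracle_nmd(genome, annotation, events[i, ],
               config$ptc_junction_threshold_nt)$nmd, NA)
  same <- (is.na(res$nmd) & is.na(orc)) |
    (!is.na(res$nmd) & !is.na(orc) & res$nmd == orc)
  list(agreement = mean(same), n = nrow(events),
       table = data.frame(gene_id = res$gene_id, pipeline = res$nmd,
                          oracle = orc, reason = res$reason,
                          agree = same, stringsAsFactors = FALSE))
}
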
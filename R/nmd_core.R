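#' NMD classification settings
#'
#' @param ptc_junction_threshold_nt Minimum distance (nt) from the last base
#'   of a PTC to the final exon-exon junction for an NMD call. The canonical
#'   rule places the boundary at 50-55 nt; the default is the conservative
#'   edge, 50.
#' @param stop_codons Stop-codon set.
#' @param validate_threshold When `TRUE` (default) the threshold must lie in
#'   the canonical 50-55 band; set `FALSE` to explore other values.
#' @return A config list.
#' @export
nmd_config <- function(ptc_junction_threshold_nt = 50L,
                       stop_codons = c("TAA", "TAG", "TGA"),
                       validate_threshold = TRUE) {
  thr <- as.integer(ptc_junction_threshold_nt)
  if (validate_threshold && (thr < 50L || thr > 55L))
    stop("ptc_junction_threshold_nt outside the canonical 50-55 band; ",
         "pass validate_threshold = FALSE to override")
  list(ptc_junction_threshold_nt = thr, stop_codons = stop_codons)
}

#' Predicted reading frame of an event-modified transcript
#'
#' Frame 0 means the annotated reading frame is preserved downstream of the
#' event (including events that do not touch the CDS); frames 1 and 2 are the
#' two frameshifts, `net_length_change mod 3`.
#'
#' @param placement Placement from [locate_event()].
#' @param mature Modified mature transcript from [apply_event()].
#' @return Integer frame in `{0, 1, 2}`.
#' @export
predicted_frame <- function(placement, mature) {
  if (!isTRUE(mature$cds_changed)) return(0L)
  as.integer(placement$net_length_change %% 3)
}

#' Enumerate stop codons per frame
#'
#' For each frame `f` in `{0,1,2}`, returns the ordered transcript
#' coordinates `p >= cds_offset` with `(p - cds_offset) mod 3 == f` whose
#' codon is a stop. Frame 0 is the translation frame of the (possibly
#' modified) transcript; positions at or beyond the mapped annotated
#' terminator are excluded from its list, so frame-0 entries are premature by
#' construction. Codons containing `N` are never stops.
#'
#' @param mature Mature transcript (modified or not).
#' @param config [nmd_config()].
#' @return List of integer vectors named `"0"`, `"1"`, `"2"`.
#' @export
scan_ptcs <- function(mature, config = nmd_config()) {
  if (is.na(mature$cds_offset)) stop("transcript has no start codon")
  s <- mature$seq
  if (grepl("[^ACGTN]", s)) stop("sequence contains non-ACGTN symbols")
  n <- nchar(s)
  cds <- mature$cds_offset
  out <- list(`0` = integer(0), `1` = integer(0), `2` = integer(0))
  if (n - cds < 3) return(out)
  pos <- cds:(n - 3L)
  codons <- substring(s, pos + 1L, pos + 3L)
  hits <- pos[codons %in% config$stop_codons]
  fr <- (hits - cds) %% 3
  for (f in 0:2) {
    p <- hits[fr == f]
    if (f == 0L && isTRUE(mature$stop_is_normal) && !is.na(mature$stop_offset))
      p <- p[p < mature$stop_offset]
    out[[as.character(f)]] <- as.integer(p)
  }
  out
}

#' Call NMD by the premature-stop / final-exon-junction rule
#'
#' Translation of the modified transcript terminates at the first frame-0
#' stop downstream of the start codon; that stop is premature unless it is
#' the mapped annotated terminator. NMD is called `TRUE` when a premature
#' terminator exists, the transcript retains at least one exon-exon
#' junction, and the distance from the last base of the PTC to the final
#' junction is at least the configured threshold. All degenerate cases map
#' to reason codes rather than errors.
#'
#' @param mature Modified mature transcript.
#' @param frame Predicted frame from [predicted_frame()].
#' @param ptcs Per-frame stop lists from [scan_ptcs()].
#' @param config [nmd_config()].
#' @return One-row data.frame with `predicted_frame`, per-frame PTC counts,
#'   `first_ptc`, `last_junction`, `distance_nt`, `nmd` and `reason`.
#' @export
classify_nmd <- function(mature, frame, ptcs, config = nmd_config()) {
  thr <- config$ptc_junction_threshold_nt
  counts <- vapply(ptcs, length, 1L)
  first_ptc <- if (length(ptcs[["0"]])) ptcs[["0"]][1] else NA_integer_
  last_junction <- if (length(mature$junctions))
    mature$junctions[length(mature$junctions)] else NA_integer_

  if (isTRUE(mature$start_lost)) {
    nmd <- NA; reason <- "START_LOST"; d <- NA_integer_
  } else if (is.na(first_ptc)) {
    nmd <- FALSE; d <- NA_integer_
    reason <- if (!isTRUE(mature$cds_changed)) "NO_CDS_CHANGE" else "NO_PTC"
  } else if (is.na(last_junction)) {
    nmd <- FALSE; reason <- "NO_JUNCTION"; d <- NA_integer_
  } else {
    d <- last_junction - (first_ptc + 2L)
    if (first_ptc >= last_junction) {
      nmd <- FALSE; reason <- "PTC_IN_LAST_EXON"
    } else if (d >= thr) {
      nmd <- TRUE; reason <- "PTC_UPSTREAM_RULE"
    } else {
      nmd <- FALSE; reason <- "PTC_TOO_CLOSE"
    }
  }
  data.frame(
    predicted_frame = if (isTRUE(mature$start_lost)) NA_integer_ else as.integer(frame),
    ptc_count_f0 = counts[["0"]], ptc_count_f1 = counts[["1"]],
    ptc_count_f2 = counts[["2"]],
    first_ptc = first_ptc, last_junction = last_junction, distance_nt = d,
    nmd = nmd, reason = reason, note = mature$note,
    stringsAsFactors = FALSE
  )
}

skip_row <- function(ev, reason) {
  data.frame(gene_id = ev$gene_id, node = ev$node,
             event_type = report_type(ev$event_type),
             predicted_frame = NA_integer_, ptc_count_f0 = NA_integer_,
             ptc_count_f1 = NA_integer_, ptc_count_f2 = NA_integer_,
             first_ptc = NA_integer_, last_junction = NA_integer_,
             distance_nt = NA_integer_, nmd = NA, reason = reason,
             note = NA_character_,
             delta_psi = ev$delta_psi, probability = ev$probability,
             stringsAsFactors = FALSE)
}

#' Run the full NMD-prediction pipeline over a set of splicing events
#'
#' For every in-scope event (ES/CE, RI, AA, AD on a canonical transcript)
#' the canonical mature transcript is assembled, the event applied, the
#' frame predicted, PTCs enumerated and the NMD call made. Out-of-scope or
#' unplaceable events appear in the output with a skip reason and `nmd = NA`.
#'
#' @param events Event data.frame from [parse_diff_table()].
#' @param annotation [load_canonical_annotation()] result.
#' @param genome [load_genome()] result.
#' @param config [nmd_config()].
#' @return data.frame with one row per event: `gene_id`, `node`,
#'   `event_type` (CE reported as ES), `predicted_frame`, `ptc_count_f0..f2`,
#'   `first_ptc`, `last_junction`, `distance_nt`, `nmd`, `reason`, `note`,
#'   `delta_psi`, `probability`. Stage counts (parsed/processed/skipped by
#'   reason) are attached as the `stage_counts` attribute.
#' @export
run_pipeline <- function(events, annotation, genome, config = nmd_config()) {
  cols <- names(skip_row(list(gene_id = "g", node = 1L, event_type = "CE",
                              delta_psi = 0, probability = 0), "X"))
  if (nrow(events) == 0L) {
    out <- skip_row(list(gene_id = "g", node = 1L, event_type = "CE",
                         delta_psi = 0, probability = 0), "X")[0, ]
    attr(out, "stage_counts") <- c(parsed = 0L, processed = 0L, skipped = 0L)
    return(out)
  }

  in_scope <- events$event_type %in% SPLICING_TYPES
  known_chrom <- events$chrom %in% names(genome)
  if (any(in_scope) && !any(known_chrom[in_scope]))
    stop("no event chromosome matches the genome: check that the FASTA and ",
         "the event table use the same chromosome naming (e.g. 'chr1' vs '1')")

  cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (!ev$event_type %in% SPLICING_TYPES) {
      rows[[i]] <- skip_row(ev, "UNSUPPORTED_TYPE"); next
    }
    tx <- annotation[[ev$gene_id]]
    if (is.null(tx) || !isTRUE(tx$has_cds)) {
      rows[[i]] <- skip_row(ev, "NOT_ON_CANONICAL"); next
    }
    res <- tryCatch({
      orig <- if (!is.null(cache[[ev$gene_id]])) cache[[ev$gene_id]]
              else cache[[ev$gene_id]] <- assemble_mature(genome, tx)
      placement <- locate_event(ev, tx)
      mature <- apply_event(genome, tx, placement, orig)
      frame <- if (mature$start_lost) NA_integer_
               else predicted_frame(placement, mature)
      cls <- if (mature$start_lost)
        classify_nmd(mature, NA_integer_, list(`0` = integer(0),
                                               `1` = integer(0),
                                               `2` = integer(0)), config)
      else classify_nmd(mature, frame, scan_ptcs(mature, config), config)
      cbind(data.frame(gene_id = ev$gene_id, node = ev$node,
                       event_type = report_type(ev$event_type),
                       stringsAsFactors = FALSE),
            cls,
            data.frame(delta_psi = ev$delta_psi, probability = ev$probability))
    },
    notOnCanonical = function(e) skip_row(ev, "NOT_ON_CANONICAL"))
    rows[[i]] <- res[, cols]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  skipped <- table(out$reason[out$reason %in% SKIP_REASONS])
  attr(out, "stage_counts") <- c(
    parsed = nrow(events),
    processed = sum(out$reason %in% PROCESSED_REASONS),
    skipped = sum(out$reason %in% SKIP_REASONS),
    stats::setNames(as.integer(skipped), names(skipped))
  )
  out
}

#' Write NMD results as TSV
#'
#' Stable column order; logicals rendered as `true`/`false`.
#'
#' @param results [run_pipeline()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nmd_results <- function(results, path) {
  out <- results
  out$nmd <- ifelse(is.na(out$nmd), "NA", ifelse(out$nmd, "true", "false"))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read back an NMD results TSV
#'
#' @param path TSV written by [write_nmd_results()].
#' @return data.frame in the [run_pipeline()] layout.
#' @export
read_nmd_results <- function(path) {
  res <- data.table::fread(path, sep = "\t", data.table = FALSE,
                           na.strings = "NA")
  if (!is.logical(res$nmd))
    res$nmd <- c(true = TRUE, false = FALSE)[tolower(as.character(res$nmd))]
  res
}
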
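#' Parse a Whippet differential-splicing table
#'
#' Reads a Whippet `.diff` TSV (plain or gzip) and returns one row per
#' quantifiable splicing event. The 1-based inclusive `Coord` column is
#' converted to 0-based half-open `start`/`end`. Rows whose psi columns are
#' `NA` (unquantifiable nodes) are dropped; their count is kept in the
#' `n_dropped` attribute and reported with a message.
#'
#' @param path Path to a tab-separated file with header columns
#'   `Gene, Node, Coord, Strand, Type, Psi_A, Psi_B, DeltaPsi, Probability,
#'   Complexity, Entropy`; `Coord` is formatted `"chrom:start-end"`.
#' @return A data.frame of splice events with columns `gene_id`, `node`,
#'   `chrom`, `start`, `end`, `strand`, `event_type`, `psi_a`, `psi_b`,
#'   `delta_psi`, `probability`, `complexity`, `entropy`.
#' @export
parse_diff_table <- function(path) {
  if (!file.exists(path)) stop("diff table not found: ", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           na.strings = c("NA", ""), data.table = FALSE,
                           colClasses = list(character = "Coord"))
  required <- c("Gene", "Node", "Coord", "Strand", "Type", "Psi_A", "Psi_B",
                "DeltaPsi", "Probability", "Complexity", "Entropy")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("diff table is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) return(empty_events())

  bad_type <- !(raw$Type %in% EVENT_TYPES)
  if (any(bad_type))
    stop("unknown event Type '", raw$Type[which(bad_type)[1]],
         "' at data line ", which(bad_type)[1])

  m <- regmatches(raw$Coord, regexec("^([^:]+):([0-9]+)-([0-9]+)$", raw$Coord))
  bad_coord <- vapply(m, length, 1L) != 4L
  if (any(bad_coord))
    stop("malformed Coord '", raw$Coord[which(bad_coord)[1]],
         "' at data line ", which(bad_coord)[1])
  chrom <- vapply(m, `[`, "", 2L)
  start1 <- as.numeric(vapply(m, `[`, "", 3L))
  end1 <- as.numeric(vapply(m, `[`, "", 4L))

  if (!all(raw$Strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")

  events <- data.frame(
    gene_id = as.character(raw$Gene),
    node = as.integer(raw$Node),
    chrom = chrom,
    start = as.integer(start1 - 1),   # to 0-based half-open
    end = as.integer(end1),
    strand = raw$Strand,
    event_type = raw$Type,
    psi_a = as.numeric(raw$Psi_A),
    psi_b = as.numeric(raw$Psi_B),
    delta_psi = as.numeric(raw$DeltaPsi),
    probability = as.numeric(raw$Probability),
    complexity = as.character(raw$Complexity),
    entropy = as.numeric(raw$Entropy),
    stringsAsFactors = FALSE
  )
  if (any(events$start >= events$end))
    stop("Coord with start >= end at data line ",
         which(events$start >= events$end)[1])

  quantified <- !(is.na(events$psi_a) | is.na(events$psi_b) |
                    is.na(events$delta_psi))
  n_dropped <- sum(!quantified)
  if (n_dropped > 0L)
    message("parse_diff_table: dropped ", n_dropped, " row(s) with NA psi")
  events <- events[quantified, , drop = FALSE]
  rownames(events) <- NULL

  ok <- events$probability >= 0 & events$probability <= 1 &
    events$psi_a >= 0 & events$psi_a <= 1 &
    events$psi_b >= 0 & events$psi_b <= 1 &
    events$delta_psi >= -1 & events$delta_psi <= 1
  if (!all(ok | is.na(ok)))
    stop("psi/probability out of [0,1] bounds at data line ", which(!ok)[1])

  attr(events, "n_dropped") <- n_dropped
  events
}

empty_events <- function() {
  data.frame(gene_id = character(), node = integer(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             event_type = character(), psi_a = numeric(), psi_b = numeric(),
             delta_psi = numeric(), probability = numeric(),
             complexity = character(), entropy = numeric(),
             stringsAsFactors = FALSE)
}

#' Write splice events back in Whippet `.diff` dialect
#'
#' Inverse of [parse_diff_table()]: coordinates are re-expressed as 1-based
#' inclusive `chrom:start-end`.
#'
#' @param events Event data.frame as returned by [parse_diff_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_diff_table <- function(events, path) {
  out <- data.frame(
    Gene = events$gene_id,
    Node = events$node,
    Coord = sprintf("%s:%d-%d", events$chrom, events$start + 1L, events$end),
    Strand = events$strand,
    Type = events$event_type,
    Psi_A = events$psi_a,
    Psi_B = events$psi_b,
    DeltaPsi = events$delta_psi,
    Probability = events$probability,
    Complexity = events$complexity,
    Entropy = events$entropy,
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Filter events by Whippet significance thresholds
#'
#' Retains events with `probability >= prob_min` and
#' `|delta_psi| > abs_dpsi_min` (strict), the thresholds recommended by the
#' Whippet documentation. Row order is preserved.
#'
#' @param events Event data.frame.
#' @param prob_min Minimum posterior probability (inclusive), default 0.9.
#' @param abs_dpsi_min Minimum |DeltaPsi| (exclusive), default 0.1.
#' @return The retained subset of `events`.
#' @export
filter_significant <- function(events, prob_min = 0.9, abs_dpsi_min = 0.1) {
  stopifnot(prob_min >= 0, prob_min <= 1, abs_dpsi_min >= 0, abs_dpsi_min <= 1)
  keep <- events$probability >= prob_min & abs(events$delta_psi) > abs_dpsi_min
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Categorize events into splicing and transcription-related groups
#'
#' Splicing-machinery events are ES (reported name of Whippet's CE nodes),
#' RI, AA and AD; TS, TE, AF and AL are transcription-related (alternative
#' transcription start/end and first/last exon).
#'
#' @param events Event data.frame.
#' @return A list with named integer count vectors `splicing`
#'   (`ES, RI, AA, AD`) and `transcription_related` (`TS, TE, AF, AL`).
#' @export
categorize_events <- function(events) {
  tab <- table(factor(events$event_type, levels = EVENT_TYPES))
  splicing <- c(ES = unname(tab[["CE"]]), RI = unname(tab[["RI"]]),
                AA = unname(tab[["AA"]]), AD = unname(tab[["AD"]]))
  transcription <- c(TS = unname(tab[["TS"]]), TE = unname(tab[["TE"]]),
                     AF = unname(tab[["AF"]]), AL = unname(tab[["AL"]]))
  list(splicing = splicing, transcription_related = transcription)
}

#' Frequencies of the four splicing-group event types
#'
#' Percentages of ES, RI, AA and AD computed over splicing-group events only
#' (transcription-related events are excluded from the denominator).
#'
#' @param events Event data.frame.
#' @return Named numeric vector of percentages over `ES, RI, AA, AD`,
#'   summing to 100 (all `NaN` if there are no splicing-group events).
#' @export
splicing_type_frequencies <- function(events) {
  counts <- categorize_events(events)$splicing
  100 * counts / sum(counts)
}

#' Parse a differential gene-expression table
#'
#' Accepts DESeq2-style column names (`gene_id`/`gene`, `log2FoldChange`/
#' `log2fc`, `padj`).
#'
#' @param path TSV/CSV path.
#' @return data.frame with columns `gene_id`, `log2fc`, `padj`.
#' @export
parse_dge_table <- function(path) {
  raw <- data.table::fread(path, data.table = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(raw))
    if (!length(hit)) stop("DGE table is missing a column among: ",
                           paste(cands, collapse = ", "))
    raw[[hit[1]]]
  }
  out <- data.frame(
    gene_id = as.character(pick(c("gene_id", "gene", "Gene"))),
    log2fc = as.numeric(pick(c("log2FoldChange", "log2fc", "log2FC"))),
    padj = as.numeric(pick(c("padj", "adj_p", "padjust"))),
    stringsAsFactors = FALSE
  )
  bad <- !is.na(out$padj) & (out$padj < 0 | out$padj > 1)
  if (any(bad)) stop("padj outside [0,1] at row ", which(bad)[1])
  out
}
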
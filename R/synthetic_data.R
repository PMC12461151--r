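## Synthetic toy genomes, canonical annotations and Whippet-style event
## tables with known ground-truth NMD labels.
##
## Construction principle: gene bodies are generated over {A,C,G} only, so
## the background contains no stop codon in any frame; every stop codon
## (start-of-CDS ATG guard, the normal terminator, and each designed PTC) is
## planted explicitly at a known transcript position and phase. Truth labels
## are therefore pure arithmetic on the designed coordinates and never
## require running the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_bases <- function(n) sample(c("A", "C", "G"), n, replace = TRUE)

revcomp_chars <- function(v) rev(chartr("ACGTN", "TGCAN", v))

## one designed gene + event + truth record ------------------------------

build_gene <- function(plan) {
  type <- plan$event_type
  scen <- plan$scenario
  thr <- plan$thr
  d <- plan$d %||% NA_integer_
  k <- plan$k %||% 1L
  shift <- plan$shift %||% 0L
  u <- 12L

  a1 <- sample(8:16, 1)
  l1 <- u + 3L * a1
  l2 <- 3L * sample(6:12, 1)
  i1 <- sample(60:120, 1)
  i2 <- sample(60:120, 1)
  i3 <- sample(60:120, 1)
  l3 <- 3L * sample(10:20, 1)
  n_exons <- 4L

  tx_plants <- list()     # list(pos = transcript coord, motif = chars)
  intron_plants <- list() # list(intron = index, off = offset, motif = chars)
  plant_tx <- function(pos, motif)
    tx_plants[[length(tx_plants) + 1]] <<- list(pos = pos, motif = motif)
  plant_intron <- function(idx, off, motif)
    intron_plants[[length(intron_plants) + 1]] <<- list(intron = idx, off = off,
                                                        motif = motif)

  need <- function(ok, why) if (!ok) stop("unsatisfiable design: ", why)
  ptc_run <- function(n) strsplit(strrep("TAA", n), "")[[1]]

  designed_frame <- 0L
  expected_nmd <- NA
  expected_reason <- NA_character_
  designed_d <- NA_integer_
  designed_k <- 0L
  net <- NA_integer_
  ev_type_in <- if (type == "ES") "CE" else type
  ev_sense <- NULL          # filled after layout for most scenarios
  ev_gene_suffix <- ""

  ## scenario-specific geometry -------------------------------------------
  if (scen == "clean") {
    if (type == "ES") { net <- -l2 }
    if (type == "RI") { i2 <- 3L * sample(15:30, 1); net <- i2 }
    if (type %in% c("AA", "AD")) { ext <- 12L; net <- ext }
    expected_nmd <- FALSE; expected_reason <- "NO_PTC"
  } else if (scen == "ptc" || scen == "too_close") {
    designed_d <- as.integer(d)
    designed_k <- as.integer(k)
    if (type == "ES" && isTRUE(plan$junction_route)) {
      ## frame-preserving skip whose new exon1|exon3 junction codon is a stop
      shift <- 0L
      l1 <- l1 + 1L                      # junction phase 1
      l3 <- designed_d + 1L
      need(l3 >= 3, "ES junction-route distance too small")
      designed_k <- 1L
      plant_tx(l1 - 1L, "T")             # exon1 last base
      plant_tx(l1 + l2 - 1L, "C")        # exon2 last base (original safety)
      ## exon2 head + exon3 head: AA completes the junction stop after skip
      plant_tx(l1, "CC")                 # exon2 first two (original safety)
      plant_tx(l1 + l2, "AA")            # exon3 first two
      net <- -l2
    } else if (type == "ES") {
      if (shift == 0L) shift <- sample(1:2, 1)
      l2 <- 3L * sample(6:12, 1) + shift
      delta <- 6L
      l3 <- designed_d + delta + 2L
      need(l3 >= delta + 3L * designed_k, "ES frameshift: exon3 too short for PTCs")
      for (j in seq_len(designed_k))
        plant_tx(l1 + l2 + delta + 3L * (j - 1L), "TAA")
      net <- -l2
    } else {
      ## RI / AA / AD: stops planted inside the inserted segment, which
      ## enters the transcript at the phase-0 point after exon2
      seg <- 3L * (designed_k + 3L) + shift   # inserted length
      l3 <- designed_d + 8L - seg
      need(l3 >= 3, "insertion design: distance too small for PTC count")
      if (type == "RI") {
        i2 <- seg
        for (j in seq_len(designed_k))
          plant_intron(2L, 6L + 3L * (j - 1L), "TAA")
      } else {
        ext <- seg
        i2 <- ext + sample(30:60, 1)
        off0 <- if (type == "AA") i2 - ext else 0L   # segment location in intron2
        for (j in seq_len(designed_k))
          plant_intron(2L, off0 + 6L + 3L * (j - 1L), "TAA")
      }
      net <- seg
    }
    designed_frame <- net %% 3L
    expected_nmd <- designed_d >= thr
    expected_reason <- if (expected_nmd) "PTC_UPSTREAM_RULE" else "PTC_TOO_CLOSE"
  } else if (scen == "last_exon") {
    designed_k <- 1L
    if (shift == 0L) shift <- sample(1:2, 1)
    if (type == "ES") {
      l2 <- 3L * sample(6:12, 1) + shift
      plant_tx(l1 + l2 + l3 + 6L, "TAA")   # exon4, original phase == shift
      net <- -l2
    } else {
      seg <- 3L * 4L + shift
      if (type == "RI") i2 <- seg
      else { ext <- seg; i2 <- ext + sample(30:60, 1) }
      ## PTC in exon4 lands at modified phase 0 after the +seg insertion
      delta4 <- 6L + ((3L - shift) %% 3L)
      plant_tx(l1 + l2 + l3 + delta4, "TAA")
      net <- seg
    }
    designed_frame <- net %% 3L
    expected_nmd <- FALSE
    expected_reason <- "PTC_IN_LAST_EXON"
  } else if (scen == "start_lost") {
    l1 <- 9L                              # exon1 is pure 5'UTR
    need(type == "ES", "start_lost is built on an ES event")
    net <- -l2
    expected_nmd <- NA
    expected_reason <- "START_LOST"
  } else if (scen == "no_junction") {
    need(type == "RI", "no_junction is built on an RI event")
    n_exons <- 2L
    designed_k <- as.integer(k)
    i1 <- 3L * (designed_k + 3L)
    for (j in seq_len(designed_k))
      plant_intron(1L, 6L + 3L * (j - 1L), "TAA")
    net <- i1
    expected_nmd <- FALSE
    expected_reason <- "NO_JUNCTION"
  } else if (scen == "no_cds_change") {
    need(type == "ES", "no_cds_change is built on an ES event in the 3'UTR")
    net <- -l3
    expected_nmd <- FALSE
    expected_reason <- "NO_CDS_CHANGE"
  } else if (scen == "not_on_canonical") {
    net <- NA_integer_
    expected_nmd <- NA
    expected_reason <- "NOT_ON_CANONICAL"
  } else if (scen == "unsupported") {
    ev_type_in <- plan$raw_type %||% "TS"
    net <- NA_integer_
    expected_nmd <- NA
    expected_reason <- "UNSUPPORTED_TYPE"
  } else stop("unknown scenario: ", scen)

  ## CDS terminator placement ---------------------------------------------
  if (n_exons == 2L) {
    dS <- 24L + ((-(l1 - u)) %% 3L)
    S <- l1 + dS
    l2 <- dS + 3L + 30L
    exon_lens <- c(l1, l2)
  } else if (scen == "start_lost") {
    u <- l1 + 3L                          # start codon sits in exon2
    dS <- 24L + ((-(l1 + l2 + l3 - u)) %% 3L)
    S <- l1 + l2 + l3 + dS
    l4 <- dS + 3L + 30L
    exon_lens <- c(l1, l2, l3, l4)
  } else if (scen == "no_cds_change") {
    S <- l1 + l2 - 15L
    S <- S - ((S - u) %% 3L)              # keep terminator in frame
    l4 <- 40L
    exon_lens <- c(l1, l2, l3, l4)
  } else {
    dS <- 24L + ((-(l1 + l2 + l3 - u)) %% 3L)
    S <- l1 + l2 + l3 + dS
    l4 <- dS + 3L + 30L
    exon_lens <- c(l1, l2, l3, l4)
  }
  plant_tx(u, "ATG")
  plant_tx(u + 3L, "C")                   # keep ATG's TG out of a TGA window
  plant_tx(S, "TAA")

  ## sense-space layout (transcription direction, introns included) -------
  intron_lens <- if (n_exons == 2L) i1 else c(i1, i2, i3)
  sE <- integer(n_exons); sI <- integer(length(intron_lens))
  pos <- 0L
  for (x in seq_len(n_exons)) {
    sE[x] <- pos; pos <- pos + exon_lens[x]
    if (x <= length(intron_lens)) { sI[x] <- pos; pos <- pos + intron_lens[x] }
  }
  L <- pos
  txcum <- c(0L, cumsum(exon_lens))
  tx2sense <- function(tp) {
    x <- findInterval(tp, txcum, rightmost.closed = FALSE)
    sE[x] + (tp - txcum[x])
  }

  bases <- rand_bases(L)
  for (p in tx_plants) {
    motif <- strsplit(p$motif, "")[[1]]
    sp <- tx2sense(p$pos)
    ## planted motifs never span an exon boundary by design
    stopifnot(tx2sense(p$pos + length(motif) - 1L) == sp + length(motif) - 1L)
    bases[(sp + 1L):(sp + length(motif))] <- motif
  }
  for (p in intron_plants) {
    motif <- strsplit(p$motif, "")[[1]]
    sp <- sI[p$intron] + p$off
    bases[(sp + 1L):(sp + length(motif))] <- motif
  }

  ## event interval in sense coordinates ----------------------------------
  if (scen == "not_on_canonical") {
    flavor <- plan$flavor %||% "unknown_gene"
    if (flavor == "unknown_gene") {
      ev_sense <- c(sE[2], sE[2] + exon_lens[2]); ev_gene_suffix <- "X"
    } else if (flavor == "coord_mismatch") {
      ev_sense <- c(sE[2] + 5L, sE[2] + exon_lens[2] + 5L)
    } else {                              # terminal exon
      ev_sense <- c(sE[1], sE[1] + exon_lens[1])
    }
  } else if (scen == "unsupported") {
    ev_sense <- c(sE[1], sE[1] + exon_lens[1])
  } else if (type == "ES") {
    idx <- if (scen == "no_cds_change") 3L else 2L
    ev_sense <- c(sE[idx], sE[idx] + exon_lens[idx])
  } else if (type == "RI") {
    idx <- if (n_exons == 2L) 1L else 2L
    ev_sense <- c(sI[idx], sI[idx] + intron_lens[idx])
    if (isTRUE(plan$ri_span_dialect) && n_exons == 4L)
      ev_sense <- c(sE[2], sE[3] + exon_lens[3])
  } else if (type == "AA") {
    ev_sense <- c(sE[3] - ext, sE[3] + exon_lens[3])
  } else if (type == "AD") {
    ev_sense <- c(sE[2], sE[2] + exon_lens[2] + ext)
  }

  ## genomic layout: 50 nt flanks; minus-strand genes are laid out as the
  ## reverse complement with mirrored coordinates
  strand <- plan$strand
  flank <- 50L
  chrom_len <- L + 2L * flank
  if (strand == "+") {
    chrom_seq <- paste0(c(rand_bases(flank), bases, rand_bases(flank)),
                        collapse = "")
    g_int <- function(ab) c(flank + ab[1], flank + ab[2])
  } else {
    chrom_seq <- paste0(c(rand_bases(flank), revcomp_chars(bases),
                          rand_bases(flank)), collapse = "")
    g_int <- function(ab) c(flank + L - ab[2], flank + L - ab[1])
  }
  exons_g <- t(vapply(seq_len(n_exons), function(x)
    g_int(c(sE[x], sE[x] + exon_lens[x])), c(0, 0)))
  exons_g <- data.frame(start = as.integer(exons_g[, 1]),
                        end = as.integer(exons_g[, 2]))
  ev_g <- g_int(ev_sense)

  ## CDS pieces for GTF (tx extent intersected with exons)
  cds_pieces <- function(lo, hi) {
    segs <- list()
    for (x in seq_len(n_exons)) {
      o1 <- max(lo, txcum[x]); o2 <- min(hi, txcum[x + 1])
      if (o1 < o2)
        segs[[length(segs) + 1]] <- g_int(c(tx2sense(o1),
                                            tx2sense(o2 - 1L) + 1L))
    }
    segs
  }
  dialect <- plan$gtf_dialect %||% "ensembl"
  cds_g <- if (dialect == "ensembl") cds_pieces(u, S) else cds_pieces(u, S + 3L)
  stop_g <- if (dialect == "ensembl") cds_pieces(S, S + 3L) else list()

  truth <- data.frame(
    gene_id = plan$gene_id, node = plan$node,
    event_type = if (ev_type_in == "CE") "ES" else ev_type_in,
    scenario = scen, strand = strand,
    net_length_change = net,
    designed_frame = if (scen %in% c("ptc", "too_close", "last_exon",
                                     "clean", "no_junction", "no_cds_change"))
      designed_frame else NA_integer_,
    designed_distance = designed_d,
    designed_ptc_count = designed_k,
    expected_nmd = expected_nmd,
    expected_reason = expected_reason,
    stringsAsFactors = FALSE
  )

  list(chrom = plan$chrom, chrom_len = chrom_len, chrom_seq = chrom_seq,
       strand = strand, exons_g = exons_g, cds_g = cds_g, stop_codon_g = stop_g,
       gene_id = plan$gene_id, tx_id = paste0(plan$gene_id, ".t1"),
       tagged = isTRUE(plan$tagged), decoy = isTRUE(plan$decoy) &&
         scen != "start_lost",
       decoy_u = u,
       event = list(gene_id = paste0(plan$gene_id, ev_gene_suffix),
                    node = plan$node, chrom = plan$chrom,
                    start = as.integer(ev_g[1]), end = as.integer(ev_g[2]),
                    strand = strand, type = ev_type_in),
       truth = truth)
}

gtf_attr <- function(gene, tx, tags = character(0)) {
  paste0('gene_id "', gene, '"; transcript_id "', tx, '"; ',
         paste0('tag "', tags, '"; ', collapse = ""))
}

write_gene_gtf <- function(g) {
  lines <- character(0)
  tags <- if (g$tagged) c("Ensembl_canonical", "basic") else "basic"
  add <- function(type, s0, e0, frame = ".", tx = g$tx_id, tg = tags)
    lines <<- c(lines, paste(g$chrom, "toygen", type, s0 + 1L, e0, ".",
                             g$strand, frame, gtf_attr(g$gene_id, tx, tg),
                             sep = "\t"))
  add("transcript", min(g$exons_g$start), max(g$exons_g$end))
  ord <- order(g$exons_g$start)
  for (x in ord) add("exon", g$exons_g$start[x], g$exons_g$end[x])
  cum <- 0L
  for (seg in g$cds_g) {     # transcription order: frame from cumulative CDS
    add("CDS", seg[1], seg[2], frame = (3L - cum %% 3L) %% 3L)
    cum <- cum + (seg[2] - seg[1])
  }
  for (seg in g$stop_codon_g) add("stop_codon", seg[1], seg[2], frame = 0L)
  if (g$decoy) {
    tx2 <- paste0(g$gene_id, ".t2")
    ord2 <- ord[seq_len(min(2L, length(ord)))]
    add("transcript", min(g$exons_g$start[ord2]), max(g$exons_g$end[ord2]),
        tx = tx2, tg = "basic")
    for (x in ord2) add("exon", g$exons_g$start[x], g$exons_g$end[x],
                        tx = tx2, tg = "basic")
    ## short decoy CDS inside exon1 so canonical selection must prefer t1
    e1 <- g$exons_g[1, ]
    seg <- if (g$strand == "+") c(e1$start + g$decoy_u, e1$start + g$decoy_u + 18L)
           else c(e1$end - g$decoy_u - 18L, e1$end - g$decoy_u)
    add("CDS", seg[1], seg[2], frame = 0L, tx = tx2, tg = "basic")
  }
  lines
}

#' Generate toy genes with Whippet-style events and ground-truth NMD labels
#'
#' Each gene lives on its own short chromosome and carries exactly one
#' splicing event with a designed outcome. Defaults emulate the study
#' conditions: splicing-type frequencies of the all-events (baseline) group
#' (ES 76.3%, RI 9.5%, AA 8.1%, AD 6.1%), an NMD-true fraction of 0.907 and
#' per-type PTC-count medians of 37/23/24/30 (ES/RI/AA/AD). NMD-false events
#' are split between frame-preserving stop-free surgery, PTCs in the last
#' exon, and PTCs closer to the final junction than the rule threshold.
#'
#' @param n_genes Number of genes (= events) to generate.
#' @param seed Integer seed; identical seeds give byte-identical files.
#' @param event_weights Sampling weights over `ES, RI, AA, AD`.
#' @param p_nmd_true Designed fraction of NMD-true events among PTC-capable
#'   designs.
#' @param ptc_count_medians Designed per-type median PTC counts; individual
#'   counts are jittered by at most +-3 so the population median is exact.
#' @param p_transcription_related Fraction of TS/TE/AF/AL rows (skipped by
#'   the pipeline).
#' @param p_not_on_canonical Fraction of events that cannot be placed on the
#'   canonical transcript (unknown gene, shifted coordinate, terminal exon).
#' @param p_degenerate Fraction of degenerate-branch designs (start lost,
#'   no junction, no CDS change), split evenly.
#' @param frac_significant Fraction of events passing the Whippet
#'   significance filter by design.
#' @param ptc_rule_nt Rule threshold the truth labels are designed against.
#' @param plans Optional explicit list of gene plans (overrides the random
#'   mix); each element may set `event_type`, `scenario`, `d`, `k`, `shift`,
#'   `strand`, `flavor`, `junction_route`, `significant`.
#' @param out_dir Output directory (created); defaults to a fresh tempdir.
#' @param prefix File name prefix.
#' @return List with file paths `fasta`, `gtf`, `diff`, `truth_path`, and the
#'   `truth` data.frame.
#' @export
make_toy_genes <- function(n_genes, seed,
                           event_weights = c(ES = 0.763, RI = 0.095,
                                             AA = 0.081, AD = 0.061),
                           p_nmd_true = 0.907,
                           ptc_count_medians = c(ES = 37, RI = 23,
                                                 AA = 24, AD = 30),
                           p_transcription_related = 0,
                           p_not_on_canonical = 0,
                           p_degenerate = 0,
                           frac_significant = 1,
                           ptc_rule_nt = 50L,
                           plans = NULL,
                           out_dir = NULL, prefix = "toy") {
  stopifnot(is.null(plans) || length(plans) >= 1, is.null(plans) || n_genes == length(plans))
  if (n_genes < 1) stop("n_genes must be >= 1")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  thr <- as.integer(ptc_rule_nt)
  if (is.null(plans)) {
    plans <- vector("list", n_genes)
    deg_cycle <- c("start_lost", "no_junction", "no_cds_change")
    noc_cycle <- c("unknown_gene", "coord_mismatch", "terminal_exon")
    deg_i <- 0L; noc_i <- 0L
    for (i in seq_len(n_genes)) {
      r <- stats::runif(1)
      if (r < p_transcription_related) {
        pl <- list(event_type = "TS", scenario = "unsupported",
                   raw_type = sample(c("TS", "TE", "AF", "AL"), 1))
      } else if (r < p_transcription_related + p_not_on_canonical) {
        noc_i <- noc_i + 1L
        pl <- list(event_type = "ES", scenario = "not_on_canonical",
                   flavor = noc_cycle[(noc_i - 1L) %% 3L + 1L])
      } else if (r < p_transcription_related + p_not_on_canonical + p_degenerate) {
        deg_i <- deg_i + 1L
        scen <- deg_cycle[(deg_i - 1L) %% 3L + 1L]
        pl <- list(event_type = if (scen == "no_junction") "RI" else "ES",
                   scenario = scen, k = 2L)
      } else {
        ty <- sample(names(event_weights), 1, prob = event_weights)
        if (stats::runif(1) < p_nmd_true) {
          ## jitter keeps extra mass at the designed value so the population
          ## median stays exact despite low-count NMD-false events
          k <- max(1L, as.integer(ptc_count_medians[[ty]]) +
                     sample(-3:3, 1, prob = c(1, 1, 1, 3, 1, 1, 1)))
          d <- max(thr + 5L, 3L * k + 10L) + sample(0:150, 1)
          pl <- list(event_type = ty, scenario = "ptc", d = d, k = k,
                     shift = if (ty == "ES") sample(1:2, 1) else sample(0:2, 1),
                     junction_route = ty == "ES" && stats::runif(1) < 0.1,
                     ri_span_dialect = ty == "RI" && i %% 5L == 0L)
          if (isTRUE(pl$junction_route)) { pl$k <- 1L; pl$d <- max(thr + 5L, 13L) + sample(0:150, 1) }
        } else {
          scen <- sample(c("clean", "last_exon", "too_close"), 1,
                         prob = c(0.5, 0.3, 0.2))
          pl <- list(event_type = ty, scenario = scen,
                     d = if (scen == "too_close") sample(7:(thr - 1L), 1) else NA,
                     k = 1L)
        }
      }
      pl$significant <- stats::runif(1) < frac_significant
      plans[[i]] <- pl
    }
  }

  fasta_lines <- character(0)
  gtf_lines <- character(0)
  diff_rows <- vector("list", n_genes)
  truth_rows <- vector("list", n_genes)

  for (i in seq_along(plans)) {
    pl <- plans[[i]]
    pl$thr <- pl$thr %||% thr
    pl$gene_id <- pl$gene_id %||% sprintf("TG%04d", i)
    pl$chrom <- pl$chrom %||% sprintf("chr%d", i)
    pl$node <- i
    pl$strand <- pl$strand %||% c("+", "-")[i %% 2L + 1L]
    pl$tagged <- pl$tagged %||% (i %% 7L != 0L)
    pl$decoy <- pl$decoy %||% (i %% 6L == 0L)
    pl$gtf_dialect <- pl$gtf_dialect %||%
      (if (i %% 9L == 0L) "stopincl" else "ensembl")
    g <- build_gene(pl)

    fasta_lines <- c(fasta_lines, paste0(">", g$chrom),
                     substring(g$chrom_seq,
                               seq(1, nchar(g$chrom_seq), 70),
                               pmin(seq(1, nchar(g$chrom_seq), 70) + 69,
                                    nchar(g$chrom_seq))))
    gtf_lines <- c(gtf_lines, write_gene_gtf(g))

    sig <- isTRUE(pl$significant %||% TRUE)
    dpsi_mag <- if (sig) round(stats::runif(1, 0.15, 0.5), 4)
                else round(stats::runif(1, 0.001, 0.08), 4)
    dpsi <- dpsi_mag * sample(c(-1, 1), 1)
    psi_a <- round(stats::runif(1, 0.25, 0.6), 4)
    diff_rows[[i]] <- data.frame(
      gene_id = g$event$gene_id, node = g$event$node, chrom = g$event$chrom,
      start = g$event$start, end = g$event$end, strand = g$event$strand,
      event_type = g$event$type, psi_a = psi_a,
      psi_b = round(min(max(psi_a + dpsi, 0), 1), 4),
      delta_psi = dpsi,
      probability = if (sig) round(stats::runif(1, 0.92, 0.999), 4)
                    else round(stats::runif(1, 0, 0.5), 4),
      complexity = "K1", entropy = round(stats::runif(1, 0, 2), 3),
      stringsAsFactors = FALSE)
    truth_rows[[i]] <- g$truth
  }

  out_dir <- out_dir %||% tempfile("toygenes")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(out_dir, paste0(prefix, ".fa"))
  gtf <- file.path(out_dir, paste0(prefix, ".gtf"))
  diff <- file.path(out_dir, paste0(prefix, ".diff"))
  truth_path <- file.path(out_dir, paste0(prefix, ".truth.tsv"))
  writeLines(fasta_lines, fasta)
  writeLines(gtf_lines, gtf)
  events <- do.call(rbind, diff_rows)
  write_diff_table(events, diff)
  truth <- do.call(rbind, truth_rows)
  data.table::fwrite(truth, truth_path, sep = "\t", quote = FALSE, na = "NA")
  list(fasta = fasta, gtf = gtf, diff = diff, truth_path = truth_path,
       truth = truth, events = events)
}

#' Boundary-distance fixture around the junction rule threshold
#'
#' One gene per requested PTC-to-junction distance, built on frame-preserving
#' retained introns with a single designed PTC.
#'
#' @param distances Integer vector of designed distances (e.g. `49:51`).
#' @param seed Integer seed.
#' @param type Event type to build on (default `RI`).
#' @param ... Passed to [make_toy_genes()].
#' @return As [make_toy_genes()].
#' @export
make_boundary_genes <- function(distances, seed, type = "RI", ...) {
  plans <- lapply(distances, function(d)
    list(event_type = type,
         scenario = if (d >= 50) "ptc" else "too_close",
         d = as.integer(d), k = 1L, shift = 0L))
  make_toy_genes(length(plans), seed, plans = plans, ...)
}

#' Mirror a toy fixture (reverse-complement genome, reflected coordinates)
#'
#' Writes a strand-flipped copy of a FASTA/GTF/diff fixture bundle: every
#' chromosome is reverse-complemented, every interval reflected about the
#' chromosome length, and every strand flipped. The mature transcripts, and
#' hence all NMD calls, are invariant under this transformation.
#'
#' @param fasta,gtf,diff Paths of the original fixture.
#' @param out_dir Output directory.
#' @return List of mirrored `fasta`, `gtf`, `diff` paths.
#' @export
mirror_fixture <- function(fasta, gtf, diff, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- load_genome(fasta)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  mirrored <- Biostrings::reverseComplement(genome)
  fa_out <- file.path(out_dir, "mirror.fa")
  Biostrings::writeXStringSet(mirrored, fa_out, width = 70L)
  flip <- c("+" = "-", "-" = "+")

  gl <- strsplit(readLines(gtf), "\t", fixed = TRUE)
  gtf_out <- vapply(gl, function(f) {
    L <- lens[[f[1]]]
    s1 <- as.integer(f[4]); e1 <- as.integer(f[5])
    f[4] <- as.character(L - e1 + 1L); f[5] <- as.character(L - s1 + 1L)
    f[7] <- flip[[f[7]]]
    paste(f, collapse = "\t")
  }, "")
  writeLines(gtf_out, file.path(out_dir, "mirror.gtf"))

  ev <- parse_diff_table(diff)
  L <- lens[ev$chrom]
  new_start <- L - ev$end
  ev$end <- L - ev$start
  ev$start <- new_start
  ev$strand <- unname(flip[ev$strand])
  diff_out <- file.path(out_dir, "mirror.diff")
  write_diff_table(ev, diff_out)
  list(fasta = fa_out, gtf = file.path(out_dir, "mirror.gtf"), diff = diff_out)
}
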
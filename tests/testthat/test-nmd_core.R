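mini_mature <- function(seq, junctions = integer(0), cds_offset = 0L,
                        stop_offset = NA_integer_, stop_is_normal = FALSE,
                        cds_changed = TRUE, start_lost = FALSE) {
  list(seq = seq, junctions = as.integer(junctions),
       cds_offset = as.integer(cds_offset),
       stop_offset = if (is.na(stop_offset)) NA_integer_ else as.integer(stop_offset),
       stop_is_normal = stop_is_normal, cds_changed = cds_changed,
       start_lost = start_lost, note = NA_character_)
}

test_that("frame prediction is net length change mod 3, zero outside the CDS", {
  pl <- function(net) list(net_length_change = as.integer(net))
  m_cds <- mini_mature("ATG", cds_changed = TRUE)
  m_utr <- mini_mature("ATG", cds_changed = FALSE)
  expect_equal(predicted_frame(pl(-100), m_cds), 2L)
  expect_equal(predicted_frame(pl(84), m_cds), 0L)
  expect_equal(predicted_frame(pl(7), m_cds), 1L)
  expect_equal(predicted_frame(pl(84), m_utr), 0L)
  expect_equal(predicted_frame(pl(-100), m_utr), 0L)
})

test_that("stop-codon scanning matches an exhaustive sliding-window oracle", {
  ## normal stop is never a PTC
  m <- mini_mature("ATGAAATAA", stop_offset = 6L, stop_is_normal = TRUE)
  expect_equal(scan_ptcs(m)[["0"]], integer(0))
  ## an upstream in-frame stop is
  m <- mini_mature("ATGTGAAAATAA", stop_offset = 9L, stop_is_normal = TRUE)
  expect_equal(scan_ptcs(m)[["0"]], 3L)

  ## random sequence versus a brute-force triplet scan, all three frames
  set.seed(31)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 999, TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.28, 0.02)), collapse = "")
  m <- mini_mature(s, cds_offset = 12L)
  got <- scan_ptcs(m)
  for (f in 0:2) {
    expected <- integer(0)
    p <- 12L + f
    while (p + 3 <= nchar(s)) {
      if (substr(s, p + 1, p + 3) %in% c("TAA", "TAG", "TGA"))
        expected <- c(expected, p)
      p <- p + 3L
    }
    expect_equal(got[[as.character(f)]], expected)
  }
  expect_error(scan_ptcs(mini_mature("ATGXXX")), "non-ACGTN")
})

test_that("NMD classification covers the rule and every degenerate branch", {
  cfg <- nmd_config(50)
  run <- function(m) classify_nmd(m, 0L, scan_ptcs(m, cfg), cfg)

  ## PTC 120 nt upstream of the final junction -> NMD true
  s <- paste0("ATG", "TAA", strrep("GCA", 60), "CCC")   # stop at 3, len 189
  m <- mini_mature(s, junctions = c(125L, 150L))
  r <- run(m)
  expect_true(r$nmd)
  expect_equal(r$reason, "PTC_UPSTREAM_RULE")
  expect_equal(r$distance_nt, 145L)

  ## distance exactly at the threshold counts as NMD (>= comparison)
  m <- mini_mature(s, junctions = 55L)
  expect_true(run(m)$nmd)
  m <- mini_mature(s, junctions = 54L)
  r <- run(m)
  expect_false(r$nmd)
  expect_equal(r$reason, "PTC_TOO_CLOSE")

  ## PTC downstream of the last junction
  m <- mini_mature(s, junctions = 2L)
  r <- run(m)
  expect_false(r$nmd)
  expect_equal(r$reason, "PTC_IN_LAST_EXON")

  ## no junction at all
  m <- mini_mature(s)
  r <- run(m)
  expect_false(r$nmd)
  expect_equal(r$reason, "NO_JUNCTION")

  ## no stop anywhere
  m <- mini_mature(paste0("ATG", strrep("GCA", 20)), junctions = 30L)
  r <- run(m)
  expect_false(r$nmd)
  expect_equal(r$reason, "NO_PTC")

  ## CDS untouched by the event
  m <- mini_mature(paste0("ATG", strrep("GCA", 20)), junctions = 30L,
                   cds_changed = FALSE)
  expect_equal(run(m)$reason, "NO_CDS_CHANGE")

  ## lost start codon: call skipped
  m <- mini_mature(s, junctions = 100L, start_lost = TRUE)
  r <- classify_nmd(m, NA_integer_,
                    list(`0` = integer(0), `1` = integer(0), `2` = integer(0)),
                    cfg)
  expect_true(is.na(r$nmd))
  expect_equal(r$reason, "START_LOST")
})

test_that("threshold configuration is validated but overridable", {
  expect_equal(nmd_config(55)$ptc_junction_threshold_nt, 55L)
  expect_error(nmd_config(40), "50-55")
  expect_equal(nmd_config(40, validate_threshold = FALSE)$ptc_junction_threshold_nt,
               40L)
})

test_that("the pipeline handles empty input, skips and mismatched chromosomes", {
  co <- std_cohort()
  empty <- run_pipeline(co$events[0, ], co$annotation, co$genome)
  expect_equal(nrow(empty), 0L)

  res <- std_results()
  ## transcription-related events carry a skip reason, never an NMD call
  ts_rows <- res[res$event_type %in% c("TS", "TE", "AF", "AL"), ]
  expect_true(all(ts_rows$reason == "UNSUPPORTED_TYPE"))
  expect_true(all(is.na(ts_rows$nmd)))
  ## every event appears exactly once; parsed = processed + skipped
  expect_equal(nrow(res), nrow(co$events))
  sc <- attr(res, "stage_counts")
  expect_equal(unname(sc["parsed"]), unname(sc["processed"] + sc["skipped"]))

  ## chromosome naming mismatch gives an actionable error
  ev_bad <- co$events
  ev_bad$chrom <- paste0("x", ev_bad$chrom)
  expect_error(run_pipeline(ev_bad, co$annotation, co$genome),
               "chromosome naming")
})

test_that("pipeline results are deterministic and match written golden output", {
  co <- std_cohort()
  r1 <- run_pipeline(co$events, co$annotation, co$genome)
  r2 <- run_pipeline(co$events, co$annotation, co$genome)
  expect_identical(r1, r2)
  p1 <- tempfile(); p2 <- tempfile()
  write_nmd_results(r1, p1); write_nmd_results(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_nmd_results(p1)
  expect_equal(back$nmd, r1$nmd)
  expect_equal(back$reason, r1$reason)
})
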
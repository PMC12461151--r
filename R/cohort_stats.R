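## Cohort-level summaries: NMD rates, subtype breakdowns, PTC medians,
## psi-magnitude comparison, test-selection logic and the protein-direction
## rule.

REPORT_TYPES <- c("ES", "RI", "AA", "AD")

summarize_one <- function(results) {
  proc <- results[results$reason %in% PROCESSED_REASONS, , drop = FALSE]
  if (nrow(proc) == 0L)
    stop("no processed events: NMD rate undefined")
  ty <- factor(proc$event_type, levels = REPORT_TYPES)
  n_true <- sum(proc$nmd)
  by_type_n <- table(ty)
  by_type_true <- table(ty[proc$nmd])
  med_by_type <- vapply(REPORT_TYPES, function(t) {
    x <- proc$ptc_count_f0[proc$event_type == t]
    if (length(x)) stats::median(x) else NA_real_
  }, 0)
  nm <- function(v) stats::setNames(as.vector(v), REPORT_TYPES)
  list(
    n_processed = nrow(proc),
    n_nmd_true = n_true,
    nmd_rate = 100 * n_true / nrow(proc),
    type_counts = stats::setNames(as.vector(by_type_n, mode = "integer"),
                                  REPORT_TYPES),
    type_percent = nm(100 * as.vector(by_type_n) / nrow(proc)),
    nmd_true_by_type = stats::setNames(as.vector(by_type_true, mode = "integer"),
                                       REPORT_TYPES),
    nmd_by_type = nm(100 * as.vector(by_type_true) / as.vector(by_type_n)),
    nmd_share_by_type = if (n_true > 0)
      nm(100 * as.vector(by_type_true) / n_true)
    else stats::setNames(rep(NA_real_, 4), REPORT_TYPES),
    ptc_median_by_type = med_by_type
  )
}

#' Two-group cohort summary of NMD predictions
#'
#' Mirrors the study construction in which all quantifiable events play the
#' baseline ("control"/"survived") role and the significantly
#' differentially-spliced events the contrast ("sepsis"/"deceased") role.
#' Rows with skip reasons are excluded from every denominator. Group
#' comparisons use a 2x2 chi-square (Yates-corrected when any expected cell
#' is below 5) for rates and shares, and a Shapiro-Wilk-gated t/Wilcoxon
#' test for PTC counts.
#'
#' @param results_all [run_pipeline()] output for the baseline event set.
#' @param results_sig [run_pipeline()] output for the significant event set.
#' @param group_labels Length-2 character labels.
#' @return A `cohort_summary` list: per-group summaries (`n_processed`,
#'   `nmd_rate`, `nmd_by_type`, `nmd_share_by_type`, `ptc_median_by_type`,
#'   type counts/percentages) and a `tests` data.frame of group comparisons.
#' @export
summarize_cohort <- function(results_all, results_sig,
                             group_labels = c("all", "significant")) {
  a <- summarize_one(results_all)
  b <- summarize_one(results_sig)
  proc_a <- results_all[results_all$reason %in% PROCESSED_REASONS, ]
  proc_b <- results_sig[results_sig$reason %in% PROCESSED_REASONS, ]

  tests <- list()
  add_test <- function(comparison, res) {
    tests[[length(tests) + 1]] <<- data.frame(
      comparison = comparison, statistic = res$statistic,
      p_value = res$p_value, test_name = res$test_name,
      stringsAsFactors = FALSE)
  }
  add_test("nmd_rate", compare_proportions(a$n_nmd_true, a$n_processed,
                                           b$n_nmd_true, b$n_processed))
  for (t in REPORT_TYPES) {
    if (a$type_counts[[t]] > 0 && b$type_counts[[t]] > 0) {
      add_test(paste0("nmd_rate_", t),
               compare_proportions(a$nmd_true_by_type[[t]], a$type_counts[[t]],
                                   b$nmd_true_by_type[[t]], b$type_counts[[t]]))
      add_test(paste0("type_share_", t),
               compare_proportions(a$type_counts[[t]], a$n_processed,
                                   b$type_counts[[t]], b$n_processed))
      if (a$n_nmd_true > 0 && b$n_nmd_true > 0)
        add_test(paste0("nmd_share_", t),
                 compare_proportions(a$nmd_true_by_type[[t]], a$n_nmd_true,
                                     b$nmd_true_by_type[[t]], b$n_nmd_true))
      x <- proc_a$ptc_count_f0[proc_a$event_type == t]
      y <- proc_b$ptc_count_f0[proc_b$event_type == t]
      if (length(x) > 1 && length(y) > 1)
        add_test(paste0("ptc_count_", t), compare_continuous(x, y))
    }
  }
  structure(list(group_labels = group_labels,
                 groups = stats::setNames(list(a, b), group_labels),
                 tests = do.call(rbind, tests)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  for (g in names(x$groups)) {
    s <- x$groups[[g]]
    cat(sprintf("group '%s': %d processed events, NMD rate %.1f%%\n",
                g, s$n_processed, s$nmd_rate))
    cat("  NMD rate by type (%):",
        paste(sprintf("%s %.1f", REPORT_TYPES, s$nmd_by_type), collapse = ", "),
        "\n")
    cat("  PTC median by type: ",
        paste(sprintf("%s %g", REPORT_TYPES, s$ptc_median_by_type),
              collapse = ", "), "\n")
  }
  cat("comparisons:\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Compare two proportions with a 2x2 chi-square test
#'
#' Yates' continuity correction is applied when any expected cell count is
#' below 5 (the conventional small-sample rule); both the corrected and
#' uncorrected statistics are returned.
#'
#' @param k1,n1 Successes and total in group 1.
#' @param k2,n2 Successes and total in group 2.
#' @return List with `statistic`, `p_value`, `test_name`, `yates`, and both
#'   `uncorrected`/`corrected` sub-results.
#' @export
compare_proportions <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (k1 > n1 || k2 > n2 || k1 < 0 || k2 < 0) stop("need 0 <= k <= n")
  m <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  yates <- any(expected < 5)
  plain <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  corr <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  chosen <- if (yates) corr else plain
  list(statistic = unname(chosen$statistic),
       p_value = chosen$p.value,
       test_name = if (yates) "chi-square (Yates)" else "chi-square",
       yates = yates,
       uncorrected = list(statistic = unname(plain$statistic),
                          p_value = plain$p.value),
       corrected = list(statistic = unname(corr$statistic),
                        p_value = corr$p.value))
}

## Shapiro-Wilk-gated two-sample comparison for continuous values: t test
## when both samples look normal at alpha = 0.05, Wilcoxon rank-sum
## otherwise (ties handled by wilcox.test's normal approximation with
## continuity correction for larger samples, exact test for small ones).
compare_continuous <- function(x, y, alpha = 0.05) {
  normal <- function(v) {
    if (length(v) < 3 || length(unique(v)) == 1) return(FALSE)
    vv <- if (length(v) > 5000) sample(v, 5000) else v
    stats::shapiro.test(vv)$p.value > alpha
  }
  if (normal(x) && normal(y)) {
    ht <- stats::t.test(x, y)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test_name = "t")
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test_name = "wilcoxon")
  }
}

#' Compare the magnitude of splicing change between two event sets
#'
#' Reports the median |DeltaPsi| per group, Anderson-Darling normality
#' p-values for context, and the two-sample Wilcoxon rank-sum p-value.
#'
#' @param events_a,events_b Event data.frames.
#' @return List with `median_a`, `median_b`, `p_value`, `normality_p`
#'   (per-group Anderson-Darling p-values, `NA` when n < 8) and `test_name`.
#' @export
compare_psi_magnitude <- function(events_a, events_b) {
  x <- abs(events_a$delta_psi); y <- abs(events_b$delta_psi)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ad_p <- function(v) {
    if (length(v) < 8) return(NA_real_)
    tryCatch(nortest::ad.test(v)$p.value, error = function(e) NA_real_)
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y))
  list(median_a = stats::median(x), median_b = stats::median(y),
       p_value = ht$p.value,
       normality_p = c(a = ad_p(x), b = ad_p(y)),
       test_name = "wilcoxon rank-sum")
}

#' Export genes whose events are predicted not to trigger NMD
#'
#' Unique gene ids over evaluated events with `nmd == FALSE` (skip-reason
#' rows excluded), sorted, one per line - the input set for external GO
#' enrichment tools.
#'
#' @param results [run_pipeline()] output.
#' @param path Optional output file.
#' @return Character vector of gene ids, invisibly when `path` is given.
#' @export
export_nmd_false_genes <- function(results, path = NULL) {
  keep <- results$reason %in% PROCESSED_REASONS & !results$nmd
  genes <- sort(unique(results$gene_id[keep]))
  if (!is.null(path)) {
    writeLines(genes, path)
    return(invisible(genes))
  }
  genes
}

#' Predict the direction of a protein-level change from DGE + splicing + NMD
#'
#' The rule covers genes whose expression is NOT significantly different:
#' if a splicing event that triggers NMD is less frequent in group B
#' (`delta_psi < 0`), fewer transcripts are decayed in B and a higher
#' protein level is predicted there; the symmetric case predicts a lower
#' level. All other combinations are indeterminate.
#'
#' @param dge One DGE record (list/row with `log2fc`, `padj`) or `NULL`.
#' @param event One splice event (needs `gene_id`, `delta_psi`).
#' @param nmd_result Matching NMD result row (needs `nmd`).
#' @param padj_max,abs_log2fc_min DGE significance thresholds (defaults
#'   0.05 and 2).
#' @return List with `gene_id`, `dge_significant`, `splicing_direction`,
#'   `nmd_flag`, `predicted_direction`.
#' @export
predict_protein_direction <- function(dge, event, nmd_result,
                                      padj_max = 0.05, abs_log2fc_min = 2) {
  dge_sig <- !is.null(dge) && !is.na(dge$padj) && !is.na(dge$log2fc) &&
    dge$padj < padj_max && abs(dge$log2fc) > abs_log2fc_min
  dir <- if (event$delta_psi > 0) "more_in_B" else "less_in_B"
  nmd_flag <- isTRUE(nmd_result$nmd)
  predicted <- if (!dge_sig && nmd_flag) {
    if (dir == "less_in_B") "higher_in_B" else "lower_in_B"
  } else "indeterminate"
  list(gene_id = as.character(event$gene_id), dge_significant = dge_sig,
       splicing_direction = dir, nmd_flag = nmd_flag,
       predicted_direction = predicted)
}
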
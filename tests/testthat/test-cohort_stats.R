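fake_results <- function(n, type = "ES", nmd = TRUE, ptc = 1L,
                         reason = NULL, gene = NULL) {
  reason <- reason %||% ifelse(nmd, "PTC_UPSTREAM_RULE", "NO_PTC")
  data.frame(gene_id = gene %||% sprintf("G%03d", seq_len(n)),
             node = seq_len(n), event_type = type,
             predicted_frame = 1L, ptc_count_f0 = ptc, ptc_count_f1 = 0L,
             ptc_count_f2 = 0L, first_ptc = 10L, last_junction = 200L,
             distance_nt = 188L, nmd = nmd, reason = reason,
             note = NA_character_, delta_psi = 0.2, probability = 0.95,
             stringsAsFactors = FALSE)
}

test_that("cohort summaries report rates, medians and shares correctly", {
  all_r <- rbind(fake_results(9, "ES", TRUE, ptc = c(37, 36, 38, 37, 37, 40, 35, 37, 30)),
                 fake_results(1, "ES", FALSE),
                 fake_results(4, "RI", TRUE, ptc = 23),
                 fake_results(2, "AA", TRUE, ptc = 24),
                 fake_results(1, "AD", TRUE, ptc = 30),
                 fake_results(2, "ES", NA, reason = "NOT_ON_CANONICAL"))
  sig_r <- rbind(fake_results(4, "ES", TRUE, ptc = 35),
                 fake_results(1, "RI", FALSE))
  s <- summarize_cohort(all_r, sig_r)
  a <- s$groups$all
  ## 16 true / 17 processed; the two skip rows never enter denominators
  expect_equal(a$n_processed, 17L)
  expect_equal(a$nmd_rate, 100 * 16 / 17)
  expect_equal(unname(a$nmd_by_type["ES"]), 90)
  expect_equal(unname(a$ptc_median_by_type["ES"]), 37)
  expect_equal(sum(a$nmd_share_by_type), 100)
  b <- s$groups$significant
  expect_equal(b$nmd_rate, 80)
  expect_true(all(c("comparison", "statistic", "p_value", "test_name")
                  %in% names(s$tests)))

  ## order independence
  perm <- all_r[sample(nrow(all_r)), ]
  s2 <- summarize_cohort(perm, sig_r)
  expect_equal(s2$groups$all, a)

  expect_error(summarize_cohort(all_r[all_r$reason == "NOT_ON_CANONICAL", ],
                                sig_r), "no processed events")
})

test_that("simple rate arithmetic: 9 true of 10 processed is 90%", {
  r <- rbind(fake_results(9, "ES", TRUE), fake_results(1, "ES", FALSE))
  expect_equal(summarize_one(r)$nmd_rate, 90)
})

test_that("proportion comparison matches a closed-form chi-square oracle", {
  ## identical proportions: statistic 0, p = 1
  r <- compare_proportions(50, 100, 50, 100)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  ## hand-computed textbook formula on random 2x2 tables (1e-9 agreement)
  chisq_oracle <- function(k1, n1, k2, n2, yates) {
    O <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    adj <- if (yates) pmin(0.5, abs(O - E)) else 0
    X2 <- sum((abs(O - E) - adj)^2 / E)
    c(X2, stats::pchisq(X2, df = 1, lower.tail = FALSE))
  }
  set.seed(8)
  for (i in 1:100) {
    n1 <- sample(20:500, 1); n2 <- sample(20:500, 1)
    k1 <- rbinom(1, n1 - 2, runif(1, 0.1, 0.9)) + 1
    k2 <- rbinom(1, n2 - 2, runif(1, 0.1, 0.9)) + 1
    r <- compare_proportions(k1, n1, k2, n2)
    expect_equal(r$uncorrected$statistic,
                 chisq_oracle(k1, n1, k2, n2, FALSE)[1], tolerance = 1e-9)
    expect_equal(r$uncorrected$p_value,
                 chisq_oracle(k1, n1, k2, n2, FALSE)[2], tolerance = 1e-9)
    expect_equal(r$corrected$statistic,
                 chisq_oracle(k1, n1, k2, n2, TRUE)[1], tolerance = 1e-9)
  }

  ## Yates branch is taken exactly when an expected cell is below 5
  r <- compare_proportions(1, 5, 4, 5)
  expect_true(r$yates)
  expect_equal(r$test_name, "chi-square (Yates)")
  r <- compare_proportions(45, 50, 40, 50)
  expect_false(r$yates)
  expect_error(compare_proportions(5, 0, 1, 2), "positive")
})

test_that("psi-magnitude comparison gates on medians and rank-sum test", {
  mk <- function(d) data.frame(delta_psi = d)
  same <- compare_psi_magnitude(mk(c(0.1, 0.2, 0.3)), mk(c(-0.1, 0.2, -0.3)))
  expect_equal(same$median_a, same$median_b)
  expect_gt(same$p_value, 0.9)

  set.seed(5)
  a <- runif(200, 0, 0.4); b <- a + 0.3
  shifted <- compare_psi_magnitude(mk(a), mk(b))
  expect_lt(shifted$p_value, 0.001)
  expect_equal(shifted$median_b - shifted$median_a, 0.3, tolerance = 1e-9)

  single <- compare_psi_magnitude(mk(0.2), mk(-0.5))
  expect_equal(single$median_a, 0.2)
  expect_equal(single$median_b, 0.5)
  expect_true(is.finite(single$p_value))
})

test_that("NMD-false gene export is unique, sorted and skip-free", {
  r <- rbind(fake_results(2, "ES", FALSE, gene = c("GB", "GA")),
             fake_results(1, "ES", FALSE, gene = "GA"),
             fake_results(1, "ES", TRUE, gene = "GC"),
             fake_results(1, "ES", NA, reason = "NOT_ON_CANONICAL", gene = "GZ"))
  path <- tempfile()
  genes <- export_nmd_false_genes(r, path)
  expect_equal(readLines(path), c("GA", "GB"))
  all_true <- fake_results(3, "ES", TRUE)
  p2 <- tempfile()
  export_nmd_false_genes(all_true, p2)
  expect_equal(readLines(p2), character(0))
})

test_that("protein-direction rule reproduces the grancalcin-style call", {
  ev <- list(gene_id = "GCA", delta_psi = -0.25)
  nmd_true <- list(nmd = TRUE)
  ## non-significant DGE + less frequent splicing in B + NMD true
  call <- predict_protein_direction(list(log2fc = 0.4, padj = 0.6),
                                    ev, nmd_true)
  expect_equal(call$predicted_direction, "higher_in_B")
  ## symmetric case
  call <- predict_protein_direction(list(log2fc = 0.4, padj = 0.6),
                                    list(gene_id = "X", delta_psi = 0.3),
                                    nmd_true)
  expect_equal(call$predicted_direction, "lower_in_B")
  ## significant DGE or NMD false -> indeterminate
  expect_equal(predict_protein_direction(list(log2fc = 3, padj = 0.001),
                                         ev, nmd_true)$predicted_direction,
               "indeterminate")
  expect_equal(predict_protein_direction(list(log2fc = 0.4, padj = 0.6),
                                         ev, list(nmd = FALSE))$predicted_direction,
               "indeterminate")
  expect_equal(predict_protein_direction(NULL, ev, nmd_true)$predicted_direction,
               "higher_in_B")
})
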
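test_that("threshold rule reproduces the order-statistic oracle", {
  # brute force over candidate thresholds: healthy 1..20 at 95% specificity
  th <- fit_thresholds(tibble::tibble(CPA = 1:20), specificity = 0.95,
                       directions = c(CPA = "high"))
  expect_equal(th$threshold, 19)
  expect_equal(th$specificity_achieved, 0.95)
  # all healthy equal: threshold c, only values > c call positive
  th2 <- fit_thresholds(tibble::tibble(CPA = rep(3.3, 12)),
                        directions = c(CPA = "high"))
  expect_equal(th2$threshold, 3.3)
  expect_equal(th2$specificity_achieved, 1)
  # specificity 1 -> max(healthy), zero healthy false positives
  th3 <- fit_thresholds(tibble::tibble(CPA = 1:20), specificity = 1,
                        directions = c(CPA = "high"))
  expect_equal(th3$threshold, 20)
  # low direction mirrors high
  th4 <- fit_thresholds(tibble::tibble(CPA = 1:20), specificity = 0.95,
                        directions = c(CPA = "low"))
  expect_equal(th4$threshold, 2)
  expect_error(fit_thresholds(tibble::tibble(CPA = 1:5)),
               class = "ctfrag_calibration_error")
  expect_error(fit_thresholds(tibble::tibble(CPA = 1:20), specificity = 0.4),
               class = "ctfrag_config_error")
})

test_that("calibration specificity holds exactly by construction", {
  withr::with_seed(4, {
    for (n in c(20, 40, 57)) {
      v <- rnorm(n)
      th <- fit_thresholds(tibble::tibble(CPA = v), directions = c(CPA = "high"))
      expect_lte(sum(v > th$threshold), floor(0.05 * n))
      expect_gte(th$specificity_achieved, 0.95)
    }
  })
})

make_thresholds <- function(value = 1) {
  structure(tibble::tibble(
    marker = c("CPA", "CTCPA", "P126_135", "D126_135", "MDS", "ALU_CGN_NCG",
               "IWFAF"),
    direction = "high", threshold = value, specificity_target = 0.95,
    specificity_achieved = 0.95, n_healthy = 40L),
    class = c("cf_thresholds", "tbl_df", "tbl", "data.frame"))
}

marker_row <- function(...) {
  defaults <- list(sample_id = "s1", CPA = 0.5, CTCPA = 0.5, P126_135 = 0.5,
                   D126_135 = 0.5, MDS = 0.5, ALU_CGN_NCG = 0.5, IWFAF = 0.5)
  args <- utils::modifyList(defaults, list(...))
  tibble::as_tibble(args)
}

test_that("combination rules follow the and/or definitions", {
  th <- make_thresholds(1)
  # everything below threshold: all negative
  neg <- call_samples(marker_row(), th)
  expect_false(any(unlist(neg[grepl("_pos$", names(neg))])))
  expect_false(neg$ctdna_any)
  # only ctCPA positive: CNVs detectable, residual ctDNA positive
  ct <- call_samples(marker_row(CTCPA = 2), th)
  expect_true(ct$CTCPA_pos && ct$cnv_detect && ct$residual_ctdna && ct$ctdna_any)
  expect_false(ct$CPA_pos)
  # only MDS positive: detected overall but not by CNVs, no residual call
  md <- call_samples(marker_row(MDS = 2), th)
  expect_true(md$ctdna_any)
  expect_false(md$cnv_detect || md$residual_ctdna)
  # only IWFAF positive: residual ctDNA without CNVs
  iw <- call_samples(marker_row(IWFAF = 2), th)
  expect_true(iw$residual_ctdna && !iw$cnv_detect)
})

test_that("ties at the threshold call negative and NAs are not evaluable", {
  th <- make_thresholds(1)
  tie <- call_samples(marker_row(CPA = 1), th)
  expect_false(tie$CPA_pos)
  na <- call_samples(marker_row(CTCPA = NA_real_), th)
  expect_false(na$CTCPA_pos)
  expect_false(na$CTCPA_eval)
  expect_true(na$CPA_eval)
})

test_that("per-sample ctCPA thresholds override the global row", {
  th <- make_thresholds(1)
  ctth <- tibble::tibble(sample_id = "s1", threshold = 0.2)
  out <- call_samples(marker_row(CTCPA = 0.5), th, ctcpa_thresholds = ctth)
  expect_true(out$CTCPA_pos)
  out2 <- call_samples(marker_row(sample_id = "other", CTCPA = 0.5), th,
                       ctcpa_thresholds = ctth)
  expect_false(out2$CTCPA_pos)
})

test_that("union detection dominates every single marker", {
  withr::with_seed(6, {
    mk <- tibble::tibble(sample_id = sprintf("s%d", 1:100))
    for (m in c("CPA", "CTCPA", "P126_135", "D126_135", "MDS", "ALU_CGN_NCG",
                "IWFAF")) mk[[m]] <- rnorm(100)
    calls <- call_samples(mk, make_thresholds(0.5))
    per_marker <- sapply(grep("_pos$", names(calls), value = TRUE),
                         function(cl) mean(calls[[cl]]))
    expect_gte(mean(calls$ctdna_any), max(per_marker))
    expect_true(all(calls$ctdna_any[calls$residual_ctdna]))
    expect_true(all(calls$residual_ctdna[calls$cnv_detect]))
  })
})

test_that("longitudinal classification reproduces the truth table", {
  expect_equal(as.character(classify_longitudinal(FALSE, FALSE)), "double_negative")
  expect_equal(as.character(classify_longitudinal(TRUE, FALSE)), "clearance")
  expect_equal(as.character(classify_longitudinal(TRUE, TRUE)), "residual_positive")
  expect_equal(as.character(classify_longitudinal(FALSE, TRUE)), "residual_positive")
  expect_equal(as.character(classify_longitudinal(NA, TRUE)), "not_evaluable")
  expect_equal(as.character(classify_longitudinal(TRUE, NA)), "not_evaluable")
  # brute-force equivalence over the full grid
  grid <- expand.grid(b = c(TRUE, FALSE, NA), c4 = c(TRUE, FALSE, NA))
  got <- classify_longitudinal(grid$b, grid$c4)
  oracle <- mapply(function(b, c4) {
    if (is.na(b) || is.na(c4)) "not_evaluable"
    else if (c4) "residual_positive"
    else if (b) "clearance"
    else "double_negative"
  }, grid$b, grid$c4)
  expect_equal(as.character(got), unname(oracle))
})

test_that("group A/B assignment follows the integrated biomarker rule", {
  expect_equal(as.character(assign_group_ab(50, FALSE, FALSE)), "A")
  expect_equal(as.character(assign_group_ab(0, FALSE, FALSE)), "B")
  expect_equal(as.character(assign_group_ab(50, TRUE, FALSE)), "B")
  expect_equal(as.character(assign_group_ab(50, FALSE, TRUE)), "B")
  expect_equal(as.character(assign_group_ab(1, FALSE, FALSE)), "A")  # TPS >= 1
  expect_true(is.na(assign_group_ab(NA, FALSE, FALSE)))
  expect_true(is.na(assign_group_ab(50, NA, FALSE)))
  expect_true(is.na(assign_group_ab(50, FALSE, NA)))
  # brute-force equivalence over a grid
  grid <- expand.grid(tps = c(0, 0.5, 1, 50), d = c(TRUE, FALSE),
                      r = c(TRUE, FALSE))
  got <- assign_group_ab(grid$tps, grid$d, grid$r)
  oracle <- ifelse(grid$tps >= 1 & !grid$d & !grid$r, "A", "B")
  expect_equal(as.character(got), oracle)
})

test_that("quantile splits dichotomize at the empirical quantiles", {
  qs <- quantile_splits(1:8, quantiles = 0.5)
  expect_equal(unname(attr(qs, "cuts")), 4.5)
  expect_equal(which(qs$above_q50), 5:8)
  qs2 <- quantile_splits(1:10, quantiles = 0.9)
  expect_equal(sum(qs2$above_q90), 1)
  qs3 <- quantile_splits(rep(2, 10))
  expect_false(any(as.matrix(qs3[, -1])))
  expect_error(quantile_splits(1:5), class = "ctfrag_data_error")
})
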
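DEFAULT_MARKERS <- c("CPA", "CTCPA", "P126_135", "D126_135", "MDS",
                     "ALU_CGN_NCG", "IWFAF")

default_directions <- function() {
  setNames(rep("high", length(DEFAULT_MARKERS)), DEFAULT_MARKERS)
}

# order-statistic threshold guaranteeing >= `specificity` on the calibration
# values: the smallest (largest, for direction "low") observed value t such
# that the fraction of calibration values strictly beyond t is <= 1 - spec.
threshold_one_sided <- function(values, specificity, direction) {
  values <- values[!is.na(values)]
  n <- length(values)
  allowed <- floor((1 - specificity) * n)
  u <- sort(unique(values))
  if (direction == "high") {
    ng <- vapply(u, function(t) sum(values > t), integer(1))
    u[min(which(ng <= allowed))]
  } else {
    u <- rev(u)
    nl <- vapply(u, function(t) sum(values < t), integer(1))
    u[min(which(nl <= allowed))]
  }
}

#' Calibrate per-marker detection thresholds at fixed specificity
#'
#' For each marker, picks the least extreme healthy value `t` such that the
#' fraction of healthy calibration samples strictly beyond `t` does not
#' exceed `1 - specificity` (an exact order-statistic rule with no
#' interpolation; positivity is `value > t` for direction `"high"`,
#' `value < t` for `"low"`, so ties at the threshold call negative and the
#' specificity guarantee holds exactly on the calibration cohort).
#'
#' @param healthy_markers tibble of healthy samples with one column per
#'   marker (any subset of `CPA, CTCPA, P126_135, D126_135, MDS,
#'   ALU_CGN_NCG, IWFAF`).
#' @param specificity target specificity in (0.5, 1] (default 0.95).
#' @param directions named character vector, `"high"` or `"low"` per marker.
#' @param min_healthy minimum non-missing healthy values per marker.
#' @return tibble of class `cf_thresholds`: `marker`, `direction`,
#'   `threshold`, `specificity_target`, `specificity_achieved`, `n_healthy`;
#'   attribute `provenance` holds the calibration sample ids when present.
#' @export
fit_thresholds <- function(healthy_markers, specificity = 0.95,
                           directions = default_directions(),
                           min_healthy = 10) {
  if (specificity <= 0.5 || specificity > 1)
    abort("`specificity` must be in (0.5, 1]", class = "ctfrag_config_error")
  markers <- intersect(names(directions), names(healthy_markers))
  if (length(markers) == 0)
    abort("no marker columns found in `healthy_markers`",
          class = "ctfrag_config_error")
  rows <- purrr::map_dfr(markers, function(m) {
    v <- healthy_markers[[m]]
    v <- v[!is.na(v)]
    if (length(v) < min_healthy)
      abort(sprintf("marker %s has %d healthy values; >= %d required",
                    m, length(v), min_healthy),
            class = "ctfrag_calibration_error")
    t <- threshold_one_sided(v, specificity, directions[[m]])
    fp <- if (directions[[m]] == "high") sum(v > t) else sum(v < t)
    tibble::tibble(marker = m, direction = directions[[m]], threshold = t,
                   specificity_target = specificity,
                   specificity_achieved = 1 - fp / length(v),
                   n_healthy = length(v))
  })
  out <- structure(rows, class = c("cf_thresholds", class(rows)))
  attr(out, "provenance") <- healthy_markers[["sample_id"]]
  out
}

#' Call per-sample marker positivity and combined detection flags
#'
#' A marker is positive when its value lies strictly beyond its threshold in
#' the calibrated direction. Missing (not evaluable) markers count as
#' negative but are flagged. Combined flags follow the marker-combination
#' rules: `cnv_detect = CPA+ or CTCPA+`, `ctdna_any` = any marker positive,
#' `residual_ctdna = cnv_detect or IWFAF+`.
#'
#' @param markers tibble with `sample_id` and marker columns.
#' @param thresholds a [fit_thresholds()] object.
#' @param ctcpa_thresholds optional tibble (`sample_id`, `threshold`) of
#'   per-sample ctCPA thresholds from the subject-specific null
#'   ([ctcpa_null_threshold()]); overrides any global CTCPA row.
#' @return tibble with one row per sample: `<marker>_pos` and
#'   `<marker>_eval` logicals plus the combined flags.
#' @export
call_samples <- function(markers, thresholds, ctcpa_thresholds = NULL) {
  out <- tibble::tibble(sample_id = markers$sample_id)
  if ("subject_id" %in% names(markers)) out$subject_id <- markers$subject_id
  present <- character(0)
  for (m in DEFAULT_MARKERS) {
    if (!m %in% names(markers)) next
    v <- markers[[m]]
    th <- rep(NA_real_, nrow(markers))
    dir <- "high"
    row <- which(thresholds$marker == m)
    if (length(row) == 1) {
      th <- rep(thresholds$threshold[row], nrow(markers))
      dir <- thresholds$direction[row]
    }
    if (m == "CTCPA" && !is.null(ctcpa_thresholds)) {
      i <- match(markers$sample_id, ctcpa_thresholds$sample_id)
      th <- ifelse(is.na(i), th, ctcpa_thresholds$threshold[i])
    }
    evaluable <- !is.na(v) & !is.na(th)
    pos <- evaluable & (if (dir == "high") v > th else v < th)
    out[[paste0(m, "_pos")]] <- pos
    out[[paste0(m, "_eval")]] <- evaluable
    present <- c(present, m)
  }
  get_pos <- function(m) {
    if (paste0(m, "_pos") %in% names(out)) out[[paste0(m, "_pos")]]
    else rep(FALSE, nrow(out))
  }
  out$cnv_detect <- get_pos("CPA") | get_pos("CTCPA")
  any_pos <- rep(FALSE, nrow(out))
  for (m in present) any_pos <- any_pos | get_pos(m)
  out$ctdna_any <- any_pos
  out$residual_ctdna <- out$cnv_detect | get_pos("IWFAF")
  out
}

#' @rdname call_samples
#' @param marker_vector one-row marker tibble.
#' @export
call_sample <- function(marker_vector, thresholds, ctcpa_thresholds = NULL) {
  call_samples(marker_vector, thresholds, ctcpa_thresholds)
}

#' Classify longitudinal biomarker status
#'
#' Combines a subject's baseline and cycle-4 detection calls (by default on
#' the residual-ctDNA basis) into the monitoring categories:
#' negative/negative is `double_negative`, positive/negative is `clearance`
#' (detectable at baseline, cleared after 4 therapy cycles), and any subject
#' still positive at cycle 4 is `residual_positive`. Missing calls give
#' `not_evaluable`.
#'
#' @param baseline_pos,cycle4_pos logical vectors of per-subject positivity.
#' @return factor with levels `double_negative`, `clearance`,
#'   `residual_positive`, `not_evaluable`.
#' @export
classify_longitudinal <- function(baseline_pos, cycle4_pos) {
  lv <- c("double_negative", "clearance", "residual_positive", "not_evaluable")
  out <- dplyr::case_when(
    is.na(baseline_pos) | is.na(cycle4_pos) ~ "not_evaluable",
    cycle4_pos ~ "residual_positive",
    baseline_pos & !cycle4_pos ~ "clearance",
    TRUE ~ "double_negative")
  factor(out, levels = lv)
}

#' Assign integrated risk groups A/B
#'
#' Group A: PD-L1 tumor proportion score >= 1%, undetectable pre-treatment
#' D126-135, and no residual ctDNA after 4 therapy cycles. Group B: positive
#' for at least one of those cfDNA biomarkers, or TPS < 1%. Any missing
#' input yields `NA` (not evaluable).
#'
#' @param tps_percent PD-L1 TPS in percent, `[0, 100]`.
#' @param baseline_d126_pos logical, baseline D126-135 detectable.
#' @param cycle4_residual_pos logical, residual ctDNA after cycle 4.
#' @return factor with levels `A`, `B` (NA when not evaluable).
#' @export
assign_group_ab <- function(tps_percent, baseline_d126_pos, cycle4_residual_pos) {
  out <- dplyr::case_when(
    is.na(tps_percent) | is.na(baseline_d126_pos) | is.na(cycle4_residual_pos) ~
      NA_character_,
    tps_percent >= 1 & !baseline_d126_pos & !cycle4_residual_pos ~ "A",
    TRUE ~ "B")
  factor(out, levels = c("A", "B"))
}

#' Dichotomize a cohort at increasing baseline quantiles
#'
#' For each requested quantile of the cohort's pre-treatment values, splits
#' patients at that cut (`value > cut`). Empirical quantiles use the default
#' continuous definition (type 7).
#'
#' @param values numeric vector of baseline marker values (>= 8).
#' @param quantiles probabilities (default 0.25, 0.5, 0.75, 0.9).
#' @return tibble with `value` and one logical `above_qXX` column per
#'   quantile; attribute `cuts` stores the cut points.
#' @export
quantile_splits <- function(values, quantiles = c(0.25, 0.5, 0.75, 0.9)) {
  if (length(values) < 8)
    abort("quantile_splits needs >= 8 values", class = "ctfrag_data_error")
  cuts <- quantile(values, probs = quantiles, na.rm = TRUE, type = 7)
  out <- tibble::tibble(value = values)
  for (i in seq_along(quantiles)) {
    out[[sprintf("above_q%02.0f", 100 * quantiles[i])]] <- values > cuts[i]
  }
  attr(out, "cuts") <- setNames(as.numeric(cuts),
                                sprintf("q%02.0f", 100 * quantiles))
  out
}
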
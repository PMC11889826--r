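#' Validation experiments
#'
#' Self-contained simulation experiments that probe the pipeline's operating
#' characteristics on synthetic cohorts: held-out specificity of the
#' calibrated thresholds, marker dose response along coupled dilution
#' series, the sensitivity gain of multi-marker detection over CNV-only
#' analysis, the tumor-informed gain of ctCPA at very low tumor fractions,
#' and end-to-end hazard-ratio recovery through the full
#' simulate-score-calibrate-detect-survival chain. Each experiment is
#' deterministic given its seed.
#'
#' @name experiments
NULL

# healthy cohort with CNV panel, end reference and per-marker healthy values.
# When `reference` is supplied, the cohort's markers are computed against that
# independent reference, so its values are exchangeable with any future sample
# normalized the same way; reusing panel members for calibration would be
# optimistic for the depth- and end-position-derived markers.
calibration_cohort <- function(config, n_healthy, seed, alu = alu_intervals(config),
                               reference = NULL) {
  bins <- genome_bins(config$genome, config$bin_width)
  seeds <- make_seeds(seed, n_healthy)
  healthy <- lapply(seeds, function(sd) simulate_healthy_sample(config, seed = sd))
  if (is.null(reference)) reference <- build_healthy_reference(healthy, bins)
  profiles <- lapply(healthy, function(h)
    normalize_profile(bin_counts(h, bins), reference$panel))
  tab <- purrr::map_dfr(seq_along(healthy), function(i) {
    compute_markers(healthy[[i]], reference, alu = alu,
                    sample_id = sprintf("H%03d", i),
                    profile_norm = profiles[[i]])
  })
  list(config = config, bins = bins, alu = alu, healthy = healthy,
       ref = reference, profiles = profiles, markers = tab)
}

sample_markers <- function(fragments, cal, informative = NULL) {
  compute_markers(fragments, cal$ref, alu = cal$alu, informative = informative)
}

#' Held-out specificity of the calibrated detection thresholds
#'
#' Fits the per-marker 95%-specificity thresholds on a healthy calibration
#' cohort and measures each marker's false-positive rate on an independent
#' held-out healthy cohort. The ctCPA null is evaluated through an
#' informative segment set taken from one simulated CNV-positive baseline.
#'
#' @param seed integer seed.
#' @param n_calibration,n_holdout healthy cohort sizes.
#' @param n_reference size of the independent healthy cohort that builds the
#'   panel of normals and end-position reference; keeping it separate from
#'   the calibration cohort makes calibration and future samples
#'   exchangeable.
#' @param config simulation configuration.
#' @return tibble: `marker`, `threshold`, `fpr` (held-out false-positive
#'   rate), `n_holdout`.
#' @rdname experiments
#' @export
experiment_specificity_calibration <- function(seed, n_calibration = 40,
                                               n_holdout = 200, n_reference = 30,
                                               config = sim_config(seed = seed)) {
  kids <- make_seeds(seed, 4)
  # panel of normals and end reference come from an independent healthy
  # cohort, so calibration and held-out samples are exchangeable
  refc <- calibration_cohort(config, n_reference, seed = kids[4])
  cal <- calibration_cohort(config, n_calibration, seed = kids[1],
                            reference = refc$ref)
  # one representative informative set for the ctCPA projection
  base <- simulate_tumor_sample(config, 0.2, seed = kids[2])
  info <- select_informative_segments(
    segment_profile(normalize_profile(bin_counts(base, cal$bins), cal$ref$panel)))
  cal_ctcpa <- vapply(cal$profiles, function(p) ctcpa_score(p, info), numeric(1))
  healthy_tab <- cal$markers
  healthy_tab$CTCPA <- cal_ctcpa
  thresholds <- fit_thresholds(healthy_tab)

  hseeds <- make_seeds(kids[3], n_holdout)
  hold <- purrr::map_dfr(seq_len(n_holdout), function(i) {
    fr <- simulate_healthy_sample(config, seed = hseeds[i])
    m <- sample_markers(fr, cal, informative = info)
    m$sample_id <- sprintf("V%03d", i)
    m
  })
  calls <- call_samples(hold, thresholds)
  purrr::map_dfr(thresholds$marker, function(m) {
    tibble::tibble(marker = m,
                   threshold = thresholds$threshold[thresholds$marker == m],
                   fpr = mean(calls[[paste0(m, "_pos")]]),
                   n_holdout = n_holdout)
  })
}

#' Marker dose response along coupled dilution series
#'
#' Simulates replicate dilution series over a tumor-fraction grid (each
#' replicate reuses one seed across the grid, the in silico analogue of
#' diluting a single specimen), averages each marker across replicates per
#' tumor fraction, and reports the Spearman correlation between the grid and
#' those means.
#'
#' @param tf_grid tumor-fraction grid.
#' @param n_replicates dilution series per tumor fraction.
#' @param n_fragments fragments per sample.
#' @return tibble: `marker`, `rho`; attribute `means` holds the tf-by-marker
#'   mean matrix.
#' @rdname experiments
#' @export
experiment_dose_response <- function(seed, tf_grid = c(0, 0.01, 0.05, 0.1, 0.2),
                                     n_replicates = 20, n_fragments = 1e4,
                                     config = sim_config(n_fragments = n_fragments,
                                                         seed = seed)) {
  kids <- make_seeds(seed, 3)
  cal <- calibration_cohort(config, 20, seed = kids[1])
  seeds <- make_seeds(kids[2], n_replicates)
  bseeds <- make_seeds(kids[3], n_replicates)
  markers <- c("CPA", "CTCPA", "P126_135", "MDS", "IWFAF", "ALU_CGN_NCG")
  res <- array(NA_real_, c(n_replicates, length(tf_grid), length(markers)),
               dimnames = list(NULL, NULL, markers))
  for (r in seq_len(n_replicates)) {
    base <- simulate_tumor_sample(config, 0.2, seed = bseeds[r])
    info <- select_informative_segments(
      segment_profile(normalize_profile(bin_counts(base, cal$bins),
                                        cal$ref$panel)))
    for (j in seq_along(tf_grid)) {
      fr <- simulate_tumor_sample(config, tf_grid[j], seed = seeds[r])
      np <- normalize_profile(bin_counts(fr, cal$bins), cal$ref$panel)
      mono <- filter_mononucleosomal(fr)
      res[r, j, ] <- c(
        cpa_score(segment_profile(np)),
        if (nrow(info) > 0) ctcpa_score(np, info) else NA_real_,
        p126_135(mono),
        mds(end_motif_counts(mono)),
        iwfaf(mono, cal$ref$end_ref),
        alu_cgn_ncg_ratio(mono, cal$alu))
    }
  }
  means <- apply(res, c(2, 3), mean, na.rm = TRUE)
  rho <- apply(means, 2, function(m) cor(tf_grid, m, method = "spearman"))
  out <- tibble::tibble(marker = markers, rho = unname(rho))
  attr(out, "means") <- means
  attr(out, "tf_grid") <- tf_grid
  out
}

#' Multi-marker complementarity over CNV-only detection
#'
#' Half the simulated tumor samples carry the copy-number clone, half are
#' copy-neutral but fragmentomically shifted. Thresholds are calibrated on a
#' healthy cohort at `specificity` per marker; the experiment reports the
#' sensitivity of the all-marker union versus CNV-only detection and the
#' union's specificity on the calibration cohort.
#'
#' @param n_healthy healthy calibration size.
#' @param n_tumor total tumor samples (half copy-neutral).
#' @param tf tumor fraction of the tumor samples.
#' @param specificity per-marker calibration specificity.
#' @return list: `sens_union`, `sens_cnv`, `gain_pp` (percentage points),
#'   `union_specificity` (calibration cohort), `n_tumor`.
#' @rdname experiments
#' @export
experiment_complementarity <- function(seed, n_healthy = 100, n_tumor = 60,
                                       tf = 0.15, specificity = 0.99,
                                       n_reference = 30,
                                       config = sim_config(seed = seed)) {
  kids <- make_seeds(seed, 3)
  refc <- calibration_cohort(config, n_reference, seed = kids[3])
  cal <- calibration_cohort(config, n_healthy, seed = kids[1],
                            reference = refc$ref)
  thresholds <- fit_thresholds(
    dplyr::select(cal$markers, -dplyr::all_of("CTCPA")),
    specificity = specificity)
  cal_calls <- call_samples(cal$markers, thresholds)
  union_spec <- 1 - mean(cal_calls$ctdna_any)

  cn_neutral <- sim_config(genome = config$genome, bin_width = config$bin_width,
                           n_fragments = config$n_fragments,
                           cnv_segments = config$cnv_segments[0, ],
                           length_model = config$length_model,
                           motif_model = config$motif_model,
                           end_position_model = config$end_position_model,
                           alu_model = config$alu_model, seed = config$seed)
  seeds <- make_seeds(kids[2], n_tumor)
  tum <- purrr::map_dfr(seq_len(n_tumor), function(i) {
    cfg_i <- if (i <= n_tumor / 2) config else cn_neutral
    fr <- simulate_tumor_sample(cfg_i, tf, seed = seeds[i])
    m <- sample_markers(fr, cal)
    m$sample_id <- sprintf("T%03d", i)
    m
  })
  calls <- call_samples(tum, thresholds)
  list(sens_union = mean(calls$ctdna_any), sens_cnv = mean(calls$cnv_detect),
       gain_pp = 100 * (mean(calls$ctdna_any) - mean(calls$cnv_detect)),
       union_specificity = union_spec, n_tumor = n_tumor)
}

#' Tumor-informed detection gain of ctCPA over CPA
#'
#' Follow-up samples at very low tumor fractions are scored with CPA (healthy
#' 95% threshold) and with ctCPA through an informative segment set from a
#' higher-burden baseline of the same subject (per-set healthy null
#' threshold at the same specificity).
#'
#' @param n_followups number of simulated follow-up samples (split evenly
#'   over `tf_followup`).
#' @param tf_followup follow-up tumor fractions.
#' @param tf_baseline baseline tumor fraction used to learn the informative
#'   segments.
#' @return list: `sens_cpa`, `sens_ctcpa`, `n_followups`, per-tf breakdown.
#' @rdname experiments
#' @export
experiment_tumor_informed <- function(seed, n_followups = 50,
                                      tf_followup = c(0.01, 0.02),
                                      tf_baseline = 0.2, n_healthy = 40,
                                      n_reference = 30,
                                      config = sim_config(seed = seed)) {
  kids <- make_seeds(seed, 4)
  refc <- calibration_cohort(config, n_reference, seed = kids[4])
  cal <- calibration_cohort(config, n_healthy, seed = kids[1],
                            reference = refc$ref)
  cpa_h <- cal$markers$CPA
  t_cpa <- threshold_one_sided(cpa_h, 0.95, "high")
  tfs <- rep(tf_followup, length.out = n_followups)
  sb <- make_seeds(kids[2], n_followups)
  sf <- make_seeds(kids[3], n_followups)
  cpa_pos <- ctcpa_pos <- logical(n_followups)
  for (i in seq_len(n_followups)) {
    base <- simulate_tumor_sample(config, tf_baseline, seed = sb[i])
    info <- select_informative_segments(
      segment_profile(normalize_profile(bin_counts(base, cal$bins),
                                        cal$ref$panel)))
    nt <- ctcpa_null_threshold(info, cal$profiles)
    fu <- simulate_tumor_sample(config, tfs[i], seed = sf[i])
    np <- normalize_profile(bin_counts(fu, cal$bins), cal$ref$panel)
    cpa_pos[i] <- cpa_score(segment_profile(np)) > t_cpa
    ctcpa_pos[i] <- ctcpa_score(np, info) > nt$threshold
  }
  list(sens_cpa = mean(cpa_pos), sens_ctcpa = mean(ctcpa_pos),
       by_tf = tibble::tibble(tf = tfs, cpa = cpa_pos, ctcpa = ctcpa_pos),
       n_followups = n_followups)
}

#' End-to-end hazard-ratio recovery
#'
#' For each replicate: simulate a healthy calibration cohort and a patient
#' cohort whose PFS hazard is multiplied by `exp(log_hr)` for
#' residual-positive subjects (cycle-4 tumor fraction > 0), run the full
#' residual-ctDNA pipeline (CPA, tumor-informed ctCPA, iwFAF; thresholds
#' refit per replicate), and fit the univariate Cox model and log-rank test
#' for the *called* residual status.
#'
#' @param n_replicates seeded replicates.
#' @param n_subjects subjects per replicate.
#' @param n_healthy healthy calibration cohort per replicate.
#' @return tibble with one row per replicate: `hazard_ratio`, `ci_low`,
#'   `ci_high`, `logrank_p`, `sens`, `fpr`, `censoring`.
#' @rdname experiments
#' @export
experiment_hr_recovery <- function(seed, n_replicates = 20, n_subjects = 50,
                                   n_healthy = 57, n_reference = 30,
                                   config = sim_config(seed = seed)) {
  bins <- genome_bins(config$genome, config$bin_width)
  cm <- config$cohort_model
  rep_seeds <- make_seeds(seed, n_replicates)
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    rs <- rep_seeds[r]
    kids <- make_seeds(rs, n_healthy + n_reference + 3)
    rseeds <- kids[seq_len(n_reference)]
    hseeds <- kids[n_reference + seq_len(n_healthy)]
    # independent panel of normals + end reference, then an exchangeable
    # healthy calibration cohort normalized against it
    ref_samples <- lapply(rseeds, function(sd) simulate_healthy_sample(config, seed = sd))
    ref <- build_healthy_reference(ref_samples, bins)
    panel <- ref$panel
    end_ref <- ref$end_ref
    healthy <- lapply(hseeds, function(sd) simulate_healthy_sample(config, seed = sd))
    norm_h <- lapply(healthy, function(h)
      normalize_profile(bin_counts(h, bins), panel))
    mono_h <- lapply(healthy, filter_mononucleosomal)
    cpa_h <- vapply(norm_h, function(p) cpa_score(segment_profile(p)), numeric(1))
    iw_h <- vapply(mono_h, function(m) iwfaf(m, end_ref), numeric(1))
    t_cpa <- threshold_one_sided(cpa_h, 0.95, "high")
    t_iw <- threshold_one_sided(iw_h, 0.95, "high")

    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(kids[n_reference + n_healthy + 1])
    base_tf <- runif(n_subjects, cm$baseline_tf[1], cm$baseline_tf[2])
    responder <- runif(n_subjects) < cm$responder_prob
    c4_tf <- base_tf * ifelse(responder, 0, cm$residual_factor)
    oc <- simulate_outcomes(c4_tf > 0, config$outcome_model)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

    sb <- make_seeds(kids[n_reference + n_healthy + 2], n_subjects)
    sf <- make_seeds(kids[n_reference + n_healthy + 3], n_subjects)
    resid <- logical(n_subjects)
    for (i in seq_len(n_subjects)) {
      fu <- simulate_tumor_sample(config, c4_tf[i], seed = sf[i])
      np <- normalize_profile(bin_counts(fu, bins), panel)
      pos <- cpa_score(segment_profile(np)) > t_cpa ||
        iwfaf(filter_mononucleosomal(fu), end_ref) > t_iw
      if (!pos) {
        base <- simulate_tumor_sample(config, base_tf[i], seed = sb[i])
        sgb <- segment_profile(normalize_profile(bin_counts(base, bins), panel))
        if (cpa_score(sgb) > t_cpa) {
          info <- select_informative_segments(sgb)
          if (nrow(info) > 0) {
            nt <- ctcpa_null_threshold(info, norm_h)
            pos <- ctcpa_score(np, info) > nt$threshold
          }
        }
      }
      resid[i] <- pos
    }
    d <- tibble::tibble(pfs = oc$pfs_months, ev = oc$pfs_event, resid = resid)
    td <- tidy(cox_fit(d, "pfs", "ev", "resid"))
    lr <- km_logrank(d$pfs, d$ev, d$resid)
    truth <- c4_tf > 0
    tibble::tibble(replicate = r, hazard_ratio = td$hazard_ratio,
                   ci_low = td$ci_low, ci_high = td$ci_high,
                   logrank_p = lr$p_value, sens = mean(resid[truth]),
                   fpr = mean(resid[!truth]), censoring = mean(!oc$pfs_event))
  })
}
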
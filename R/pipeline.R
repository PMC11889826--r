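#' Run the full ctDNA quantification and monitoring pipeline
#'
#' End-to-end orchestration on a synthetic cohort: simulate, profile
#' copy number, score CPA/ctCPA, compute the fragmentomic markers, calibrate
#' healthy thresholds at fixed specificity, call per-sample and combined
#' positivity, classify longitudinal status and risk groups A/B, and fit the
#' survival models for the marker-defined strata. Optionally writes the
#' report bundle (score table, thresholds YAML, call matrix, longitudinal
#' categories, survival fits, manifest) to `out_dir`; every output records
#' the configuration hash, and a rerun into the same directory refuses to
#' mix hashes.
#'
#' @param config a [sim_config()].
#' @param specificity target per-marker specificity (default 0.95).
#' @param use_alu compute the Alu CGN/NCG marker (FALSE skips it with a
#'   warning, all other markers are still computed).
#' @param z_min,min_bins informative-segment selection parameters.
#' @param out_dir optional output directory for the report bundle.
#' @return list of class `ctfrag_run`: `scores`, `thresholds`,
#'   `ctcpa_thresholds`, `calls`, `longitudinal`, `groups`, `response`,
#'   `survival_fits`, `correlations`, `clinical`, `truth`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), specificity = 0.95,
                         use_alu = TRUE, z_min = 3, min_bins = 3,
                         out_dir = NULL) {
  cohort <- simulate_cohort(config)
  bins <- genome_bins(config$genome, config$bin_width)
  alu <- if (use_alu) alu_intervals(config) else NULL
  if (!use_alu)
    warn("Alu intervals not supplied: ALU_CGN_NCG marker skipped; all other markers computed")

  meta <- cohort$samples
  healthy_idx <- which(meta$timepoint == "healthy")
  ref <- build_healthy_reference(meta$fragments[healthy_idx], bins)

  stage <- function(what, sample_id, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s failed for sample %s: %s", what, sample_id,
                    conditionMessage(e)), parent = e)
    })
  }

  # per-sample profiling and segmentation (all samples)
  norms <- vector("list", nrow(meta))
  segs <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    norms[[i]] <- stage("cnv_profile", meta$sample_id[i], {
      normalize_profile(bin_counts(meta$fragments[[i]], bins), ref$panel)
    })
    segs[[i]] <- stage("segment", meta$sample_id[i], segment_profile(norms[[i]]))
  }

  # healthy marker table and global thresholds (ctCPA handled per subject)
  healthy_markers <- purrr::map_dfr(healthy_idx, function(i) {
    stage("markers", meta$sample_id[i], {
      compute_markers(meta$fragments[[i]], ref, alu = alu,
                      sample_id = meta$sample_id[i],
                      profile_norm = norms[[i]], segments = segs[[i]])
    })
  })
  na_only <- DEFAULT_MARKERS[colSums(!is.na(healthy_markers[DEFAULT_MARKERS])) == 0]
  thresholds <- fit_thresholds(
    dplyr::select(healthy_markers, -dplyr::all_of(na_only)),
    specificity = specificity)

  # informative segment sets for subjects with a CNV-detectable baseline
  cpa_threshold <- thresholds$threshold[thresholds$marker == "CPA"]
  informative <- list()
  ctcpa_th <- list()
  for (sid in cohort$truth$subject_id) {
    b <- which(meta$subject_id == sid & meta$timepoint == "baseline")
    if (length(b) != 1) next
    base_cpa <- cpa_score(segs[[b]])
    if (base_cpa <= cpa_threshold) next
    info <- select_informative_segments(segs[[b]], z_min = z_min,
                                        min_bins = min_bins,
                                        source_sample_id = meta$sample_id[b])
    if (nrow(info) == 0) next
    informative[[sid]] <- info
    null <- ctcpa_null_threshold(info, ref$healthy_profiles, specificity)
    ids <- meta$sample_id[meta$subject_id == sid & meta$timepoint != "healthy"]
    ctcpa_th[[sid]] <- tibble::tibble(sample_id = ids, subject_id = sid,
                                      threshold = null$threshold)
  }
  ctcpa_thresholds <- if (length(ctcpa_th)) dplyr::bind_rows(ctcpa_th) else
    tibble::tibble(sample_id = character(), subject_id = character(),
                   threshold = numeric())

  # marker vectors for all samples
  patient_idx <- which(meta$timepoint != "healthy")
  patient_markers <- purrr::map_dfr(patient_idx, function(i) {
    sid <- meta$subject_id[i]
    stage("markers", meta$sample_id[i], {
      compute_markers(meta$fragments[[i]], ref, alu = alu,
                      informative = informative[[sid]],
                      sample_id = meta$sample_id[i],
                      profile_norm = norms[[i]], segments = segs[[i]])
    })
  })
  scores <- dplyr::bind_rows(
    dplyr::mutate(healthy_markers,
                  subject_id = NA_character_, timepoint = "healthy"),
    dplyr::mutate(patient_markers,
                  subject_id = meta$subject_id[patient_idx],
                  timepoint = meta$timepoint[patient_idx])) %>%
    dplyr::left_join(dplyr::select(meta, "sample_id", "tf"), by = "sample_id")

  calls <- call_samples(
    dplyr::filter(scores, .data$timepoint != "healthy"),
    thresholds, ctcpa_thresholds = ctcpa_thresholds)

  # longitudinal classification on the residual-ctDNA basis
  by_tp <- function(tp, col) {
    ids <- paste0(cohort$truth$subject_id, "_", tp)
    calls[[col]][match(ids, calls$sample_id)]
  }
  base_res <- by_tp("baseline", "residual_ctdna")
  c4_res <- by_tp("cycle4", "residual_ctdna")
  base_d126 <- by_tp("baseline", "D126_135_pos")
  longitudinal <- tibble::tibble(
    subject_id = cohort$truth$subject_id,
    baseline_residual = base_res, cycle4_residual = c4_res,
    category = classify_longitudinal(base_res, c4_res))
  groups <- tibble::tibble(
    subject_id = cohort$truth$subject_id,
    group_ab = assign_group_ab(cohort$clinical$pd_l1_tps, base_d126, c4_res))

  clinical <- cohort$clinical %>%
    dplyr::left_join(longitudinal, by = "subject_id") %>%
    dplyr::left_join(groups, by = "subject_id") %>%
    dplyr::mutate(response = dichotomize_response(.data$pfs_months, .data$pfs_event),
                  group_b = .data$group_ab == "B")

  fit_safe <- function(label, expr) {
    expr <- substitute(expr)
    tryCatch(suppressWarnings(eval.parent(expr)), error = function(e) {
      inform(sprintf("survival fit `%s` skipped: %s", label, conditionMessage(e)))
      NULL
    })
  }
  survival_fits <- list(
    pfs_residual_cox = fit_safe("pfs_residual_cox",
      cox_fit(clinical, "pfs_months", "pfs_event", "cycle4_residual")),
    pfs_residual_logrank = fit_safe("pfs_residual_logrank",
      km_logrank(clinical$pfs_months, clinical$pfs_event,
                 clinical$cycle4_residual)),
    pfs_group_cox = fit_safe("pfs_group_cox",
      cox_fit(clinical, "pfs_months", "pfs_event", "group_b")),
    os_residual_cox = fit_safe("os_residual_cox",
      cox_fit(clinical, "os_months", "os_event", "cycle4_residual")))

  base_scores <- scores %>%
    dplyr::filter(.data$timepoint == "baseline") %>%
    dplyr::arrange(match(.data$subject_id, clinical$subject_id))
  correlations <- fit_safe("correlations", {
    correlation_matrix(
      dplyr::select(base_scores, dplyr::any_of(DEFAULT_MARKERS)),
      dplyr::select(clinical, dplyr::any_of(c("ldh", "crp", "hemoglobin",
                                              "creatinine", "nlr", "platelets"))))
  })

  manifest <- list(config_hash = rlang::hash(unclass(config)),
                   seed = config$seed,
                   n_samples = nrow(meta),
                   n_subjects = nrow(cohort$truth),
                   package_version = as.character(utils::packageVersion("ctfrag")))

  run <- structure(list(scores = scores, thresholds = thresholds,
                        ctcpa_thresholds = ctcpa_thresholds, calls = calls,
                        longitudinal = longitudinal, groups = groups,
                        clinical = clinical, truth = cohort$truth,
                        survival_fits = survival_fits,
                        correlations = correlations, manifest = manifest),
                   class = "ctfrag_run")
  if (!is.null(out_dir)) write_run_bundle(run, out_dir)
  run
}

#' @export
print.ctfrag_run <- function(x, ...) {
  cat("<ctfrag_run>\n")
  cat(sprintf("  %d samples scored, %d subjects; config %s\n",
              nrow(x$scores), nrow(x$truth), x$manifest$config_hash))
  invisible(x)
}

write_run_bundle <- function(run, out_dir) {
  hash <- run$manifest$config_hash
  manifest_path <- file.path(out_dir, "manifest.yaml")
  if (file.exists(manifest_path)) {
    old <- yaml::read_yaml(manifest_path)
    if (!identical(old$config_hash, hash))
      abort(sprintf(
        "output directory %s holds results for config %s; refusing to mix with %s",
        out_dir, old$config_hash, hash), class = "ctfrag_config_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    writeLines(sprintf("# config_hash=%s", hash), path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  }
  tsv(run$scores, "scores.tsv")
  tsv(run$calls, "calls.tsv")
  pos_cols <- grep("_pos$", names(run$calls), value = TRUE)
  tsv(run$calls[, c("sample_id", pos_cols, "cnv_detect", "ctdna_any",
                    "residual_ctdna")], "call_matrix.tsv")
  tsv(run$longitudinal, "longitudinal.tsv")
  readr::write_csv(dplyr::select(run$clinical, -dplyr::any_of("fragments")),
                   file.path(out_dir, "clinical.csv"), progress = FALSE)
  lr <- run$survival_fits$pfs_residual_logrank
  if (inherits(lr, "cf_logrank")) tsv(tidy(lr), "km_curves.tsv")
  fits <- purrr::imap_dfr(run$survival_fits, function(f, nm) {
    if (is.null(f) || !inherits(f, "cf_cox")) return(tibble::tibble())
    dplyr::mutate(tidy(f), fit = nm, .before = 1)
  })
  tsv(fits, "survival_fits.tsv")
  yaml::write_yaml(c(run$manifest, list(
    thresholds = purrr::transpose(as.list(run$thresholds)))),
    file.path(out_dir, "thresholds.yaml"))
  yaml::write_yaml(run$manifest, manifest_path)
  invisible(out_dir)
}
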
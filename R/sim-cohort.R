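#' Simulate a synthetic cfDNA monitoring cohort
#'
#' Generates healthy controls plus NSCLC-like subjects sampled at therapy
#' baseline, after four therapy cycles, and (for a random subset) at disease
#' progression, together with a clinical table whose progression-free and
#' overall survival depend on the ground-truth residual-disease flag through
#' the configured proportional-hazards outcome model.
#'
#' Cycle-4 tumor fraction is `baseline tf * response factor` (0 for
#' responders, `residual_factor` otherwise); a subject's residual truth flag
#' is `cycle-4 tf > 0`, and their PFS hazard is multiplied by
#' `exp(log_hr_residual)` when that flag is set. OS is PFS plus an independent
#' exponential post-progression time; both endpoints share one censoring time
#' (independent exponential, truncated at the administrative horizon).
#'
#' @param config a [sim_config()]; cohort sizes and outcome parameters come
#'   from its `cohort_model` and `outcome_model`.
#' @param n_healthy,n_subjects optional overrides of the cohort design.
#' @return A list of class `cf_cohort` with elements:
#'   \describe{
#'     \item{samples}{tibble: `sample_id`, `subject_id`, `timepoint`
#'       (healthy/baseline/cycle4/progression), `tf`, `seed`, and a
#'       `fragments` list-column of fragment tibbles.}
#'     \item{clinical}{one row per subject: demographics, PD-L1 TPS,
#'       laboratory values, `pfs_months`/`pfs_event`, `os_months`/`os_event`.}
#'     \item{truth}{per-subject ground truth: baseline and cycle-4 tumor
#'       fractions, responder and residual flags.}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
simulate_cohort <- function(config, n_healthy = NULL, n_subjects = NULL) {
  if (!inherits(config, "cf_sim_config")) validate_sim_config(config)
  cm <- config$cohort_model
  om <- config$outcome_model
  if (is.null(n_healthy)) n_healthy <- cm$n_healthy
  if (is.null(n_subjects)) n_subjects <- cm$n_subjects

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  subject_id <- sprintf("S%03d", seq_len(n_subjects))
  baseline_tf <- runif(n_subjects, cm$baseline_tf[1], cm$baseline_tf[2])
  responder <- runif(n_subjects) < cm$responder_prob
  response_factor <- ifelse(responder, 0, cm$residual_factor)
  cycle4_tf <- baseline_tf * response_factor
  has_progression <- runif(n_subjects) < cm$progression_prob
  progression_tf <- pmin(baseline_tf * cm$progression_factor, 0.95)
  residual_positive <- cycle4_tf > 0

  # clinical covariates
  age <- round(rnorm(n_subjects, 65, 8))
  sex <- sample(c("female", "male"), n_subjects, replace = TRUE)
  histology <- sample(c("adenocarcinoma", "squamous"), n_subjects,
                      replace = TRUE, prob = c(0.7, 0.3))
  therapy <- sample(c("PD-(L)1 mono", "chemo-immunotherapy"), n_subjects,
                    replace = TRUE)
  pd_l1_tps <- sample(c(0, 0, 1, 5, 25, 60, 90), n_subjects, replace = TRUE)
  ldh <- round(exp(rnorm(n_subjects, log(220), 0.3)), 1)
  crp <- round(exp(rnorm(n_subjects, log(8), 0.8)), 1)
  hemoglobin <- round(rnorm(n_subjects, 13, 1.5), 1)
  creatinine <- round(rnorm(n_subjects, 0.9, 0.15), 2)
  nlr <- round(exp(rnorm(n_subjects, log(4), 0.4)), 1)
  platelets <- round(rnorm(n_subjects, 280, 60))

  # outcomes: exponential PFS with multiplicative hazard for residual disease
  oc <- simulate_outcomes(residual_positive, om)
  pfs_months <- oc$pfs_months
  pfs_event <- oc$pfs_event
  os_months <- oc$os_months
  os_event <- oc$os_event

  meta <- dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("H%03d", seq_len(n_healthy)),
                   subject_id = NA_character_, timepoint = "healthy", tf = 0),
    tibble::tibble(sample_id = paste0(subject_id, "_baseline"),
                   subject_id = subject_id, timepoint = "baseline", tf = baseline_tf),
    tibble::tibble(sample_id = paste0(subject_id, "_cycle4"),
                   subject_id = subject_id, timepoint = "cycle4", tf = cycle4_tf),
    tibble::tibble(sample_id = paste0(subject_id[has_progression], "_progression"),
                   subject_id = subject_id[has_progression], timepoint = "progression",
                   tf = progression_tf[has_progression]))
  meta$seed <- make_seeds(config$seed, nrow(meta))
  meta$fragments <- purrr::map(seq_len(nrow(meta)), function(i) {
    simulate_tumor_sample(config, tf = meta$tf[i], seed = meta$seed[i],
                          sample_id = meta$sample_id[i])
  })

  clinical <- tibble::tibble(
    subject_id = subject_id, age = age, sex = sex, histology = histology,
    stage = "IV", therapy = therapy, pd_l1_tps = pd_l1_tps,
    ldh = ldh, crp = crp, hemoglobin = hemoglobin, creatinine = creatinine,
    nlr = nlr, platelets = platelets,
    pfs_months = pfs_months, pfs_event = pfs_event,
    os_months = os_months, os_event = os_event)

  truth <- tibble::tibble(
    subject_id = subject_id, baseline_tf = baseline_tf, cycle4_tf = cycle4_tf,
    responder = responder, residual_positive = residual_positive,
    has_progression = has_progression)

  structure(list(samples = meta, clinical = clinical, truth = truth,
                 config = config),
            class = "cf_cohort")
}

#' Simulate survival outcomes for a set of subjects
#'
#' Exponential progression-free survival with a multiplicative hazard
#' `exp(log_hr_residual)` for residual-positive subjects, independent
#' exponential censoring truncated at the administrative horizon, and
#' overall survival as PFS plus an exponential post-progression time (always
#' `OS >= PFS`; both endpoints share the censoring time). Uses the current
#' RNG state; seed it upstream for reproducibility.
#'
#' @param residual_positive logical vector of ground-truth residual flags.
#' @param outcome_model an outcome model list ([default_outcome_model()]).
#' @return tibble with `pfs_months`, `pfs_event`, `os_months`, `os_event`.
#' @export
simulate_outcomes <- function(residual_positive, outcome_model = default_outcome_model()) {
  om <- outcome_model
  n <- length(residual_positive)
  rate <- om$baseline_hazard * exp(om$log_hr_residual * residual_positive)
  pfs_lat <- rexp(n) / rate
  cens <- pmin(rexp(n) / om$censor_rate, om$horizon)
  os_lat <- pfs_lat + rexp(n) / om$os_extra_rate
  tibble::tibble(pfs_months = pmin(pfs_lat, cens), pfs_event = pfs_lat <= cens,
                 os_months = pmin(os_lat, cens), os_event = os_lat <= cens)
}

#' @export
print.cf_cohort <- function(x, ...) {
  cat("<cf_cohort>\n")
  cat(sprintf("  %d samples (%d healthy, %d subjects), %d fragments each\n",
              nrow(x$samples), sum(x$samples$timepoint == "healthy"),
              nrow(x$clinical), x$config$n_fragments))
  invisible(x)
}
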
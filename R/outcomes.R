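#' Dichotomize clinical response by progression-free survival
#'
#' Durable clinical response (DCR) is PFS > `cut` months (observed or
#' censored beyond the cut); short clinical response (SCR) is progression or
#' death at or before `cut` months. Subjects censored at or before the cut
#' without an event cannot be classified and return `NA`.
#'
#' @param pfs_months numeric PFS in months.
#' @param pfs_event logical/0-1 event indicator (TRUE = progression/death).
#' @param cut boundary in months (default 12; exactly 12.0 with an event is
#'   SCR).
#' @return factor with levels `DCR`, `SCR` (NA = not evaluable).
#' @export
dichotomize_response <- function(pfs_months, pfs_event, cut = 12) {
  ev <- as.logical(pfs_event)
  out <- dplyr::case_when(
    is.na(pfs_months) | is.na(ev) ~ NA_character_,
    pfs_months > cut ~ "DCR",
    ev ~ "SCR",
    TRUE ~ NA_character_)
  factor(out, levels = c("DCR", "SCR"))
}

#' Two-sided log-rank test with exported survival curves
#'
#' Standard log-rank comparison of Kaplan-Meier curves across groups
#' (delegates to [survival::survdiff()]), returning the test together with
#' tidy curve coordinates for plotting or export.
#'
#' @param time,event survival times and event indicators.
#' @param group group labels (>= 2 groups, >= 1 event overall).
#' @return object of class `cf_logrank` with `statistic`, `df`, `p_value`,
#'   `n` per group, and a `curves` tibble (`group`, `time`, `n_risk`,
#'   `n_event`, `surv`).
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2)
    abort("km_logrank needs >= 2 groups", class = "ctfrag_data_error")
  if (sum(event) < 1)
    abort("km_logrank needs >= 1 event", class = "ctfrag_data_error")
  df <- data.frame(time = time, event = as.integer(event), group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  stat <- as.numeric(sd$chisq)
  dfree <- length(sd$n) - 1
  p <- pchisq(stat, df = dfree, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- tibble::tibble(group = sub("^group=", "", strata), time = sf$time,
                           n_risk = sf$n.risk, n_event = sf$n.event,
                           surv = sf$surv)
  structure(list(statistic = stat, df = dfree, p_value = p,
                 n = setNames(as.integer(sd$n), sub("^group=", "", names(sd$n))),
                 curves = curves),
            class = "cf_logrank")
}

#' @export
print.cf_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.3f on %d df, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @method tidy cf_logrank
#' @export
tidy.cf_logrank <- function(x, ...) x$curves

#' @method glance cf_logrank
#' @export
glance.cf_logrank <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n = sum(x$n))
}

#' Cox proportional-hazards fit with tidy hazard ratios
#'
#' Partial-likelihood Cox regression (delegates to [survival::coxph()]) for
#' marker-defined strata, univariable or adjusted. Reports per-term hazard
#' ratios with Wald 95% confidence intervals and p-values via [tidy()], and
#' model-level summaries via [glance()]. Apparent separation (diverging
#' coefficients) raises a diagnostic error with group counts.
#'
#' @param data data frame with the survival columns and covariates.
#' @param time,event column names of the time and event variables.
#' @param covariates character vector of covariate column names; the first
#'   is conventionally the marker of interest.
#' @return object of class `cf_cox`.
#' @export
cox_fit <- function(data, time, event, covariates) {
  if (length(covariates) < 1) abort("cox_fit needs >= 1 covariate")
  n_events <- sum(data[[event]])
  if (n_events < length(covariates) + 1)
    abort(sprintf("cox_fit: %d events for %d covariates", n_events,
                  length(covariates)),
          class = "ctfrag_data_error")
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = data)
  if (any(!is.finite(stats::coef(fit))) || any(abs(stats::coef(fit)) > 15)) {
    counts <- paste(vapply(covariates, function(cv) {
      paste0(cv, ": ", paste(capture_counts(data[[cv]]), collapse = "/"))
    }, ""), collapse = "; ")
    abort(sprintf("cox_fit did not converge (possible separation); group counts: %s",
                  counts),
          class = "ctfrag_data_error")
  }
  structure(list(fit = fit, data_n = nrow(data), n_events = n_events,
                 covariates = covariates),
            class = "cf_cox")
}

capture_counts <- function(x) {
  if (is.numeric(x) && length(unique(stats::na.omit(x))) > 4) return(length(x))
  as.integer(table(x))
}

#' @export
print.cf_cox <- function(x, ...) {
  cat(sprintf("Cox model (%d subjects, %d events)\n", x$data_n, x$n_events))
  print(tidy(x))
  invisible(x)
}

#' @describeIn cox_fit per-term hazard ratios, 95% CI and Wald p-values.
#' @param x a `cf_cox` object.
#' @param ... unused.
#' @method tidy cf_cox
#' @export
tidy.cf_cox <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  ci <- s$conf.int
  tibble::tibble(term = rownames(co),
                 estimate = co[, "coef"],
                 hazard_ratio = ci[, "exp(coef)"],
                 ci_low = ci[, "lower .95"],
                 ci_high = ci[, "upper .95"],
                 std_error = co[, "se(coef)"],
                 p_value = co[, "Pr(>|z|)"])
}

#' @describeIn cox_fit model-level summary (n, events, concordance,
#'   likelihood-ratio p).
#' @method glance cf_cox
#' @export
glance.cf_cox <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(n = x$data_n, n_events = x$n_events,
                 concordance = as.numeric(s$concordance[1]),
                 logtest_p = as.numeric(s$logtest["pvalue"]))
}

#' Rank-based group comparison
#'
#' Two-sided Mann-Whitney U test for independent samples or Wilcoxon signed
#' rank test for paired samples. Degenerate inputs (all values identical, or
#' all paired differences zero) return p = 1 with a flag instead of an
#' error.
#'
#' @param values_a,values_b numeric vectors (>= 3 values, or >= 3 pairs when
#'   `paired`).
#' @param paired paired test (default FALSE).
#' @return one-row tibble: `p_value`, `method`, `degenerate`.
#' @export
group_compare <- function(values_a, values_b, paired = FALSE) {
  if (paired && length(values_a) != length(values_b))
    abort("paired comparison needs equal-length vectors", class = "ctfrag_data_error")
  if (length(values_a) < 3 || length(values_b) < 3)
    abort("group_compare needs >= 3 values per group", class = "ctfrag_data_error")
  method <- if (paired) "wilcoxon_paired" else "mann_whitney"
  degenerate <- if (paired) all(values_a == values_b)
                else length(unique(c(values_a, values_b))) == 1
  if (degenerate)
    return(tibble::tibble(p_value = 1, method = method, degenerate = TRUE))
  p <- suppressWarnings(
    wilcox.test(values_a, values_b, paired = paired, exact = NULL)$p.value)
  tibble::tibble(p_value = p, method = method, degenerate = FALSE)
}

#' Spearman correlation matrix with significance bands
#'
#' Pairwise Spearman rank correlations between marker scores and (e.g.)
#' laboratory values on complete pairs, banded as `none` (|rho| < 0.25),
#' `moderate` (0.25 <= |rho| < 0.7) or `strong` (|rho| >= 0.7) when p <
#' `alpha`; cells with fewer than `min_pairs` complete pairs are marked not
#' evaluable.
#'
#' @param score_table,lab_table data frames with matched rows (same
#'   samples); all numeric columns are crossed.
#' @param min_pairs minimum complete pairs per cell (default 5).
#' @param alpha significance level for banding (default 0.05).
#' @return long tibble: `score`, `lab`, `n`, `rho`, `p_value`, `band`.
#' @export
correlation_matrix <- function(score_table, lab_table, min_pairs = 5,
                               alpha = 0.05) {
  sc <- dplyr::select(tibble::as_tibble(score_table), dplyr::where(is.numeric))
  lb <- dplyr::select(tibble::as_tibble(lab_table), dplyr::where(is.numeric))
  if (nrow(sc) != nrow(lb))
    abort("score and lab tables must have matched rows", class = "ctfrag_data_error")
  grid <- tidyr::expand_grid(score = names(sc), lab = names(lb))
  purrr::pmap_dfr(grid, function(score, lab) {
    x <- sc[[score]]
    y <- lb[[lab]]
    ok <- complete.cases(x, y)
    n <- sum(ok)
    if (n < min_pairs)
      return(tibble::tibble(score = score, lab = lab, n = n, rho = NA_real_,
                            p_value = NA_real_, band = "not_evaluable"))
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                    exact = FALSE))
    rho <- as.numeric(ct$estimate)
    p <- ct$p.value
    band <- if (is.na(p) || p >= alpha || abs(rho) < 0.25) "none"
            else if (abs(rho) >= 0.7) "strong" else "moderate"
    tibble::tibble(score = score, lab = lab, n = n, rho = rho, p_value = p,
                   band = band)
  })
}
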
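#' Fragment length distribution plot
#'
#' Histogram of fragment lengths with the 126-135 bp short-fragment window
#' shaded, the standard first look at a plasma sample's size profile.
#'
#' @param fragments fragment tibble.
#' @param window length window to highlight (bp).
#' @param binwidth histogram bin width (bp).
#' @return a ggplot object.
#' @export
plot_fragment_lengths <- function(fragments, window = c(126, 135), binwidth = 2) {
  ggplot2::ggplot(fragments, ggplot2::aes(x = .data$length)) +
    ggplot2::annotate("rect", xmin = window[1], xmax = window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick") +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::coord_cartesian(xlim = c(50, 400)) +
    ggplot2::labs(x = "fragment length (bp)", y = "fragments") +
    ggplot2::theme_minimal()
}

#' Genome-wide copy-ratio profile plot
#'
#' Per-bin log2 copy ratios with the fitted segment means overlaid.
#'
#' @param profile_norm normalized bin profile ([normalize_profile()]).
#' @param segments optional segment tibble ([segment_profile()]).
#' @return a ggplot object.
#' @export
plot_copy_profile <- function(profile_norm, segments = NULL) {
  p <- ggplot2::ggplot(dplyr::filter(profile_norm, .data$usable),
                       ggplot2::aes(x = .data$start / 1e6, y = .data$log2_ratio)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "log2 copy ratio") +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    p <- p + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$mean_ratio, yend = .data$mean_ratio),
      color = "firebrick", linewidth = 1)
  }
  p
}

#' Kaplan-Meier plot for marker-defined strata
#'
#' @param time,event,group survival data and stratum labels.
#' @return a ggplot object (step curves per stratum).
#' @export
plot_km <- function(time, event, group) {
  lr <- km_logrank(time, event, group)
  anchor <- lr$curves %>%
    dplyr::distinct(.data$group) %>%
    dplyr::mutate(time = 0, surv = 1)
  curves <- dplyr::bind_rows(anchor, lr$curves)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$surv,
                                       color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "survival probability",
                  subtitle = sprintf("log-rank p = %.3g", lr$p_value)) +
    ggplot2::theme_minimal()
}

#' Forest plot of a Cox fit
#'
#' @param object a [cox_fit()] result.
#' @param ... unused.
#' @return a ggplot object showing hazard ratios with 95% CIs on a log scale.
#' @importFrom ggplot2 autoplot
#' @method autoplot cf_cox
#' @export
autoplot.cf_cox <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hazard_ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.15) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
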
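#' Copy-number abnormality (CPA) score
#'
#' Genome-wide chromosomal-instability summary of a segmented copy-ratio
#' profile: the length-weighted mean absolute segment log2 ratio,
#' `sum(L_s * |r_s|) / sum(L_s)` over the usable genome. Unitless, >= 0, and
#' linear in the segment amplitudes; detection uses it only relative to a
#' healthy-derived threshold.
#'
#' @param segments segment tibble from [segment_profile()].
#' @return scalar CPA score.
#' @export
cpa_score <- function(segments) {
  segs <- segments[!is.na(segments$mean_ratio), , drop = FALSE]
  if (nrow(segs) == 0 || sum(segs$length) <= 0)
    abort("cannot compute CPA on an empty segment profile",
          class = "ctfrag_data_error")
  sum(segs$length * abs(segs$mean_ratio)) / sum(segs$length)
}

#' Select patient-specific informative segments from a baseline profile
#'
#' Identifies the copy-number-aberrant segments of a (detectable) baseline
#' sample that later time points are projected onto for the tumor-informed
#' ctCPA score. A segment qualifies when its standardised mean deviation
#' `sqrt(n_bins) * |mean z|` reaches `z_min` and it spans at least
#' `min_bins` bins; its direction (gain/loss) is recorded. An empty result is
#' a valid signal that the baseline has no usable CNVs (the caller falls back
#' to CPA-only detection).
#'
#' @param segments baseline segment tibble from [segment_profile()].
#' @param z_min minimum standardised segment deviation (default 3).
#' @param min_bins minimum segment size in bins (default 3).
#' @param source_sample_id optional id of the baseline sample, recorded.
#' @return tibble of informative segments: `chrom`, `start`, `end`,
#'   `n_bins`, `length`, `sign` (+1 gain / -1 loss), `magnitude`
#'   (`|mean_ratio|` at baseline); attribute `source_sample_id`.
#' @export
select_informative_segments <- function(segments, z_min = 3, min_bins = 3,
                                        source_sample_id = NULL) {
  z_stat <- sqrt(segments$n_bins) * abs(segments$mean_z)
  keep <- !is.na(z_stat) & z_stat >= z_min & segments$n_bins >= min_bins
  out <- segments[keep, , drop = FALSE]
  out <- tibble::tibble(chrom = out$chrom, start = out$start, end = out$end,
                        n_bins = out$n_bins, length = out$length,
                        sign = sign(out$mean_ratio),
                        magnitude = abs(out$mean_ratio))
  attr(out, "source_sample_id") <- source_sample_id
  out
}

#' ctDNA-informed CPA (ctCPA) score
#'
#' Deviation from copy-number neutrality evaluated only at the
#' patient-specific informative segments: the length-weighted mean follow-up
#' bin ratio inside each segment, signed by the baseline direction,
#' `sum(L_s * sign_s * rbar_s) / sum(L_s)`. Positive when the follow-up
#' deviates in the baseline direction, about zero for copy-neutral plasma,
#' negative when inverted. Restricting to known aberrant regions and keeping
#' the sign suppresses background noise, analogous to tumor-tissue-informed
#' ctDNA assays.
#'
#' @param profile_norm follow-up normalized bin profile
#'   ([normalize_profile()]), on the same bins as the baseline.
#' @param informative informative segment set from
#'   [select_informative_segments()]; must be non-empty.
#' @return scalar ctCPA score (signed).
#' @export
ctcpa_score <- function(profile_norm, informative) {
  if (is.null(informative) || nrow(informative) == 0)
    abort("informative segment set is empty; ctCPA is undefined",
          class = "ctfrag_data_error")
  num <- 0
  den <- 0
  for (s in seq_len(nrow(informative))) {
    i <- profile_norm$chrom == informative$chrom[s] &
      profile_norm$start >= informative$start[s] &
      profile_norm$start < informative$end[s] &
      profile_norm$usable & !is.na(profile_norm$log2_ratio)
    if (!any(i)) next
    rbar <- mean(profile_norm$log2_ratio[i])
    num <- num + informative$length[s] * informative$sign[s] * rbar
    den <- den + informative$length[s]
  }
  if (den <= 0)
    abort("informative segments share no usable bins with the follow-up profile",
          class = "ctfrag_config_error")
  num / den
}

#' Healthy-cohort null distribution and threshold for a ctCPA projection
#'
#' Projects each healthy normalized profile through one subject's informative
#' segment set and calibrates the detection threshold at the requested
#' specificity with the same order-statistic rule used for the global
#' markers. Because the null scale of ctCPA depends on the informative set,
#' thresholds are per subject rather than pooled.
#'
#' @param informative informative segment set.
#' @param healthy_profiles list of healthy normalized bin profiles.
#' @param specificity target specificity (default 0.95).
#' @return list with `values` (healthy null scores) and `threshold`.
#' @export
ctcpa_null_threshold <- function(informative, healthy_profiles,
                                 specificity = 0.95) {
  vals <- vapply(healthy_profiles, function(p) ctcpa_score(p, informative),
                 numeric(1))
  list(values = vals, threshold = threshold_one_sided(vals, specificity, "high"))
}
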
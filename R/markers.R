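#' Build the healthy reference set for marker computation and calibration
#'
#' From a healthy cohort of fragment sets, constructs everything the markers
#' need: the copy-number panel of normals, the recurrent fragment
#' end-position reference, and the healthy P126-135 distribution (whose
#' median anchors D126-135).
#'
#' @param healthy_fragments list of healthy fragment tibbles.
#' @param bins genome bins ([genome_bins()]).
#' @param max_length mononucleosomal cutoff applied before the fragmentomic
#'   references (default 250 bp).
#' @param k,w end-position recurrence rule, see
#'   [build_end_position_reference()].
#' @return list of class `cf_reference`: `panel`, `end_ref`, `healthy_p126`,
#'   `bins`, `healthy_profiles` (normalized healthy bin profiles, reused for
#'   ctCPA null distributions).
#' @export
build_healthy_reference <- function(healthy_fragments, bins, max_length = 250,
                                    k = NULL, w = 0) {
  raw <- lapply(healthy_fragments, bin_counts, bins = bins)
  panel <- build_panel(raw)
  norm <- lapply(raw, normalize_profile, panel = panel)
  mono <- lapply(healthy_fragments, filter_mononucleosomal,
                 max_length = max_length)
  end_ref <- build_end_position_reference(mono, k = k, w = w)
  healthy_p126 <- vapply(mono, p126_135, numeric(1))
  structure(list(panel = panel, end_ref = end_ref,
                 healthy_p126 = healthy_p126, bins = bins,
                 healthy_profiles = norm, max_length = max_length),
            class = "cf_reference")
}

#' Compute the seven-marker vector for one sample
#'
#' Runs the full per-sample scoring: copy-number profiling (all fragment
#' lengths) for CPA and, when an informative segment set is supplied, ctCPA;
#' then the five fragmentomic markers on the mononucleosome-filtered set
#' (P126-135, D126-135, MDS, Alu CGN/NCG ratio, iwFAF).
#'
#' @param fragments one sample's fragment tibble.
#' @param reference a [build_healthy_reference()] object.
#' @param alu Alu interval tibble, or NULL to skip the Alu marker (reported
#'   as NA).
#' @param informative informative segment set of the sample's subject, or
#'   NULL (ctCPA reported as NA).
#' @param sample_id sample identifier for the output row.
#' @param min_fragments,min_alu_ends minimum-data guards.
#' @param profile_norm,segments optional precomputed normalized bin profile
#'   and segmentation for this sample (recomputed when NULL).
#' @return one-row tibble: `sample_id`, the seven marker columns, and QC
#'   counts (`n_fragments`, `n_mono`).
#' @export
compute_markers <- function(fragments, reference, alu = NULL,
                            informative = NULL, sample_id = NULL,
                            min_fragments = 1000, min_alu_ends = 200,
                            profile_norm = NULL, segments = NULL) {
  if (is.null(sample_id))
    sample_id <- if ("sample_id" %in% names(fragments) && nrow(fragments) > 0)
      fragments$sample_id[1] else NA_character_
  norm <- if (is.null(profile_norm))
    normalize_profile(bin_counts(fragments, reference$bins), reference$panel)
  else profile_norm
  segs <- if (is.null(segments)) segment_profile(norm) else segments
  cpa <- cpa_score(segs)
  ctcpa <- if (!is.null(informative) && nrow(informative) > 0)
    ctcpa_score(norm, informative) else NA_real_
  mono <- filter_mononucleosomal(fragments, max_length = reference$max_length)
  p126 <- p126_135(mono, min_fragments = min_fragments)
  d126 <- d126_135(p126, reference$healthy_p126)
  mds_score <- mds(end_motif_counts(mono))
  alu_ratio <- if (!is.null(alu))
    alu_cgn_ncg_ratio(mono, alu, min_alu_ends = min_alu_ends) else NA_real_
  iwfaf_score <- iwfaf(mono, reference$end_ref)
  tibble::tibble(sample_id = sample_id, CPA = cpa, CTCPA = ctcpa,
                 P126_135 = p126, D126_135 = d126, MDS = mds_score,
                 ALU_CGN_NCG = alu_ratio, IWFAF = iwfaf_score,
                 n_fragments = nrow(fragments), n_mono = nrow(mono))
}
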
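#' Simulation configuration for the synthetic cfDNA cohort generator
#'
#' Assembles and validates the full parameterisation of the synthetic plasma
#' cohort: a toy genome, a copy-number clone, fragment-length and end-motif
#' models, recurrent fragment-end positions, Alu CpG end-motif emission, and a
#' proportional-hazards outcome model. The defaults define the study
#' conditions used throughout the package's tests and vignette; every piece is
#' overridable.
#'
#' The generator is built around inverse-CDF sampling from a per-fragment
#' matrix of uniforms that depends only on `(seed, fragment index)`. Running
#' it at increasing tumor fraction with the same seed therefore produces a
#' *coupled* dilution series: the set of tumor-derived fragments is nested
#' across tumor fractions, the computational analogue of diluting a single
#' specimen.
#'
#' @param genome tibble with columns `chrom`, `length` (bp).
#' @param bin_width genome bin width in bp used by copy-number profiling.
#' @param n_fragments number of fragments drawn per sample.
#' @param cnv_segments tibble with columns `chrom`, `start`, `end`, `cn`
#'   (tumor copy number, integer 0--4); non-overlapping, within the genome.
#'   The default clone is gain-heavy on chr1 and loss-heavy on chr2 so that
#'   chromosome-level copy signal does not cancel.
#' @param length_model,motif_model,end_position_model,alu_model,outcome_model,cohort_model
#'   sub-model lists; see [default_length_model()] and friends.
#' @param duplicate_rate probability that a fragment is flagged duplicate.
#' @param min_length minimum simulated fragment length (bp).
#' @param seed integer master seed.
#' @return A validated list of class `cf_sim_config`.
#' @seealso [simulate_healthy_sample()], [simulate_tumor_sample()],
#'   [simulate_cohort()]
#' @examples
#' cfg <- sim_config(n_fragments = 1000, seed = 7)
#' frags <- simulate_healthy_sample(cfg, seed = 1)
#' nrow(frags)
#' @export
sim_config <- function(genome = tibble::tibble(chrom = c("chr1", "chr2"),
                                               length = c(5e7, 5e7)),
                       bin_width = 5e5,
                       n_fragments = 2e4,
                       cnv_segments = default_cnv_segments(),
                       length_model = default_length_model(),
                       motif_model = default_motif_model(),
                       end_position_model = default_end_position_model(),
                       alu_model = default_alu_model(),
                       outcome_model = default_outcome_model(),
                       cohort_model = default_cohort_model(),
                       duplicate_rate = 0,
                       min_length = 50,
                       seed = 1L) {
  cfg <- structure(
    list(genome = tibble::as_tibble(genome),
         bin_width = bin_width,
         n_fragments = as.integer(n_fragments),
         cnv_segments = tibble::as_tibble(cnv_segments),
         length_model = length_model,
         motif_model = motif_model,
         end_position_model = end_position_model,
         alu_model = alu_model,
         outcome_model = outcome_model,
         cohort_model = cohort_model,
         duplicate_rate = duplicate_rate,
         min_length = as.integer(min_length),
         seed = as.integer(seed)),
    class = "cf_sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Default tumor copy-number clone
#'
#' An aneuploid NSCLC-like clone: high-level gains (CN 4, emulating
#' amplified arms) over 80% of chr1 and deep plus hemizygous losses (CN 0-1)
#' over 80% of chr2. Gains and losses are balanced genome-wide (40% gained,
#' 40% lost, 20% neutral) so that per-sample median re-centering of the
#' copy-ratio profile leaves the copy-neutral level at zero, and each
#' chromosome is aberrant in a single direction so chromosome-scale signal
#' does not self-cancel.
#' @return tibble with `chrom`, `start`, `end`, `cn`.
#' @export
default_cnv_segments <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr2"),
    start = c(0, 25e6, 0, 15e6, 25e6),
    end   = c(20e6, 45e6, 10e6, 25e6, 45e6),
    cn    = c(4L, 4L, 0L, 0L, 1L))
}

#' Default fragment-length model
#'
#' Mixture of discretised Gaussians. Healthy plasma: a mononucleosomal core at
#' 166 bp, 10-bp sawtooth sub-peaks below 160 bp with geometrically decaying
#' weights, and a minor dinucleosomal tail. Tumor-derived fragments: a
#' shortened mode at 145 bp and sub-peaks shifted to 134, 124, ... bp, which
#' concentrates extra mass in the 126--135 bp window.
#' @param healthy,tumor data frames with columns `mean`, `sd`, `weight`
#'   (weights sum to 1 within each class).
#' @param max_length upper bound of the discrete support (bp).
#' @return list with components `healthy`, `tumor`, `max_length`.
#' @export
default_length_model <- function(healthy = NULL, tumor = NULL, max_length = 600) {
  saw_w <- function(k, total) total * 0.55^(seq_len(k) - 1) / sum(0.55^(seq_len(k) - 1))
  if (is.null(healthy)) {
    healthy <- tibble::tibble(
      mean = c(166, seq(156, 96, by = -10), 320),
      sd = c(9, rep(4, 7), 30),
      weight = c(0.72, saw_w(7, 0.20), 0.08))
  }
  if (is.null(tumor)) {
    tumor <- tibble::tibble(
      mean = c(166, 145, seq(134, 94, by = -10), 320),
      sd = c(9, 11, rep(4, 5), 30),
      weight = c(0.30, 0.35, saw_w(5, 0.30), 0.05))
  }
  list(healthy = tibble::as_tibble(healthy), tumor = tibble::as_tibble(tumor),
       max_length = max_length)
}

#' Default end-motif model
#'
#' Healthy 5' end trinucleotides follow a fixed non-uniform simplex over the
#' 64 motifs (geometric decay in lexicographic order); tumor fragments draw
#' from a mixture of that simplex with the uniform distribution, which raises
#' end-motif diversity, as expected when nuclease-driven end preferences are
#' eroded in tumor-derived cfDNA.
#' @param healthy_probs length-64 probability vector over [TRINUCLEOTIDES].
#' @param tumor_uniform_mix mixing weight toward the uniform simplex for
#'   tumor-derived fragments.
#' @return list with `healthy_probs`, `tumor_probs`, `tumor_uniform_mix`.
#' @export
default_motif_model <- function(healthy_probs = NULL, tumor_uniform_mix = 0.6) {
  if (is.null(healthy_probs)) {
    healthy_probs <- exp(-0.06 * (0:63))
    healthy_probs <- healthy_probs / sum(healthy_probs)
  }
  tumor_probs <- (1 - tumor_uniform_mix) * healthy_probs + tumor_uniform_mix / 64
  list(healthy_probs = setNames(healthy_probs, TRINUCLEOTIDES),
       tumor_probs = setNames(tumor_probs, TRINUCLEOTIDES),
       tumor_uniform_mix = tumor_uniform_mix)
}

#' Default fragment end-position model
#'
#' A fixed grid of preferred (nucleosome-phased) end sites shared by the whole
#' cohort: one site every `site_spacing` bp at `site_offset` (the default
#' spacing is deliberately incommensurate with the Alu grid so preferred ends
#' sample all positions relative to Alu elements). Healthy
#' fragments place one of their two ends exactly on the nearest site with
#' probability `p_adhere`; tumor-derived fragments adhere with probability
#' `p_adhere * (1 - tumor_aberrancy)`, so the aberrant-end rate of a sample
#' grows linearly with its tumor fraction.
#' @export
default_end_position_model <- function(site_spacing = 20411, site_offset = 9973,
                                       p_adhere = 0.8, tumor_aberrancy = 0.6) {
  list(site_spacing = site_spacing, site_offset = site_offset,
       p_adhere = p_adhere, tumor_aberrancy = tumor_aberrancy)
}

#' Default Alu end-motif model
#'
#' Regularly spaced Alu intervals (`alu_length` bp every `alu_spacing` bp).
#' Fragment ends falling inside an Alu emit a CG-leading motif (CGN) with a
#' class-specific probability and a CG-trailing motif (NCG) otherwise with a
#' second probability; hypomethylated tumor DNA emits more CGN and fewer NCG
#' ends, raising the CGN/NCG ratio.
#' @export
default_alu_model <- function(alu_spacing = 5e3, alu_length = 300, alu_offset = 1e3,
                              healthy_cgn = 0.05, healthy_ncg = 0.05,
                              tumor_cgn = 0.14, tumor_ncg = 0.04) {
  list(alu_spacing = alu_spacing, alu_length = alu_length, alu_offset = alu_offset,
       healthy_cgn = healthy_cgn, healthy_ncg = healthy_ncg,
       tumor_cgn = tumor_cgn, tumor_ncg = tumor_ncg)
}

#' Default outcome model
#'
#' Exponential progression-free survival with multiplicative hazards: subjects
#' with residual tumor fraction after four therapy cycles carry
#' `exp(log_hr_residual)` times the baseline hazard (default 4). Independent
#' exponential censoring at `censor_rate` per month (default tuned to about
#' 20% censoring) plus administrative censoring at `horizon` months. Overall
#' survival adds an exponential post-progression survival time.
#' @export
default_outcome_model <- function(baseline_hazard = log(2) / 12,
                                  log_hr_residual = log(4),
                                  censor_rate = 0.025,
                                  horizon = 60,
                                  os_extra_rate = log(2) / 10) {
  list(baseline_hazard = baseline_hazard, log_hr_residual = log_hr_residual,
       censor_rate = censor_rate, horizon = horizon, os_extra_rate = os_extra_rate)
}

#' Default cohort design
#'
#' Healthy controls plus NSCLC-like subjects sampled at therapy baseline,
#' after four therapy cycles, and (for a subset) at progression. Baseline
#' tumor fraction is uniform on `baseline_tf`; responders (probability
#' `responder_prob`) clear their tumor fraction by cycle 4
#' (`response factor 0`), non-responders retain `residual_factor` of it.
#' @export
default_cohort_model <- function(n_healthy = 20L, n_subjects = 16L,
                                 baseline_tf = c(0.05, 0.3),
                                 responder_prob = 0.5,
                                 residual_factor = 0.8,
                                 progression_prob = 0.5,
                                 progression_factor = 1.5) {
  list(n_healthy = as.integer(n_healthy), n_subjects = as.integer(n_subjects),
       baseline_tf = baseline_tf, responder_prob = responder_prob,
       residual_factor = residual_factor, progression_prob = progression_prob,
       progression_factor = progression_factor)
}

validate_sim_config <- function(cfg) {
  stop_field <- function(field, msg) {
    abort(sprintf("invalid simulation config: field `%s` %s", field, msg),
          class = "ctfrag_config_error")
  }
  g <- cfg$genome
  if (!all(c("chrom", "length") %in% names(g)) || nrow(g) == 0)
    stop_field("genome", "must have columns chrom, length")
  if (any(g$length <= 0)) stop_field("genome", "chromosome lengths must be > 0")
  if (anyDuplicated(g$chrom)) stop_field("genome", "chromosome names must be unique")
  if (cfg$bin_width <= 0) stop_field("bin_width", "must be > 0")
  if (cfg$n_fragments < 1) stop_field("n_fragments", "must be >= 1")
  if (cfg$duplicate_rate < 0 || cfg$duplicate_rate > 1)
    stop_field("duplicate_rate", "must be in [0, 1]")

  cs <- cfg$cnv_segments
  if (nrow(cs) > 0) {
    if (!all(c("chrom", "start", "end", "cn") %in% names(cs)))
      stop_field("cnv_segments", "must have columns chrom, start, end, cn")
    if (!all(cs$cn %in% 0:4)) stop_field("cnv_segments", "cn must be in 0..4")
    if (!all(cs$chrom %in% g$chrom)) stop_field("cnv_segments", "chrom not in genome")
    if (any(cs$end <= cs$start)) stop_field("cnv_segments", "must have end > start")
    lens <- g$length[match(cs$chrom, g$chrom)]
    if (any(cs$end > lens)) stop_field("cnv_segments", "must lie within the genome")
    by_chr <- split(cs[order(cs$start), ], cs$chrom[order(cs$start)])
    for (d in by_chr) {
      if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
        stop_field("cnv_segments", "must be non-overlapping")
    }
  }

  for (cls in c("healthy", "tumor")) {
    comp <- cfg$length_model[[cls]]
    if (any(comp$sd <= 0) || any(comp$weight < 0))
      stop_field("length_model", "needs sd > 0 and weights >= 0")
    if (abs(sum(comp$weight) - 1) > 1e-9)
      stop_field("length_model", sprintf("%s weights must sum to 1", cls))
  }
  for (p in c("healthy_probs", "tumor_probs")) {
    pr <- cfg$motif_model[[p]]
    if (length(pr) != 64 || any(pr < 0) || abs(sum(pr) - 1) > 1e-9)
      stop_field("motif_model", sprintf("%s must be a 64-simplex summing to 1", p))
  }
  ep <- cfg$end_position_model
  if (ep$p_adhere < 0 || ep$p_adhere > 1)
    stop_field("end_position_model", "p_adhere must be in [0, 1]")
  if (ep$tumor_aberrancy < 0 || ep$tumor_aberrancy > 1)
    stop_field("end_position_model", "tumor_aberrancy must be in [0, 1]")
  am <- cfg$alu_model
  for (f in c("healthy_cgn", "healthy_ncg", "tumor_cgn", "tumor_ncg")) {
    if (am[[f]] < 0 || am[[f]] > 1) stop_field("alu_model", sprintf("%s must be in [0, 1]", f))
  }
  if (am$healthy_cgn + am$healthy_ncg > 1 || am$tumor_cgn + am$tumor_ncg > 1)
    stop_field("alu_model", "cgn + ncg emission probabilities must be <= 1")
  if (cfg$min_length < 1) stop_field("min_length", "must be >= 1")
  invisible(cfg)
}

#' Discrete fragment-length distribution implied by a length model
#'
#' Integrates the configured Gaussian mixture over unit-length bins on
#' `min_length..max_length` and renormalises.
#' @param length_model as produced by [default_length_model()].
#' @param min_length,max_length support bounds (bp).
#' @param tumor use the tumor components instead of the healthy ones.
#' @return tibble with columns `length`, `prob` (summing to 1).
#' @export
length_pmf <- function(length_model, min_length = 50, max_length = NULL,
                       tumor = FALSE) {
  if (is.null(max_length)) max_length <- length_model$max_length
  support <- min_length:max_length
  comp <- if (tumor) length_model$tumor else length_model$healthy
  dens <- rep(0, length(support))
  for (i in seq_len(nrow(comp))) {
    dens <- dens + comp$weight[i] *
      (pnorm(support + 0.5, comp$mean[i], comp$sd[i]) -
         pnorm(support - 0.5, comp$mean[i], comp$sd[i]))
  }
  tibble::tibble(length = support, prob = dens / sum(dens))
}

#' Analytic mass of a length window under the configured mixture
#'
#' @inheritParams length_pmf
#' @param window inclusive `[lower, upper]` length window in bp.
#' @return scalar probability.
#' @export
length_window_mass <- function(length_model, window = c(126, 135),
                               min_length = 50, tumor = FALSE) {
  pmf <- length_pmf(length_model, min_length = min_length, tumor = tumor)
  sum(pmf$prob[pmf$length >= window[1] & pmf$length <= window[2]])
}

#' Preferred fragment-end sites of a simulation config
#'
#' @param config a [sim_config()].
#' @return tibble with columns `chrom`, `pos` (0-based).
#' @export
end_sites <- function(config) {
  ep <- config$end_position_model
  purrr::map_dfr(seq_len(nrow(config$genome)), function(i) {
    len <- config$genome$length[i]
    pos <- seq(ep$site_offset, len - 1, by = ep$site_spacing)
    tibble::tibble(chrom = config$genome$chrom[i], pos = as.numeric(pos))
  })
}

#' Alu intervals of a simulation config
#'
#' Regularly spaced toy Alu elements as 0-based half-open intervals.
#' @param config a [sim_config()].
#' @return tibble with columns `chrom`, `start`, `end`.
#' @export
alu_intervals <- function(config) {
  am <- config$alu_model
  purrr::map_dfr(seq_len(nrow(config$genome)), function(i) {
    len <- config$genome$length[i]
    start <- seq(am$alu_offset, len - am$alu_length, by = am$alu_spacing)
    tibble::tibble(chrom = config$genome$chrom[i], start = as.numeric(start),
                   end = start + am$alu_length)
  })
}

#' Derive reproducible child seeds from a master seed
#'
#' @param seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, all below 2^31.
#' @export
make_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
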
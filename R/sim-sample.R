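#' Simulate one plasma cfDNA sample
#'
#' Draws `config$n_fragments` fragments i.i.d. from the generative model: a
#' fragment's genomic position is sampled proportionally to local expected
#' copy number `(1 - tf) * 2 + tf * CN`, its origin (tumor vs. background) by
#' the local tumor-read expectation, its length from the class-specific
#' mixture, its end positions snap to the shared preferred-end grid with
#' class-specific adherence, and its end trinucleotides come from the
#' class-specific motif simplex, overridden inside Alu elements by the CGN/NCG
#' emission model. At `tf = 0` every fragment is background, so the tumor
#' sampler reduces exactly to the healthy one (same code path).
#'
#' All randomness comes from a `(seed, fragment index)`-indexed matrix of
#' uniforms transformed by inverse CDFs, so identical `(config, seed)` give
#' byte-identical tables and a fixed seed across a tumor-fraction grid yields
#' a coupled dilution series with nested tumor-fragment sets.
#'
#' @param config a [sim_config()].
#' @param tf tumor fraction in `[0, 1]`.
#' @param seed integer seed for this sample.
#' @param sample_id optional sample identifier column.
#' @return A fragment tibble with columns `sample_id` (if given), `chrom`,
#'   `start`, `end` (0-based half-open), `length`, `motif5_left`,
#'   `motif5_right`, `mapq`, `is_duplicate`, and the ground-truth flag
#'   `tumor_origin`.
#' @export
simulate_tumor_sample <- function(config, tf, seed, sample_id = NULL) {
  if (!inherits(config, "cf_sim_config")) validate_sim_config(config)
  if (!is.numeric(tf) || length(tf) != 1 || is.na(tf) || tf < 0 || tf > 1)
    abort("`tf` must be a single number in [0, 1]", class = "ctfrag_domain_error")
  n <- config$n_fragments

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  U <- matrix(runif(n * 11L), nrow = n, ncol = 11L)

  iv <- cn_intervals(config)
  w <- (iv$end - iv$start) * ((1 - tf) * 2 + tf * iv$cn)
  if (sum(w) <= 0) abort("all sampling weights are zero", class = "ctfrag_domain_error")
  cw <- cumsum(w) / sum(w)
  idx <- findInterval(U[, 1L], cw) + 1L
  idx[idx > nrow(iv)] <- nrow(iv)

  denom <- (1 - tf) * 2 + tf * iv$cn[idx]
  p_tumor <- ifelse(denom > 0, tf * iv$cn[idx] / denom, 0)
  tumor <- U[, 2L] < p_tumor

  pmf_h <- length_pmf(config$length_model, min_length = config$min_length)
  pmf_t <- length_pmf(config$length_model, min_length = config$min_length, tumor = TRUE)
  len <- ifelse(tumor,
                q_discrete(U[, 3L], pmf_t$prob, pmf_t$length),
                q_discrete(U[, 3L], pmf_h$prob, pmf_h$length))

  span <- pmax(iv$end[idx] - iv$start[idx] - len, 1)
  start <- iv$start[idx] + floor(U[, 4L] * span)
  chrom_len <- config$genome$length[match(iv$chrom[idx], config$genome$chrom)]
  start <- pmax(0, pmin(start, chrom_len - len))
  end <- start + len
  chrom <- iv$chrom[idx]

  # end-position adherence: snap one end to the nearest preferred site
  ep <- config$end_position_model
  p_ad <- ifelse(tumor, ep$p_adhere * (1 - ep$tumor_aberrancy), ep$p_adhere)
  adhere <- U[, 5L] < p_ad
  snap_left <- U[, 6L] < 0.5
  kmax <- floor((chrom_len - 1 - ep$site_offset) / ep$site_spacing)
  snap_to_site <- function(x, kmax_i) {
    k <- pmin(pmax(round((x - ep$site_offset) / ep$site_spacing), 0), kmax_i)
    ep$site_offset + k * ep$site_spacing
  }
  i_l <- adhere & snap_left
  i_r <- adhere & !snap_left
  start[i_l] <- snap_to_site(start[i_l], kmax[i_l])
  end[i_l] <- start[i_l] + len[i_l]
  end[i_r] <- snap_to_site(end[i_r] - 1, kmax[i_r]) + 1
  start[i_r] <- end[i_r] - len[i_r]
  start <- pmax(0, pmin(start, chrom_len - len))
  end <- start + len

  mm <- config$motif_model
  cdf_h <- cumsum(mm$healthy_probs)
  cdf_t <- cumsum(mm$tumor_probs)
  pick_motif <- function(u, tum) {
    i <- ifelse(tum, findInterval(u, cdf_t), findInterval(u, cdf_h)) + 1L
    TRINUCLEOTIDES[pmin(i, 64L)]
  }
  motif_l <- pick_motif(U[, 7L], tumor)
  motif_r <- pick_motif(U[, 8L], tumor)

  # Alu CGN/NCG emission overrides motifs for ends inside Alu elements
  am <- config$alu_model
  alu_kmax <- floor((chrom_len - am$alu_length - am$alu_offset) / am$alu_spacing)
  in_alu <- function(pos) {
    rel <- pos - am$alu_offset
    rel >= 0 & (rel %% am$alu_spacing) < am$alu_length &
      floor(rel / am$alu_spacing) <= alu_kmax
  }
  emit_alu <- function(motif, pos, u, tum) {
    inside <- in_alu(pos)
    c1 <- ifelse(tum, am$tumor_cgn, am$healthy_cgn)
    c2 <- ifelse(tum, am$tumor_ncg, am$healthy_ncg)
    bases <- c("A", "C", "G", "T")
    cgn <- inside & u < c1
    ncg <- inside & !cgn & u < c1 + c2
    b3 <- bases[pmin(floor(u[cgn] / c1[cgn] * 4) + 1L, 4L)]
    motif[cgn] <- paste0("CG", b3)
    b1 <- bases[pmin(floor((u[ncg] - c1[ncg]) / c2[ncg] * 4) + 1L, 4L)]
    motif[ncg] <- paste0(b1, "CG")
    motif
  }
  motif_l <- emit_alu(motif_l, start, U[, 9L], tumor)
  motif_r <- emit_alu(motif_r, end - 1, U[, 10L], tumor)

  out <- tibble::tibble(
    chrom = chrom,
    start = as.numeric(start),
    end = as.numeric(end),
    length = as.integer(len),
    motif5_left = motif_l,
    motif5_right = motif_r,
    mapq = 60L,
    is_duplicate = U[, 11L] < config$duplicate_rate,
    tumor_origin = tumor)
  if (!is.null(sample_id)) out <- dplyr::mutate(out, sample_id = sample_id, .before = 1L)
  attr(out, "tf") <- tf
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Simulate one healthy-donor cfDNA sample
#'
#' Identical to [simulate_tumor_sample()] at tumor fraction 0 (same code
#' path).
#' @inheritParams simulate_tumor_sample
#' @export
simulate_healthy_sample <- function(config, seed, sample_id = NULL) {
  simulate_tumor_sample(config, tf = 0, seed = seed, sample_id = sample_id)
}

#' Simulate a coupled dilution series
#'
#' Runs the generator at each tumor fraction with the *same* seed, yielding
#' samples whose tumor-fragment sets are nested across the grid -- the in
#' silico analogue of serially diluting one tumor specimen into one healthy
#' plasma background.
#'
#' @inheritParams simulate_tumor_sample
#' @param tf_grid numeric vector of tumor fractions.
#' @return named list of fragment tibbles, one per tumor fraction.
#' @export
simulate_dilution_series <- function(config, tf_grid, seed) {
  out <- lapply(tf_grid, function(tf) simulate_tumor_sample(config, tf, seed))
  names(out) <- formatC(tf_grid, format = "g")
  out
}

# Piecewise-constant copy-number intervals covering the genome (CN = 2
# outside the configured tumor segments).
cn_intervals <- function(config) {
  purrr::map_dfr(seq_len(nrow(config$genome)), function(i) {
    chrom <- config$genome$chrom[i]
    len <- config$genome$length[i]
    segs <- config$cnv_segments[config$cnv_segments$chrom == chrom, , drop = FALSE]
    segs <- segs[order(segs$start), , drop = FALSE]
    brk <- sort(unique(c(0, len, segs$start, segs$end)))
    st <- brk[-length(brk)]
    en <- brk[-1]
    cn <- rep(2L, length(st))
    if (nrow(segs) > 0) {
      hit <- findInterval(st, segs$start)
      ok <- hit >= 1 & st < segs$end[pmax(hit, 1)]
      cn[ok] <- segs$cn[hit[ok]]
    }
    tibble::tibble(chrom = chrom, start = st, end = en, cn = cn)
  })
}

# Inverse-CDF draw from a discrete distribution.
q_discrete <- function(u, prob, values) {
  cdf <- cumsum(prob)
  i <- findInterval(u, cdf) + 1L
  values[pmin(i, length(values))]
}
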
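#' Fixed-width genome bins
#'
#' Tiles each chromosome with non-overlapping bins of `bin_width` bp (the
#' last partial bin is kept). GC content per bin may be supplied; by default
#' a smooth synthetic GC track is attached so GC-decile correction is
#' exercised even on simulated data that carry no sequence.
#'
#' @param genome tibble with `chrom`, `length`.
#' @param bin_width bin width in bp.
#' @param gc optional numeric vector of per-bin GC fractions (genome order).
#' @return tibble with `bin_id`, `chrom`, `start`, `end`, `gc`, `usable`.
#' @export
genome_bins <- function(genome, bin_width = 5e5, gc = NULL) {
  bins <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    starts <- seq(0, genome$length[i] - 1, by = bin_width)
    tibble::tibble(chrom = genome$chrom[i], start = starts,
                   end = pmin(starts + bin_width, genome$length[i]))
  })
  bins$bin_id <- seq_len(nrow(bins))
  if (is.null(gc)) gc <- 0.40 + 0.08 * sin(2 * pi * bins$bin_id / 17)
  if (length(gc) != nrow(bins) || any(gc < 0 | gc > 1))
    abort("`gc` must be one fraction in [0,1] per bin", class = "ctfrag_config_error")
  bins$gc <- gc
  bins$usable <- TRUE
  dplyr::select(bins, "bin_id", "chrom", "start", "end", "gc", "usable")
}

#' Count fragments per genome bin
#'
#' Assigns each fragment to the bin containing its midpoint
#' (`floor((start + end) / 2)`; bins are half-open, so a midpoint on a bin
#' boundary belongs to the right-hand bin). Duplicate-flagged fragments are
#' excluded. Copy-number profiling deliberately uses *all* fragment lengths
#' (no mononucleosomal filter).
#'
#' @param fragments fragment tibble.
#' @param bins bin tibble from [genome_bins()].
#' @return `bins` with a `raw_count` column (a raw bin profile).
#' @export
bin_counts <- function(fragments, bins) {
  fr <- dplyr::filter(fragments, !.data$is_duplicate)
  missing_contigs <- setdiff(unique(fr$chrom), unique(bins$chrom))
  if (length(missing_contigs) > 0) {
    warn(sprintf("bin_counts: contig(s) not covered by bins, excluded: %s",
                 paste(missing_contigs, collapse = ", ")))
    fr <- dplyr::filter(fr, !.data$chrom %in% missing_contigs)
  }
  mid <- floor((fr$start + fr$end) / 2)
  counts <- rep(0L, nrow(bins))
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    m <- mid[fr$chrom == ch]
    if (length(m) == 0) next
    idx <- findInterval(m, b$start)
    ok <- idx >= 1 & m < b$end[pmax(idx, 1)]
    tab <- tabulate(idx[ok], nbins = nrow(b))
    counts[b$bin_id] <- counts[b$bin_id] + tab
  }
  out <- bins
  out$raw_count <- counts
  out
}

# library-size normalisation + per-sample GC-decile median-ratio correction
gc_correct <- function(profile, n_deciles = 10) {
  usable <- profile$usable & !is.na(profile$raw_count)
  x <- profile$raw_count / mean(profile$raw_count[usable])
  dec <- cut(profile$gc, breaks = quantile(profile$gc[usable],
                                           probs = seq(0, 1, length.out = n_deciles + 1)),
             include.lowest = TRUE)
  med_all <- median(x[usable])
  for (d in levels(dec)) {
    i <- which(usable & dec == d)
    if (length(i) >= 3) {
      m <- median(x[i])
      if (m > 0) x[i] <- x[i] * med_all / m
    }
  }
  x
}

#' Build a panel of normals from healthy bin profiles
#'
#' Each healthy profile is scaled to library size and GC-corrected; the panel
#' stores the per-bin mean and the per-bin standard deviation of
#' log2(sample / panel mean) across the healthy cohort, which calibrates the
#' per-bin z-scores of [normalize_profile()].
#'
#' @param profiles list of raw bin profiles from [bin_counts()], healthy
#'   samples only.
#' @param min_samples minimum panel size.
#' @return object of class `cf_panel`.
#' @export
build_panel <- function(profiles, min_samples = 5) {
  if (length(profiles) < min_samples)
    abort(sprintf("panel of normals needs >= %d healthy samples", min_samples),
          class = "ctfrag_calibration_error")
  bins <- profiles[[1]][, c("bin_id", "chrom", "start", "end", "gc", "usable")]
  for (p in profiles) {
    if (nrow(p) != nrow(bins) || any(p$bin_id != bins$bin_id))
      abort("panel profiles must share one bin set", class = "ctfrag_config_error")
  }
  X <- vapply(profiles, gc_correct, numeric(nrow(bins)))
  mu <- rowMeans(X)
  L <- log2(sweep(X, 1, mu, "/"))
  L[!is.finite(L)] <- NA
  # per-sample median re-centering, as applied to test samples
  L <- sweep(L, 2, apply(L[bins$usable, , drop = FALSE], 2, median, na.rm = TRUE))
  sigma <- apply(L, 1, sd, na.rm = TRUE)
  usable <- bins$usable & is.finite(mu) & mu > 0 & is.finite(sigma) & sigma > 0
  structure(list(bins = bins, mu = mu, sigma = sigma, usable = usable,
                 n_healthy = length(profiles)),
            class = "cf_panel")
}

#' Normalize a raw bin profile against a panel of normals
#'
#' Scales to library size, GC-corrects by median ratio per GC decile, divides
#' by the panel's expected (mean) profile, and reports `log2_ratio` together
#' with the panel-calibrated per-bin z-score `z = log2_ratio / panel SD`.
#' Normalisation is invariant to global library-size scaling.
#'
#' @param profile_raw raw bin profile from [bin_counts()].
#' @param panel a [build_panel()] object built on identical bins.
#' @return bin profile tibble with `log2_ratio`, `z`, and updated `usable`.
#' @export
normalize_profile <- function(profile_raw, panel) {
  if (!inherits(panel, "cf_panel")) abort("`panel` must be a cf_panel")
  if (nrow(profile_raw) != nrow(panel$bins) ||
      any(profile_raw$bin_id != panel$bins$bin_id))
    abort("profile bins do not match panel bins", class = "ctfrag_config_error")
  x <- gc_correct(profile_raw)
  l <- log2(x / panel$mu)
  # median re-centering removes the depth-dependent (Jensen) offset of
  # log-ratios, so copy-neutral plasma sits at 0 regardless of library size
  l <- l - median(l[panel$usable & is.finite(l)])
  z <- l / panel$sigma
  out <- profile_raw
  out$usable <- panel$usable & is.finite(l)
  out$log2_ratio <- ifelse(out$usable, l, NA_real_)
  out$z <- ifelse(out$usable, z, NA_real_)
  out
}

#' Segment a normalized copy-ratio profile
#'
#' Least-squares changepoint segmentation per chromosome by dynamic
#' programming with an SIC-style penalty (`2 * sigma^2 * log(n)` per
#' changepoint, with `sigma` estimated robustly from first differences).
#' Chromosomes with fewer than two usable bins yield a single trivial
#' segment.
#'
#' @param profile_norm normalized profile from [normalize_profile()].
#' @param penalty optional penalty per additional segment; default SIC-style.
#' @return segment tibble: `chrom`, `start`, `end`, `n_bins`, `length`,
#'   `mean_ratio`, `mean_z` (per-bin z averaged over the segment).
#' @export
segment_profile <- function(profile_norm, penalty = NULL) {
  if (!"log2_ratio" %in% names(profile_norm))
    abort("`profile_norm` must be a normalized bin profile")
  out <- list()
  for (ch in unique(profile_norm$chrom)) {
    p <- profile_norm[profile_norm$chrom == ch & profile_norm$usable &
                        !is.na(profile_norm$log2_ratio), ]
    if (nrow(p) == 0) next
    y <- p$log2_ratio
    if (nrow(p) < 2) {
      cp <- c(0L, nrow(p))
    } else {
      lambda <- penalty
      if (is.null(lambda)) {
        sig <- mad(diff(y)) / sqrt(2)
        lambda <- max(2 * sig^2 * log(length(y)), 1e-12)
      }
      cp <- segment_dp(y, lambda)
    }
    for (s in seq_len(length(cp) - 1)) {
      i <- (cp[s] + 1):cp[s + 1]
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch, start = p$start[i[1]], end = p$end[i[length(i)]],
        n_bins = length(i), length = sum(p$end[i] - p$start[i]),
        mean_ratio = mean(y[i]), mean_z = mean(p$z[i]))
    }
  }
  if (length(out) == 0)
    abort("no usable bins to segment", class = "ctfrag_data_error")
  dplyr::bind_rows(out)
}

# Optimal-partitioning DP: minimise sum of within-segment RSS + lambda per
# segment. Returns changepoint indices including 0 and n.
segment_dp <- function(y, lambda) {
  n <- length(y)
  S1 <- c(0, cumsum(y))
  S2 <- c(0, cumsum(y^2))
  F <- c(0, rep(Inf, n))
  prev <- integer(n)
  for (j in seq_len(n)) {
    i <- seq_len(j)
    rss <- (S2[j + 1] - S2[i]) - (S1[j + 1] - S1[i])^2 / (j - i + 1)
    cand <- F[i] + rss + lambda
    i0 <- which.min(cand)
    F[j + 1] <- cand[i0]
    prev[j] <- i0 - 1L
  }
  cp <- n
  while (cp[1] > 0) cp <- c(prev[cp[1]], cp)
  cp
}
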
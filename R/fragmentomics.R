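#' Proportion of short fragments (P126-135)
#'
#' Fraction of mononucleosomal fragments whose length lies in the inclusive
#' `[126, 135]` bp window, a marker of ctDNA-associated short-fragment
#' enrichment. The denominator is all fragments in the supplied
#' (mononucleosome-filtered) set.
#'
#' @param fragments mononucleosome-filtered fragment tibble.
#' @param window inclusive length window in bp.
#' @param min_fragments minimum fragments required (default 1000).
#' @return fraction in `[0, 1]`.
#' @export
p126_135 <- function(fragments, window = c(126, 135), min_fragments = 1000) {
  if (nrow(fragments) < min_fragments)
    abort(sprintf("p126_135 needs >= %d fragments (got %d)",
                  min_fragments, nrow(fragments)),
          class = "ctfrag_insufficient_data")
  mean(fragments$length >= window[1] & fragments$length <= window[2])
}

#' Absolute deviation of P126-135 from the healthy median (D126-135)
#'
#' `|p_sample - median(healthy)|`: captures fragment-length shifts in either
#' direction, since short-fragment proportions can be reduced as well as
#' elevated relative to healthy donors.
#'
#' @param p_sample the sample's P126-135.
#' @param healthy_p_values P126-135 values of >= 3 healthy donors.
#' @return non-negative deviation.
#' @export
d126_135 <- function(p_sample, healthy_p_values) {
  if (length(healthy_p_values) < 3)
    abort("d126_135 needs >= 3 healthy reference values",
          class = "ctfrag_calibration_error")
  abs(p_sample - median(healthy_p_values))
}

#' Fragment end trinucleotide counts
#'
#' Counts the 5' trinucleotide motifs over both fragment ends
#' (`motif5_right` is already the reverse complement of the reference at the
#' right end, i.e. both counts are 5'-oriented). The sentinel `"NNN"` is
#' excluded.
#'
#' @param fragments fragment tibble with motif columns.
#' @return named integer vector over the 64 motifs (lexicographic order).
#' @export
end_motif_counts <- function(fragments) {
  m <- c(fragments$motif5_left, fragments$motif5_right)
  m <- m[m != "NNN" & !is.na(m)]
  if (length(m) == 0)
    abort("no informative end motifs (all NNN)", class = "ctfrag_insufficient_data")
  counts <- table(factor(m, levels = TRINUCLEOTIDES))
  setNames(as.integer(counts), TRINUCLEOTIDES)
}

#' Motif diversity score (MDS)
#'
#' Normalized Shannon entropy of the 64 fragment-end trinucleotide
#' frequencies: `-sum(f * log f) / log 64`, with `0 * log 0 = 0`. 1 for a
#' uniform motif usage, 0 when a single motif is used. Invariant to motif
#' relabeling and to the logarithm base.
#'
#' @param motif_counts named 64-vector from [end_motif_counts()].
#' @return diversity score in `[0, 1]`.
#' @export
mds <- function(motif_counts) {
  total <- sum(motif_counts)
  if (total <= 0) abort("mds needs positive motif counts",
                        class = "ctfrag_insufficient_data")
  f <- motif_counts / total
  f <- f[f > 0]
  -sum(f * log(f)) / log(64)
}

#' Alu CGN/NCG end-motif ratio
#'
#' Among the end motifs of fragment ends falling inside Alu elements, the
#' ratio of CG-leading motifs (`CGN`: first two bases CG) to CG-trailing
#' motifs (`NCG`: last two bases CG), each with a pseudocount. Unmethylated
#' Alu CpGs are cut preferentially right before the CpG, so hypomethylation
#' elevates CGN ends and the ratio rises; a 3-mer can never match both
#' patterns. Both fragment ends are evaluated (left end at `start`, right
#' end at `end - 1`).
#'
#' @param fragments mononucleosome-filtered fragment tibble.
#' @param alu tibble of Alu intervals (`chrom`, `start`, `end`; 0-based
#'   half-open, non-overlapping).
#' @param min_alu_ends minimum Alu-overlapping ends required (default 200).
#' @param pseudocount added to both counts (default 0.5).
#' @return positive ratio.
#' @export
alu_cgn_ncg_ratio <- function(fragments, alu, min_alu_ends = 200,
                              pseudocount = 0.5) {
  ends <- fragment_ends(fragments)
  inside <- in_intervals(ends$chrom, ends$pos, alu)
  motifs <- ends$motif[inside]
  motifs <- motifs[motifs != "NNN" & !is.na(motifs)]
  if (length(motifs) < min_alu_ends)
    abort(sprintf("alu_cgn_ncg_ratio needs >= %d Alu-overlapping ends (got %d)",
                  min_alu_ends, length(motifs)),
          class = "ctfrag_insufficient_data")
  n_cgn <- sum(substr(motifs, 1, 2) == "CG")
  n_ncg <- sum(substr(motifs, 2, 3) == "CG")
  (n_cgn + pseudocount) / (n_ncg + pseudocount)
}

# both end coordinates of each fragment with their 5' motifs
fragment_ends <- function(fragments) {
  tibble::tibble(
    chrom = rep(fragments$chrom, 2),
    pos = c(fragments$start, fragments$end - 1),
    motif = c(fragments$motif5_left, fragments$motif5_right),
    fragment = rep(seq_len(nrow(fragments)), 2))
}

# membership of positions in sorted non-overlapping intervals
in_intervals <- function(chrom, pos, intervals) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0) next
    iv <- iv[order(iv$start), , drop = FALSE]
    sel <- which(chrom == ch)
    idx <- findInterval(pos[sel], iv$start)
    out[sel] <- idx >= 1 & pos[sel] < iv$end[pmax(idx, 1)]
  }
  out
}

#' Build the healthy fragment end-position reference
#'
#' Collects genomic positions recurrently used as fragment ends (either end)
#' by the healthy cohort: a position enters the reference when at least `k`
#' distinct healthy samples use it. Each reference position carries its
#' pooled healthy usage frequency `f_pos`, the basis of the iwFAF
#' self-information weights.
#'
#' @param healthy_fragments list of >= 5 healthy (mononucleosome-filtered)
#'   fragment tibbles.
#' @param k recurrence rule: minimum number of distinct healthy samples
#'   using a position (default `ceiling(n_healthy / 4)`).
#' @param w matching window in bp around a reference position (default 0 =
#'   exact).
#' @param pseudocount frequency pseudocount for ends not in the reference.
#' @return object of class `cf_end_reference`: tibble of positions plus
#'   calibration metadata.
#' @export
build_end_position_reference <- function(healthy_fragments, k = NULL, w = 0,
                                         pseudocount = 0.5) {
  n <- length(healthy_fragments)
  if (n < 5)
    abort("end-position reference needs >= 5 healthy samples",
          class = "ctfrag_calibration_error")
  if (is.null(k)) k <- ceiling(n / 4)
  # encode (chrom, pos) as one numeric key and count by sorting
  chroms <- sort(unique(unlist(lapply(healthy_fragments,
                                      function(f) unique(f$chrom)))))
  key_of <- function(f) {
    e <- fragment_ends(f)
    (match(e$chrom, chroms) - 1) * 2^32 + e$pos
  }
  keys <- lapply(healthy_fragments, key_of)
  total_pooled <- sum(lengths(keys))
  count_sorted <- function(x) {
    x <- sort(x, method = "radix")
    new <- c(TRUE, x[-1] != x[-length(x)])
    idx <- which(new)
    list(key = x[idx], n = diff(c(idx, length(x) + 1L)))
  }
  usage <- count_sorted(unlist(keys))
  per_sample <- count_sorted(unlist(lapply(keys, unique)))
  keep <- per_sample$n >= k
  kept_keys <- per_sample$key[keep]
  ref <- tibble::tibble(
    chrom = chroms[kept_keys %/% 2^32 + 1],
    pos = kept_keys %% 2^32,
    n_uses = usage$n[match(kept_keys, usage$key)],
    n_samples = per_sample$n[keep])
  ref$f_pos <- ref$n_uses / total_pooled
  ref <- dplyr::arrange(ref, .data$chrom, .data$pos)
  structure(list(positions = ref, k = k, w = w, pseudocount = pseudocount,
                 n_healthy = n, total_pooled = total_pooled),
            class = "cf_end_reference")
}

#' Information-weighted fraction of aberrant fragments (iwFAF)
#'
#' A fragment is aberrant when *neither* end lies within `w` bp of a
#' reference (recurrent healthy) end position. Each fragment is weighted by
#' the self-information `-log(p)` of its less frequent end under the healthy
#' end-usage distribution (pseudocounted for unseen positions), and iwFAF is
#' the weighted share of aberrant fragments, in `[0, 1]`.
#'
#' @param fragments mononucleosome-filtered fragment tibble.
#' @param reference a [build_end_position_reference()] object.
#' @return weighted aberrant fraction in `[0, 1]`.
#' @export
iwfaf <- function(fragments, reference) {
  if (!inherits(reference, "cf_end_reference") ||
      nrow(reference$positions) == 0)
    abort("empty end-position reference", class = "ctfrag_calibration_error")
  if (nrow(fragments) == 0)
    abort("iwfaf needs a non-empty fragment set", class = "ctfrag_insufficient_data")
  p0 <- reference$pseudocount / reference$total_pooled
  f_left <- match_end_freq(fragments$chrom, fragments$start, reference)
  f_right <- match_end_freq(fragments$chrom, fragments$end - 1, reference)
  aberrant <- is.na(f_left) & is.na(f_right)
  p_min <- pmin(ifelse(is.na(f_left), p0, f_left),
                ifelse(is.na(f_right), p0, f_right))
  wgt <- -log(p_min)
  sum(wgt[aberrant]) / sum(wgt)
}

# frequency of the nearest reference position within w bp, NA if none
match_end_freq <- function(chrom, pos, reference) {
  ref <- reference$positions
  w <- reference$w
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    rp <- ref[ref$chrom == ch, , drop = FALSE]
    sel <- which(chrom == ch)
    if (nrow(rp) == 0) next
    idx <- findInterval(pos[sel], rp$pos)
    lo <- pmax(idx, 1)
    hi <- pmin(idx + 1, nrow(rp))
    d_lo <- abs(pos[sel] - rp$pos[lo])
    d_hi <- abs(pos[sel] - rp$pos[hi])
    use_hi <- d_hi < d_lo
    best <- ifelse(use_hi, hi, lo)
    dist <- pmin(d_lo, d_hi)
    hit <- dist <= w
    out[sel[hit]] <- rp$f_pos[best[hit]]
  }
  out
}
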
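#' Read aligned paired-end cfDNA fragments from a BAM file
#'
#' Converts proper read pairs into fragments spanning the outer coordinates
#' of the pair (leftmost start to rightmost end, i.e. the TLEN span), with
#' the standard quality filters: minimum mapping quality, duplicate removal,
#' and autosome restriction. BAM 1-based positions are converted to the
#' package's 0-based half-open convention on read. End trinucleotides are
#' looked up from `reference_fasta` when provided (`motif5_left` is the
#' reference at the left 5' end; `motif5_right` the reverse complement of the
#' reference at the right end), otherwise set to the sentinel `"NNN"`.
#'
#' Requires the Bioconductor packages Rsamtools (and Biostrings for motif
#' lookup).
#'
#' @param path coordinate-sorted BAM file.
#' @param min_mapq minimum mapping quality (default 30).
#' @param drop_duplicates drop duplicate-flagged pairs (default TRUE).
#' @param autosomes_only drop chrX/chrY/chrM contigs (default TRUE).
#' @param reference_fasta optional indexed FASTA for end-motif lookup.
#' @param min_length,max_length fragment length bounds retained.
#' @param sample_id optional sample id to attach.
#' @return fragment tibble as in [read_fragment_table()].
#' @export
read_alignments <- function(path, min_mapq = 30, drop_duplicates = TRUE,
                            autosomes_only = TRUE, reference_fasta = NULL,
                            min_length = 50, max_length = Inf,
                            sample_id = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    abort("read_alignments() requires the Rsamtools package")
  if (!file.exists(path))
    abort(sprintf("BAM file not found: %s", path), class = "ctfrag_input_error")
  if (!is.null(reference_fasta) && !file.exists(reference_fasta))
    abort(sprintf("reference FASTA not found: %s", reference_fasta),
          class = "ctfrag_config_error")

  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                 isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "mapq", "isize", "flag"))
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  df <- tibble::tibble(chrom = as.character(rec$rname), pos = rec$pos,
                       mapq = rec$mapq, isize = rec$isize, flag = rec$flag)
  # one fragment per pair: the leftmost mate carries a positive TLEN
  df <- dplyr::filter(df, !is.na(.data$isize), .data$isize > 0, !is.na(.data$pos))
  df$is_duplicate <- bitwAnd(df$flag, 1024L) > 0L
  df <- dplyr::filter(df, .data$mapq >= min_mapq)
  if (drop_duplicates) df <- dplyr::filter(df, !.data$is_duplicate)
  if (autosomes_only) {
    sex_mt <- c("chrX", "chrY", "chrM", "chrMT", "X", "Y", "M", "MT")
    df <- dplyr::filter(df, !.data$chrom %in% sex_mt)
  }
  out <- tibble::tibble(chrom = df$chrom,
                        start = as.numeric(df$pos - 1L),
                        end = as.numeric(df$pos - 1L + df$isize),
                        length = as.integer(df$isize),
                        motif5_left = "NNN", motif5_right = "NNN",
                        mapq = as.integer(df$mapq),
                        is_duplicate = df$is_duplicate)
  out <- dplyr::filter(out, .data$length >= min_length, .data$length <= max_length)
  if (!is.null(reference_fasta) && nrow(out) > 0) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      abort("end-motif lookup requires the Biostrings package")
    fa <- Rsamtools::FaFile(reference_fasta)
    if (!file.exists(paste0(reference_fasta, ".fai"))) Rsamtools::indexFa(reference_fasta)
    left_gr <- GenomicRanges_safe(out$chrom, out$start + 1, out$start + 3)
    right_gr <- GenomicRanges_safe(out$chrom, out$end - 2, out$end)
    left_seq <- as.character(Rsamtools::scanFa(fa, left_gr))
    right_seq <- as.character(Biostrings::reverseComplement(
      Rsamtools::scanFa(fa, right_gr)))
    out$motif5_left <- toupper(left_seq)
    out$motif5_right <- toupper(right_seq)
    bad <- !grepl("^[ACGT]{3}$", out$motif5_left)
    out$motif5_left[bad] <- "NNN"
    bad <- !grepl("^[ACGT]{3}$", out$motif5_right)
    out$motif5_right[bad] <- "NNN"
  }
  if (!is.null(sample_id)) out <- dplyr::mutate(out, sample_id = sample_id, .before = 1)
  attr(out, "provenance") <- list(source = path, min_mapq = min_mapq,
                                  drop_duplicates = drop_duplicates,
                                  autosomes_only = autosomes_only,
                                  min_length = min_length)
  out
}

GenomicRanges_safe <- function(chrom, start, end) {
  if (!requireNamespace("GenomicRanges", quietly = TRUE) ||
      !requireNamespace("IRanges", quietly = TRUE))
    abort("motif lookup requires GenomicRanges/IRanges")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end))
}

#' Write a fragment set as a coordinate-sorted SAM file
#'
#' Emits one proper read pair (flags 99/147) per fragment with fixed read
#' length, suitable for conversion to BAM (`Rsamtools::asBam`) and
#' round-tripping through [read_alignments()]. Intended for exercising the
#' BAM reader against simulator output.
#'
#' @param fragments fragment tibble.
#' @param path output SAM path.
#' @param genome tibble with `chrom`, `length` for the SAM header.
#' @param read_length sequenced read length; capped at the fragment length.
#' @return `path`, invisibly.
#' @export
write_fragments_sam <- function(fragments, path, genome, read_length = 60) {
  fr <- dplyr::arrange(fragments, match(.data$chrom, genome$chrom), .data$start)
  rl <- pmin(fr$length, read_length)
  qname <- sprintf("frag%07d", seq_len(nrow(fr)))
  p1 <- fr$start + 1                     # SAM is 1-based
  p2 <- fr$end - rl + 1
  flag1 <- 99L + ifelse(fr$is_duplicate, 1024L, 0L)
  flag2 <- 147L + ifelse(fr$is_duplicate, 1024L, 0L)
  cigar <- sprintf("%dM", rl)
  seq1 <- vapply(rl, function(k) paste(rep("A", k), collapse = ""), "")
  qual <- vapply(rl, function(k) paste(rep("I", k), collapse = ""), "")
  rec1 <- paste(qname, flag1, fr$chrom, p1, fr$mapq, cigar, "=", p2,
                fr$length, seq1, qual, sep = "\t")
  rec2 <- paste(qname, flag2, fr$chrom, p2, fr$mapq, cigar, "=", p1,
                -fr$length, seq1, qual, sep = "\t")
  recs <- tibble::tibble(chrom = rep(fr$chrom, 2), pos = c(p1, p2),
                         line = c(rec1, rec2))
  recs <- dplyr::arrange(recs, match(.data$chrom, genome$chrom), .data$pos)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$chrom, as.integer(genome$length)))
  writeLines(c(header, recs$line), path)
  invisible(path)
}
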
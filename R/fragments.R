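#' Read a plain fragment table
#'
#' Reads a TSV of per-fragment records (one row per sequenced cfDNA fragment)
#' into the canonical fragment tibble. Required columns: `chrom`, `start`,
#' `end` (0-based half-open). Optional columns `length`, `motif5_left`,
#' `motif5_right`, `mapq`, `is_duplicate`, `sample_id` are filled with
#' defaults when absent. Rows violating the fragment invariants (`end >
#' start`, length below `min_length`, malformed motifs) are dropped and the
#' drop count reported.
#'
#' @param path TSV file; lines starting with `#` are treated as comments.
#' @param sample_id optional sample id to attach (overrides any column).
#' @param min_length minimum fragment length kept (bp). The additional
#'   short-fragment floor is configurable and reported, since callers may
#'   want a different lower cutoff than the 50 bp default.
#' @return fragment tibble; attribute `provenance` records the source path,
#'   filters applied and the number of dropped rows.
#' @export
read_fragment_table <- function(path, sample_id = NULL, min_length = 50) {
  if (!file.exists(path))
    abort(sprintf("fragment table not found: %s", path), class = "ctfrag_input_error")
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    abort(sprintf("fragment table missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "ctfrag_format_error")
  if (nrow(df) == 0) {
    warn("fragment table is empty; returning an empty fragment set")
    return(empty_fragments(sample_id))
  }
  df <- tibble::as_tibble(df)
  if (!"motif5_left" %in% names(df)) df$motif5_left <- "NNN"
  if (!"motif5_right" %in% names(df)) df$motif5_right <- "NNN"
  if (!"mapq" %in% names(df)) df$mapq <- 60L
  if (!"is_duplicate" %in% names(df)) df$is_duplicate <- FALSE
  df$length <- as.integer(df$end - df$start)

  motif_ok <- function(m) grepl("^[ACGT]{3}$", m) | m == "NNN"
  ok <- !is.na(df$start) & !is.na(df$end) & df$end > df$start &
    df$start >= 0 & df$length >= min_length &
    motif_ok(df$motif5_left) & motif_ok(df$motif5_right)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    inform(sprintf("read_fragment_table: dropped %d row(s) violating fragment invariants",
                   n_dropped))
  df <- df[ok, , drop = FALSE]
  if (!is.null(sample_id)) df$sample_id <- sample_id
  keep <- intersect(c("sample_id", "chrom", "start", "end", "length",
                      "motif5_left", "motif5_right", "mapq", "is_duplicate"),
                    names(df))
  out <- df[, keep]
  attr(out, "provenance") <- list(source = path, min_length = min_length,
                                  n_dropped = n_dropped)
  out
}

#' Write a fragment table to TSV
#'
#' Writes the canonical columns with a header comment recording the
#' generating seed (if known), so tables round-trip through
#' [read_fragment_table()].
#' @param fragments fragment tibble.
#' @param path output TSV path.
#' @export
write_fragment_table <- function(fragments, path) {
  seed <- attr(fragments, "seed")
  header <- c("# ctfrag fragment table",
              if (!is.null(seed)) sprintf("# seed=%d", seed))
  keep <- intersect(c("sample_id", "chrom", "start", "end", "length",
                      "motif5_left", "motif5_right", "mapq", "is_duplicate"),
                    names(fragments))
  writeLines(header, path)
  readr::write_tsv(fragments[, keep], path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

empty_fragments <- function(sample_id = NULL) {
  out <- tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                        length = integer(), motif5_left = character(),
                        motif5_right = character(), mapq = integer(),
                        is_duplicate = logical())
  if (!is.null(sample_id)) out <- dplyr::mutate(out, sample_id = character(), .before = 1)
  out
}

#' Write genomic intervals as a 3-column BED file
#'
#' @param intervals tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  readr::write_tsv(intervals[, c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a 3-column BED file of genomic intervals
#'
#' @param path BED file (0-based half-open; extra columns ignored).
#' @return tibble with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 3) abort("BED file needs >= 3 columns", class = "ctfrag_format_error")
  tibble::tibble(chrom = as.character(df[[1]]), start = as.numeric(df[[2]]),
                 end = as.numeric(df[[3]]))
}

#' Restrict a fragment set to the mononucleosomal peak
#'
#' Keeps fragments with `length <= max_length` (boundary inclusive). Applied
#' before all fragmentomic markers but *not* before copy-number binning,
#' which uses all fragment lengths.
#'
#' @param fragments fragment tibble.
#' @param max_length inclusive upper length bound in bp (default 250).
#' @return filtered fragment tibble.
#' @export
filter_mononucleosomal <- function(fragments, max_length = 250) {
  out <- dplyr::filter(fragments, .data$length <= max_length)
  attr(out, "provenance") <- c(attr(fragments, "provenance"),
                               list(max_length = max_length))
  out
}

#' Quality-filter a fragment set
#'
#' Applies the mapping-quality and duplicate filters used upstream of all
#' marker computations. Idempotent; commutes with [filter_mononucleosomal()].
#'
#' @param fragments fragment tibble.
#' @param min_mapq minimum mapping quality retained.
#' @param drop_duplicates drop fragments flagged as PCR/optical duplicates.
#' @return filtered fragment tibble.
#' @export
filter_fragments <- function(fragments, min_mapq = 30, drop_duplicates = TRUE) {
  out <- dplyr::filter(fragments, .data$mapq >= min_mapq)
  if (drop_duplicates) out <- dplyr::filter(out, !.data$is_duplicate)
  out
}
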
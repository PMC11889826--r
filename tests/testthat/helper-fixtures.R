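# Shared fixtures, built lazily once per test run and cached.

.tcache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .tcache)) assign(key, expr, envir = .tcache)
  get(key, envir = .tcache)
}

# small, fast configuration: 2 x 20 Mb genome, 80 bins, 5k fragments
test_config <- function(n_fragments = 5000,
                        cnv_segments = tibble::tibble(
                          chrom = c("chr1", "chr1", "chr2", "chr2"),
                          start = c(0, 10e6, 0, 8e6),
                          end = c(8e6, 18e6, 6e6, 18e6),
                          cn = c(4L, 4L, 0L, 1L)),
                        seed = 42L, ...) {
  sim_config(genome = tibble::tibble(chrom = c("chr1", "chr2"),
                                     length = c(2e7, 2e7)),
             n_fragments = n_fragments, cnv_segments = cnv_segments,
             seed = seed, ...)
}

test_bins <- function(cfg = test_config()) genome_bins(cfg$genome, cfg$bin_width)

# healthy cohort + reference on the small config
test_reference <- function() {
  cached("ref", {
    cfg <- test_config()
    healthy <- lapply(make_seeds(9001, 12),
                      function(sd) simulate_healthy_sample(cfg, seed = sd))
    list(cfg = cfg, healthy = healthy,
         ref = build_healthy_reference(healthy, test_bins(cfg)))
  })
}

# hand-built fragment tibble
make_fragments <- function(chrom, start, end, motif5_left = "AAA",
                           motif5_right = "AAA", mapq = 60L,
                           is_duplicate = FALSE) {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 length = as.integer(end - start),
                 motif5_left = motif5_left, motif5_right = motif5_right,
                 mapq = mapq, is_duplicate = is_duplicate)
}
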
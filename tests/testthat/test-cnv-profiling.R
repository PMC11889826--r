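test_that("fragments are assigned to the bin containing their midpoint", {
  bins <- genome_bins(tibble::tibble(chrom = "chr1", length = 1e7), 1e6)
  fr <- make_fragments("chr1", rep(6.2e6, 100), rep(6.2e6 + 166, 100))
  prof <- bin_counts(fr, bins)
  expect_equal(prof$raw_count[7], 100)
  expect_equal(sum(prof$raw_count), 100)
  # midpoint exactly on a bin boundary goes to the right-hand bin
  fr2 <- make_fragments("chr1", 2e6 - 83, 2e6 + 83)
  expect_equal(bin_counts(fr2, bins)$raw_count[3], 1)
  # uncovered contigs are excluded with a warning
  fr3 <- make_fragments(c("chr1", "chrZ"), c(0, 0), c(166, 166))
  expect_warning(p3 <- bin_counts(fr3, bins), "chrZ")
  expect_equal(sum(p3$raw_count), 1)
})

test_that("a CN=4 clone doubles segment coverage at tf = 1", {
  cfg <- test_config(
    n_fragments = 1e5,
    cnv_segments = tibble::tibble(chrom = "chr1", start = 0, end = 8e6, cn = 4L))
  bins <- test_bins(cfg)
  prof <- bin_counts(simulate_tumor_sample(cfg, tf = 1, seed = 3), bins)
  seg <- prof$chrom == "chr1" & prof$start < 8e6
  neutral <- !seg
  ratio <- mean(prof$raw_count[seg]) / median(prof$raw_count[neutral])
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("panel members normalize to near-zero log ratios", {
  cfg <- test_config(n_fragments = 1e5)
  bins <- test_bins(cfg)
  healthy <- lapply(make_seeds(71, 6),
                    function(sd) simulate_healthy_sample(cfg, seed = sd))
  raw <- lapply(healthy, bin_counts, bins = bins)
  panel <- build_panel(raw)
  norm <- normalize_profile(raw[[1]], panel)
  expect_lt(median(abs(norm$log2_ratio), na.rm = TRUE), 0.05)
  # |z| > 3 in < 1% of usable bins (calibration sanity)
  zrates <- sapply(raw, function(r) {
    n <- normalize_profile(r, panel)
    mean(abs(n$z) > 3, na.rm = TRUE)
  })
  expect_lt(mean(zrates), 0.01)
})

test_that("normalization is invariant to global library-size scaling", {
  cfg <- test_config()
  bins <- test_bins(cfg)
  healthy <- lapply(make_seeds(72, 5),
                    function(sd) simulate_healthy_sample(cfg, seed = sd))
  raw <- lapply(healthy, bin_counts, bins = bins)
  panel <- build_panel(raw)
  test_raw <- bin_counts(simulate_healthy_sample(cfg, seed = 99), bins)
  doubled <- test_raw
  doubled$raw_count <- doubled$raw_count * 2L
  expect_equal(normalize_profile(test_raw, panel)$log2_ratio,
               normalize_profile(doubled, panel)$log2_ratio)
})

test_that("segment log ratios recover the closed-form mixture expectation", {
  # CN = 3 at tf = 0.2: expected ratio log2((2*0.8 + 3*0.2)/2) = log2(1.1);
  # a balancing loss on chr2 keeps the genome median copy-neutral
  cfg <- test_config(
    n_fragments = 1e5,
    cnv_segments = tibble::tibble(chrom = c("chr1", "chr2"),
                                  start = c(0, 0), end = c(8e6, 8e6),
                                  cn = c(3L, 1L)))
  bins <- test_bins(cfg)
  healthy <- lapply(make_seeds(73, 6),
                    function(sd) simulate_healthy_sample(cfg, seed = sd))
  panel <- build_panel(lapply(healthy, bin_counts, bins = bins))
  norm <- normalize_profile(bin_counts(simulate_tumor_sample(cfg, 0.2, seed = 12),
                                       bins), panel)
  seg_mean <- mean(norm$log2_ratio[norm$chrom == "chr1" & norm$start < 8e6],
                   na.rm = TRUE)
  expect_lt(abs(seg_mean - log2(1.1)), 0.03)
})

test_that("segmentation returns one segment per chromosome on flat profiles", {
  bins <- genome_bins(tibble::tibble(chrom = c("chr1", "chr2"),
                                     length = c(5e7, 5e7)), 5e5)
  prof <- bins
  withr::with_seed(8, prof$log2_ratio <- rnorm(nrow(bins), 0, 0.01))
  prof$z <- prof$log2_ratio / 0.01
  segs <- segment_profile(prof)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$n_bins, c(100, 100))
})

test_that("a single step is recovered within one bin", {
  bins <- genome_bins(tibble::tibble(chrom = "chr1", length = 5e7), 5e5)
  prof <- bins
  truth <- rep(0, 100)
  truth[41:60] <- 0.5
  withr::with_seed(9, prof$log2_ratio <- truth + rnorm(100, 0, 0.05))
  prof$z <- prof$log2_ratio / 0.05
  segs <- segment_profile(prof)
  expect_equal(nrow(segs), 3)
  starts <- segs$start / 5e5
  expect_lte(abs(starts[2] - 40), 1)
  expect_lte(abs(starts[3] - 60), 1)
  # segment means equal brute-force per-segment averages
  for (s in seq_len(nrow(segs))) {
    i <- prof$start >= segs$start[s] & prof$start < segs$end[s]
    expect_equal(segs$mean_ratio[s], mean(prof$log2_ratio[i]))
  }
})

test_that("length-weighted segment means conserve the genome-wide mean", {
  cfg <- test_config(n_fragments = 2e4)
  bins <- test_bins(cfg)
  healthy <- lapply(make_seeds(74, 5),
                    function(sd) simulate_healthy_sample(cfg, seed = sd))
  panel <- build_panel(lapply(healthy, bin_counts, bins = bins))
  norm <- normalize_profile(bin_counts(simulate_tumor_sample(cfg, 0.3, seed = 5),
                                       bins), panel)
  segs <- segment_profile(norm)
  # all bins are equal width here, so the bin-weighted segment average must
  # equal the genome-wide mean ratio
  expect_equal(sum(segs$mean_ratio * segs$n_bins) / sum(segs$n_bins),
               mean(norm$log2_ratio, na.rm = TRUE), tolerance = 1e-10)
})

test_that("bin set mismatches are rejected", {
  cfg <- test_config()
  bins <- test_bins(cfg)
  healthy <- lapply(make_seeds(75, 5),
                    function(sd) simulate_healthy_sample(cfg, seed = sd))
  panel <- build_panel(lapply(healthy, bin_counts, bins = bins))
  other_bins <- genome_bins(cfg$genome, 1e6)
  raw <- bin_counts(simulate_healthy_sample(cfg, seed = 1), other_bins)
  expect_error(normalize_profile(raw, panel), class = "ctfrag_config_error")
})
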
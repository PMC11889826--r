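test_that("P126-135 counts the inclusive window over all fragments", {
  all130 <- make_fragments("chr1", rep(0, 4), rep(130, 4))
  expect_equal(p126_135(all130, min_fragments = 1), 1)
  mix <- make_fragments("chr1", rep(0, 4), c(126, 135, 136, 200))
  expect_equal(p126_135(mix, min_fragments = 1), 0.5)
  none <- make_fragments("chr1", rep(0, 3), c(166, 180, 200))
  expect_equal(p126_135(none, min_fragments = 1), 0)
  expect_error(p126_135(none), class = "ctfrag_insufficient_data")
})

test_that("D126-135 is the absolute two-sided deviation from the healthy median", {
  healthy <- c(0.06, 0.07, 0.08)
  expect_equal(d126_135(0.07, healthy), 0)
  expect_equal(d126_135(0.10, healthy), 0.03)
  expect_equal(d126_135(0.04, healthy), 0.03)  # reductions count equally
  expect_error(d126_135(0.07, c(0.06, 0.07)), class = "ctfrag_calibration_error")
})

test_that("end motif counts cover both 5' ends and exclude the sentinel", {
  fr <- make_fragments("chr1", 0, 166, motif5_left = "AAA", motif5_right = "CCC")
  counts <- end_motif_counts(fr)
  expect_equal(sum(counts), 2)
  expect_equal(counts[["AAA"]], 1)
  expect_equal(counts[["CCC"]], 1)
  fr2 <- make_fragments("chr1", rep(0, 10), rep(166, 10))
  expect_equal(sum(end_motif_counts(fr2)), 20)
  frN <- make_fragments("chr1", 0, 166, motif5_left = "NNN", motif5_right = "NNN")
  expect_error(end_motif_counts(frN), class = "ctfrag_insufficient_data")
  expect_equal(sum(end_motif_counts(dplyr::bind_rows(fr, frN))), 2)
})

test_that("MDS is normalized Shannon entropy over the 64 motifs", {
  uniform <- setNames(rep(5L, 64), ctfrag:::TRINUCLEOTIDES)
  expect_equal(mds(uniform), 1)
  single <- setNames(c(100L, rep(0L, 63)), ctfrag:::TRINUCLEOTIDES)
  expect_equal(mds(single), 0)
  counts <- setNames(rep(0L, 64), ctfrag:::TRINUCLEOTIDES)
  counts[c("AAA", "CCC", "GGG")] <- c(2L, 1L, 1L)
  expect_equal(mds(counts), 0.25)   # 1.5 bits / 6 bits
  # invariant to motif relabeling
  perm <- withr::with_seed(2, sample(64))
  expect_equal(mds(setNames(counts[perm], ctfrag:::TRINUCLEOTIDES)), mds(counts))
})

test_that("simulated end motifs follow the configured simplex", {
  # disable the Alu emission override so all motifs come from the simplex
  cfg <- test_config(n_fragments = 20000,
                     alu_model = default_alu_model(healthy_cgn = 0,
                                                   healthy_ncg = 0))
  fr <- simulate_healthy_sample(cfg, seed = 77)
  counts <- end_motif_counts(fr)
  f <- counts / sum(counts)
  p <- cfg$motif_model$healthy_probs
  for (m in c("AAA", "ACG", "CGA", "TTT")) {
    se <- sqrt(p[[m]] * (1 - p[[m]]) / sum(counts))
    expect_lt(abs(f[[m]] - p[[m]]), 3 * se + 1e-6)
  }
})

test_that("Alu CGN/NCG ratio counts CG-leading vs CG-trailing end motifs", {
  alu <- tibble::tibble(chrom = "chr1", start = 1000, end = 2000)
  # 30 CGN ends + 15 NCG ends inside the Alu; right ends sit outside with
  # neutral motifs
  fr <- make_fragments("chr1", rep(1100, 45), rep(1100 + 5000, 45),
                       motif5_left = c(rep("CGA", 30), rep("ACG", 15)),
                       motif5_right = "TTT")
  expect_equal(alu_cgn_ncg_ratio(fr, alu, min_alu_ends = 1), 30.5 / 15.5)
  # equal counts give exactly 1 (pseudocounts cancel)
  fr2 <- make_fragments("chr1", rep(1100, 20), rep(6100, 20),
                        motif5_left = rep(c("CGT", "TCG"), 10),
                        motif5_right = "AAA")
  expect_equal(alu_cgn_ncg_ratio(fr2, alu, min_alu_ends = 1), 1)
  expect_error(alu_cgn_ncg_ratio(fr2, alu, min_alu_ends = 200),
               class = "ctfrag_insufficient_data")
})

test_that("CGN and NCG patterns are disjoint for trinucleotides", {
  alu <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  ratio_for <- function(motif) {
    fr <- make_fragments("chr1", rep(10, 8), rep(5000, 8),
                         motif5_left = motif, motif5_right = "TAT")
    alu_cgn_ncg_ratio(fr, alu, min_alu_ends = 1, pseudocount = 0.5)
  }
  expect_equal(ratio_for("CGG"), 8.5 / 0.5)  # CGN only
  expect_equal(ratio_for("GCG"), 0.5 / 8.5)  # NCG only
  expect_equal(ratio_for("CCG"), 0.5 / 8.5)  # NCG only
  expect_equal(ratio_for("TAA"), 1)          # neither
})

test_that("end-position reference applies the k-of-n recurrence rule", {
  # 5 healthy samples; position 5000 used by all, 6000 by one sample only
  mk <- function(extra) make_fragments("chr1", c(5000, extra),
                                       c(5000 + 166, extra + 166))
  healthy <- list(mk(6000), mk(7000), mk(8000), mk(9000), mk(10000))
  ref <- build_end_position_reference(healthy, k = 2)
  expect_true(5000 %in% ref$positions$pos)
  expect_false(6000 %in% ref$positions$pos)
  # pooled usage frequency: 5 uses / (5 samples * 4 ends)
  expect_equal(ref$positions$f_pos[ref$positions$pos == 5000], 5 / 20)
  # raising k shrinks the reference monotonically
  sizes <- vapply(1:5, function(k)
    nrow(build_end_position_reference(healthy, k = k)$positions), 1L)
  expect_true(all(diff(sizes) <= 0))
  expect_error(build_end_position_reference(healthy[1:4]),
               class = "ctfrag_calibration_error")
})

test_that("iwFAF is the weighted share of fragments with two aberrant ends", {
  healthy <- lapply(1:5, function(i)
    make_fragments("chr1", c(1000, 3000), c(1000 + 166, 3000 + 166)))
  ref <- build_end_position_reference(healthy, k = 5)
  # all ends at reference positions -> 0
  at_ref <- make_fragments("chr1", c(1000, 3000), c(1166, 3166))
  expect_equal(iwfaf(at_ref, ref), 0)
  # one end at a reference position still counts as concordant
  one_end <- make_fragments("chr1", 1000, 1000 + 200)
  expect_equal(iwfaf(one_end, ref), 0)
  # no end anywhere near the reference -> 1
  off <- make_fragments("chr1", c(50000, 60000), c(50166, 60166))
  expect_equal(iwfaf(off, ref), 1)
  # 2 of 4 aberrant with all fragments equal-weight: pseudocount chosen so
  # unseen ends carry the same frequency as reference ends -> exactly 0.5
  ref_eq <- build_end_position_reference(healthy, k = 5, pseudocount = 5)
  mix <- make_fragments("chr1", c(1000, 3000, 50000, 60000),
                        c(1166, 3166, 50166, 60166))
  expect_equal(iwfaf(mix, ref_eq), 0.5)
  # unequal weights: brute force from the self-information definition
  f_ref <- 5 / 20
  p0 <- 0.5 / 20
  expect_equal(iwfaf(mix, ref),
               (2 * -log(p0)) / (2 * -log(p0) + 2 * -log(f_ref)))
  expect_error(iwfaf(mix, build_end_position_reference(healthy, k = 6)),
               class = "ctfrag_calibration_error")
})

test_that("iwFAF matching honours the window parameter", {
  healthy <- lapply(1:5, function(i)
    make_fragments("chr1", 1000, 1166))
  ref0 <- build_end_position_reference(healthy, k = 5, w = 0)
  ref5 <- build_end_position_reference(healthy, k = 5, w = 5)
  near <- make_fragments("chr1", 1003, 1003 + 200)
  expect_equal(iwfaf(near, ref0), 1)
  expect_equal(iwfaf(near, ref5), 0)
})

test_that("fragmentomic markers stay within their ranges on simulated data", {
  fx <- test_reference()
  alu <- alu_intervals(fx$cfg)
  for (tf in c(0, 0.2)) {
    m <- filter_mononucleosomal(simulate_tumor_sample(fx$cfg, tf, seed = 31))
    p <- p126_135(m)
    iw <- iwfaf(m, fx$ref$end_ref)
    expect_true(p >= 0 && p <= 1)
    expect_true(iw >= 0 && iw <= 1)
    expect_gte(d126_135(p, fx$ref$healthy_p126), 0)
    md <- mds(end_motif_counts(m))
    expect_true(md >= 0 && md <= 1)
    expect_gt(alu_cgn_ncg_ratio(m, alu), 0)
  }
})
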
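test_that("healthy sampler conserves fragment counts and respects length bounds", {
  cfg <- test_config(n_fragments = 10000)
  fr <- simulate_healthy_sample(cfg, seed = 1)
  expect_equal(nrow(fr), 10000)
  expect_true(all(fr$length >= cfg$min_length))
  expect_true(all(fr$end > fr$start))
  expect_true(all(fr$length == fr$end - fr$start))
  expect_true(all(fr$chrom %in% cfg$genome$chrom))
  lens <- cfg$genome$length[match(fr$chrom, cfg$genome$chrom)]
  expect_true(all(fr$start >= 0 & fr$end <= lens))
})

test_that("identical (config, seed) give byte-identical fragment tables", {
  cfg <- test_config()
  a <- simulate_healthy_sample(cfg, seed = 7)
  b <- simulate_healthy_sample(cfg, seed = 7)
  expect_identical(a, b)
  tf_a <- simulate_tumor_sample(cfg, 0.1, seed = 7)
  tf_b <- simulate_tumor_sample(cfg, 0.1, seed = 7)
  expect_identical(tf_a, tf_b)
  expect_false(identical(a, simulate_healthy_sample(cfg, seed = 8)))
})

test_that("tf = 0 tumor sampler is exactly the healthy sampler", {
  cfg <- test_config()
  expect_identical(simulate_healthy_sample(cfg, seed = 3),
                   simulate_tumor_sample(cfg, 0, seed = 3))
})

test_that("empirical short-fragment mass matches the analytic window mass", {
  cfg <- test_config(n_fragments = 20000)
  # independent oracle: integrate the configured Gaussian mixture over the
  # discrete support and take the window share
  comp <- cfg$length_model$healthy
  support <- cfg$min_length:cfg$length_model$max_length
  dens <- rep(0, length(support))
  for (i in seq_len(nrow(comp)))
    dens <- dens + comp$weight[i] * (pnorm(support + 0.5, comp$mean[i], comp$sd[i]) -
                                     pnorm(support - 0.5, comp$mean[i], comp$sd[i]))
  mass <- sum(dens[support >= 126 & support <= 135]) / sum(dens)
  expect_equal(length_window_mass(cfg$length_model, c(126, 135),
                                  min_length = cfg$min_length),
               mass, tolerance = 1e-12)
  fr <- simulate_healthy_sample(cfg, seed = 5)
  p_hat <- mean(fr$length >= 126 & fr$length <= 135)
  se <- sqrt(mass * (1 - mass) / nrow(fr))
  expect_lt(abs(p_hat - mass), 3 * se)
})

test_that("homozygous deletions receive no fragments at tf = 1", {
  cfg <- test_config(
    cnv_segments = tibble::tibble(chrom = "chr1", start = 5e6, end = 10e6, cn = 0L),
    end_position_model = default_end_position_model(p_adhere = 0))
  fr <- simulate_tumor_sample(cfg, tf = 1, seed = 2)
  inside <- fr$chrom == "chr1" & fr$start >= 5e6 & fr$start < 10e6
  expect_equal(sum(inside), 0)
  expect_true(all(fr$tumor_origin))
})

test_that("tumor fragment sets are nested across a coupled dilution series", {
  cfg <- test_config()
  dil <- simulate_dilution_series(cfg, c(0.05, 0.1, 0.2), seed = 9)
  # nesting can break only for the few fragments whose copy-number interval
  # assignment shifts with tf; require near-perfect nesting
  viol12 <- mean(dil[[1]]$tumor_origin & !dil[[2]]$tumor_origin)
  viol23 <- mean(dil[[2]]$tumor_origin & !dil[[3]]$tumor_origin)
  expect_lt(viol12, 0.02)
  expect_lt(viol23, 0.02)
  expect_equal(sapply(dil, function(d) mean(d$tumor_origin)) > c(0.02, 0.07, 0.15),
               setNames(rep(TRUE, 3), names(dil)))
})

test_that("mean P126-135 increases with tumor fraction", {
  cfg <- test_config()
  tfs <- c(0, 0.05, 0.1, 0.2)
  seeds <- make_seeds(31, 8)
  m <- sapply(tfs, function(tf) {
    mean(sapply(seeds, function(sd) {
      fr <- filter_mononucleosomal(simulate_tumor_sample(cfg, tf, seed = sd))
      p126_135(fr)
    }))
  })
  expect_true(all(diff(m) > 0))
})

test_that("invalid configurations raise errors naming the offending field", {
  expect_error(test_config(duplicate_rate = 2), "duplicate_rate")
  expect_error(test_config(cnv_segments = tibble::tibble(
    chrom = "chr1", start = 0, end = 3e7, cn = 3L)), "cnv_segments")
  expect_error(test_config(cnv_segments = tibble::tibble(
    chrom = c("chr1", "chr1"), start = c(0, 1e6), end = c(2e6, 3e6),
    cn = c(3L, 3L))), "non-overlapping")
  expect_error(
    sim_config(motif_model = list(healthy_probs = rep(1, 64),
                                  tumor_probs = rep(1 / 64, 64))),
    "motif_model")
  expect_error(simulate_tumor_sample(test_config(), tf = 1.2, seed = 1),
               class = "ctfrag_domain_error")
})

test_that("simulated cohorts satisfy their structural invariants", {
  cfg <- test_config(n_fragments = 1500,
                     cohort_model = default_cohort_model(n_healthy = 3, n_subjects = 6))
  cohort <- simulate_cohort(cfg)
  expect_false(anyDuplicated(cohort$samples$sample_id) > 0)
  expect_false(anyDuplicated(cohort$truth$subject_id) > 0)
  expect_true(all(cohort$samples$subject_id[cohort$samples$timepoint != "healthy"]
                  %in% cohort$clinical$subject_id))
  expect_true(all(cohort$clinical$os_months >= cohort$clinical$pfs_months))
  expect_true(all(cohort$truth$cycle4_tf ==
                    cohort$truth$baseline_tf * ifelse(cohort$truth$responder, 0,
                                                      cfg$cohort_model$residual_factor)))
  # responders (response factor 0) have cycle-4 tf exactly 0
  expect_true(all(cohort$truth$cycle4_tf[cohort$truth$responder] == 0))
  # truth tf recorded for every sample
  expect_true(all(!is.na(cohort$samples$tf)))
  # determinism of the whole cohort
  cohort2 <- simulate_cohort(cfg)
  expect_identical(cohort$samples$fragments, cohort2$samples$fragments)
  expect_identical(cohort$clinical, cohort2$clinical)
})

test_that("outcome model links hazard to the residual flag as configured", {
  flags <- rep(c(TRUE, FALSE), each = 2000)
  om <- default_outcome_model(censor_rate = 0, horizon = Inf)
  withr::with_seed(1, {
    oc <- simulate_outcomes(flags, om)
    # exponential medians scale as 1/hazard ratio
    ratio <- median(oc$pfs_months[!flags]) / median(oc$pfs_months[flags])
    expect_equal(ratio, exp(om$log_hr_residual), tolerance = 0.15)
    expect_true(all(oc$os_months >= oc$pfs_months))
    # null model: no hazard link
    oc0 <- simulate_outcomes(flags, default_outcome_model(log_hr_residual = 0,
                                                          censor_rate = 0))
    r0 <- median(oc0$pfs_months[!flags]) / median(oc0$pfs_months[flags])
    expect_equal(r0, 1, tolerance = 0.15)
  })
})
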
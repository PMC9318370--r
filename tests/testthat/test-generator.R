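sr_base <- function(...) {
  utils::modifyList(
    list(mean_rr_mu = 800, mean_rr_sigma = 0, resp_amplitude = 0,
         resp_frequency = 0.25, lf_amplitude = 0, lf_frequency = 0.05,
         ar1_coefficient = 0.8, noise_sd = 15, noise_sd_cv = 0,
         ectopy_rate = 0, ectopy_rate_sd = 0, ectopy_early = 0.75),
    list(...))
}

af_base <- function(...) {
  utils::modifyList(
    list(mean_rr_mu = 650, mean_rr_sigma = 0, dispersion_cv = 0.2,
         dispersion_cv_sd = 0, dispersion_cv_range = c(0.04, 0.35),
         lag1_corr = 0, lag1_corr_range = c(0, 0.2)),
    list(...))
}

test_that("noise-free SR series is constant with zero pRR50 and covers the duration minimally", {
  rec <- generate_sr_series(sr_base(noise_sd = 0), 60, seed = 1)
  expect_true(all(rec$rr_ms == 800))
  expect_equal(length(rec$rr_ms), 75)   # minimal prefix: 75 * 800 = 60000
  expect_true(all(rec$rhythm_label == "SR"))
  fv <- compute_features(make_segment(rec$rr_ms))
  expect_equal(fv$pRR50, 0)
})

test_that("generated series reach the requested duration with a minimal prefix", {
  for (s in 1:5) {
    rec <- generate_sr_series(sr_base(), 120, seed = s)
    expect_gte(sum(rec$rr_ms), 120000)
    expect_lt(sum(rec$rr_ms[-length(rec$rr_ms)]), 120000)
    rec <- generate_af_series(af_base(), 120, seed = s)
    expect_gte(sum(rec$rr_ms), 120000)
    expect_lt(sum(rec$rr_ms[-length(rec$rr_ms)]), 120000)
  }
})

test_that("series generation is deterministic in the seed", {
  a <- generate_sr_series(sr_base(), 300, seed = 42)
  b <- generate_sr_series(sr_base(), 300, seed = 42)
  expect_identical(a, b)
  expect_false(identical(
    a$rr_ms, generate_sr_series(sr_base(), 300, seed = 43)$rr_ms))
  expect_error(generate_sr_series(sr_base(), -5, seed = 1), "positive")
  expect_error(generate_af_series(af_base(), 0, seed = 1), "positive")
})

test_that("SR lag-1 autocorrelation matches the AR(1) coefficient against a sample oracle", {
  # pure AR(1) configuration: no respiratory or low-frequency modulation
  acs <- vapply(1:10, function(s) {
    rr <- generate_sr_series(sr_base(ar1_coefficient = 0.8), 600, seed = s)$rr_ms
    stats::cor(rr[-1], rr[-length(rr)])
  }, numeric(1))
  expect_true(all(abs(acs - 0.8) < 0.1))
})

test_that("AF series realizes the target coefficient of variation", {
  for (s in 1:5) {
    rr <- generate_af_series(af_base(dispersion_cv = 0.2), 600, seed = s)$rr_ms
    cv <- stats::sd(rr) / mean(rr)
    expect_gte(cv, 0.16)
    expect_lte(cv, 0.24)
  }
  # blending leaves the CV on target
  rr <- generate_af_series(af_base(dispersion_cv = 0.2, lag1_corr = 0.2),
                           600, seed = 1)$rr_ms
  expect_gte(stats::sd(rr) / mean(rr), 0.16)
  expect_lte(stats::sd(rr) / mean(rr), 0.24)
})

test_that("AF variability vanishes in the zero-dispersion limit", {
  rr <- generate_af_series(af_base(dispersion_cv = 0), 60, seed = 3)$rr_ms
  expect_true(all(rr == 650))
  expect_equal(compute_features(make_segment(rr))$pRR50, 0)
})

test_that("artifact injection follows the binomial rate and is the only out-of-range source", {
  rec <- generate_sr_series(sr_base(mean_rr_mu = 600), 6000, seed = 9)
  n <- length(rec$rr_ms)
  expect_gt(n, 9900)
  same <- inject_artifacts(rec, 0, seed = 1)
  expect_identical(same$rr_ms, rec$rr_ms)

  small <- generate_sr_series(sr_base(), 4, seed = 2)
  all_art <- inject_artifacts(small, 1, seed = 1)
  expect_true(all(all_art$beat_label == "artifact"))

  inj <- inject_artifacts(rec, 0.02, seed = 5)
  k <- attr(inj, "n_injected")
  expect_lt(abs(k - 0.02 * n), 3 * sqrt(0.02 * n))   # binomial 3-sigma band
  out_of_range <- inj$rr_ms < 240 | inj$rr_ms > 3000
  expect_true(all(inj$beat_label[out_of_range] == "artifact"))
  expect_true(all(inj$rr_ms > 0))
})

test_that("cohort generation is reproducible and carries the expected structure", {
  cfg <- generator_config(n_patients_per_class = 4, recording_duration = 120,
                          seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  man <- cohort_manifest(a)
  expect_equal(nrow(man), 8)
  expect_setequal(unique(man$database_tag), c("SYN-A", "SYN-B"))
  # mixed patients have exactly one labeled transition
  for (rec in a[man$mixed]) {
    expect_equal(sum(diff(as.integer(factor(rec$rhythm_label))) != 0), 1)
  }
})

test_that("AF cohorts have larger successive-difference variability than SR cohorts", {
  cfg <- generator_config(n_patients_per_class = 8, recording_duration = 300,
                          seed = 31, artifact_rate = 0,
                          mixed_rhythm_fraction = 0)
  tab <- build_feature_table(segment_cohort(generate_cohort(cfg))$segments)
  med <- tapply(tab$pRR50, tab$rhythm_class, median)
  expect_gt(med[["AF"]], med[["SR"]])
})

test_that("class overlap is smaller for pRR50 than for mean RR", {
  overlap_coef <- function(x, cls) {
    br <- seq(min(x), max(x), length.out = 21)
    p <- hist(x[cls == "AF"], breaks = br, plot = FALSE)$counts
    q <- hist(x[cls == "SR"], breaks = br, plot = FALSE)$counts
    sum(pmin(p / sum(p), q / sum(q)))
  }
  cfg <- generator_config(n_patients_per_class = 20,
                          recording_duration = 300, seed = 13)
  tab <- build_feature_table(segment_cohort(generate_cohort(cfg))$segments)
  expect_lt(overlap_coef(tab$pRR50, tab$rhythm_class),
            overlap_coef(tab$meanRR, tab$rhythm_class))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(artifact_rate = 1.5))
  expect_error(generator_config(sr_params = list(ar1_coefficient = 1)))
  expect_error(generator_config(af_params = list(lag1_corr = 0.5)))
  expect_error(generator_config(recording_duration = 0))
})
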
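test_that("a constant pure-SR recording tiles into full windows of 75 intervals", {
  rec <- rr_recording("P1", "T", rep(800, 750), rep("sinus", 750),
                      rep("SR", 750))          # 600 s exactly
  out <- segment_recording(rec)
  expect_length(out$segments, 10)
  for (seg in out$segments) {
    expect_equal(length(seg$rr_ms), 75)
    expect_equal(seg$removed_ms_total, 0)
    expect_true(all(seg$adjacency))
  }
  expect_equal(out$segments[[4]]$segment_index, 3)
})

test_that("a single long artifact below the 6 s budget is removed but the window kept", {
  rr <- c(rep(800, 40), 3500, rep(800, 40))    # 67.5 s total
  rec <- rr_recording("P1", "T", rr, rep("sinus", 81), rep("SR", 81))
  out <- segment_recording(rec)
  expect_length(out$segments, 1)
  seg <- out$segments[[1]]
  expect_equal(seg$n_removed, 1L)
  expect_equal(seg$removed_ms_total, 3500)
  # adjacency is broken exactly once, and pair count drops by 2
  expect_equal(sum(!seg$adjacency), 1)
  expect_equal(nrow(successive_pairs(seg)), length(seg$rr_ms) - 2)
})

test_that("removed duration at or above 10% of the window discards it (inclusive)", {
  # removed intervals summing 6300 ms (> 6000): discard
  rr <- c(rep(800, 30), 3200, rep(800, 30), 3100, rep(800, 20))
  rec <- rr_recording("P1", "T", rr, rep("sinus", length(rr)),
                      rep("SR", length(rr)))
  out <- segment_recording(rec)
  expect_true("excess_removed" %in% out$qc$outcome)
  # exactly at the boundary: removed sum == 6000 must also discard
  rr2 <- c(rep(800, 30), 4500, 1500, rep(100, 15), rep(800, 40))
  rec2 <- rr_recording("P2", "T", rr2, rep("sinus", length(rr2)),
                       rep("SR", length(rr2)))
  # removed in window 0: 4500 + 15 * 100 = 6000 exactly
  out2 <- segment_recording(rec2)
  expect_equal(out2$qc$outcome[1], "excess_removed")
})

test_that("windows mixing rhythms or containing other rhythms are excluded", {
  rr <- rep(750, 90)
  rec <- rr_recording("P1", "T", rr, rep("sinus", 90),
                      rep(c("SR", "AF"), c(45, 45)))
  out <- segment_recording(rec)
  expect_length(out$segments, 0)
  expect_equal(out$qc$outcome[1], "mixed_rhythm")

  rec2 <- rr_recording("P2", "T", rr, rep("sinus", 90),
                       rep(c("SR", "other"), c(60, 30)))
  out2 <- segment_recording(rec2)
  expect_equal(out2$qc$outcome[1], "other_rhythm")
})

test_that("window tiling assigns every interval of complete windows exactly once", {
  for (s in 1:5) {
    rec <- generate_af_series(
      list(mean_rr_mu = 700, mean_rr_sigma = 0, dispersion_cv = 0.25,
           lag1_corr = 0), 200, seed = s)
    cfg <- segmentation_config(min_retained_intervals = 2)
    out <- segment_recording(rec, cfg)
    start <- cumsum(c(0, rec$rr_ms[-length(rec$rr_ms)]))
    n_complete <- floor(sum(rec$rr_ms) / 60000)
    expected <- sum(start < n_complete * 60000)
    got <- sum(vapply(out$segments, function(s2)
      length(s2$rr_ms) + s2$n_removed, numeric(1)))
    expect_equal(got, expected)
  }
})

test_that("loosening the filters never decreases the surviving-segment count", {
  cfg <- generator_config(n_patients_per_class = 4, recording_duration = 240,
                          seed = 3, artifact_rate = 0.05)
  cohort <- generate_cohort(cfg)
  strict <- segmentation_config()
  loose_bounds <- segmentation_config(rr_min_ms = 100, rr_max_ms = 7000)
  loose_frac <- segmentation_config(max_removed_fraction = 0.5)
  n <- function(c) length(segment_cohort(cohort, c)$segments)
  expect_gte(n(loose_bounds), n(strict))
  expect_gte(n(loose_frac), n(strict))
})

test_that("emitted segments are pure and in-range", {
  cfg <- generator_config(n_patients_per_class = 6, recording_duration = 240,
                          seed = 8, artifact_rate = 0.03)
  out <- segment_cohort(generate_cohort(cfg))
  for (seg in out$segments) {
    expect_true(seg$rhythm_class %in% c("AF", "SR"))
    expect_true(all(seg$rr_ms >= 240 & seg$rr_ms <= 3000))
    expect_lt(seg$removed_ms_total, 6000)
    expect_equal(length(seg$adjacency), length(seg$rr_ms) - 1)
  }
})

test_that("filtering summary reproduces totals, handles no-op filters and empty input", {
  fx <- make_filter_fixtures()
  out <- segment_cohort(fx)
  tab <- summarize_filtering(out$qc)
  expect_equal(sum(tab$filtered), 3)        # pure_sr, pure_af, artifact_light
  expect_equal(sum(tab$total), 4)           # + artifact_heavy (pure SR window)

  noop <- segmentation_config(rr_min_ms = 1, rr_max_ms = 1e9,
                              max_removed_fraction = 1,
                              min_retained_intervals = 2)
  tab2 <- summarize_filtering(segment_cohort(fx, noop)$qc)
  expect_equal(tab2$total, tab2$filtered)

  empty <- summarize_filtering(segment_cohort(list(), noop)$qc)
  expect_true(all(empty$total == 0) && all(empty$filtered == 0))
})

test_that("short recordings yield no windows", {
  rec <- rr_recording("P1", "T", rep(800, 10), rep("sinus", 10),
                      rep("SR", 10))
  out <- segment_recording(rec)
  expect_length(out$segments, 0)
  expect_equal(nrow(out$qc), 0)
})
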
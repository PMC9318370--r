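#' Annotated RR-interval recording
#'
#' Container for one patient's beat-to-beat record: interval durations in
#' milliseconds plus a per-interval beat-type label (sinus, supraventricular,
#' ventricular, artifact) and rhythm label (AF, SR, other), mirroring the
#' annotation streams of Holter arrhythmia databases.
#'
#' @param patient_id,database_tag provenance strings.
#' @param rr_ms positive interval durations (ms).
#' @param beat_label per-interval beat codes.
#' @param rhythm_label per-interval rhythm codes, `"AF"`, `"SR"` or `"other"`.
#' @return an object of class `rr_recording`.
#' @export
rr_recording <- function(patient_id, database_tag, rr_ms, beat_label,
                         rhythm_label) {
  rr_ms <- as.numeric(rr_ms)
  n <- length(rr_ms)
  if (n < 1L) stop("an rr_recording needs at least one interval")
  if (length(beat_label) != n || length(rhythm_label) != n) {
    stop("rr_ms, beat_label and rhythm_label must have equal length")
  }
  if (any(!is.finite(rr_ms)) || any(rr_ms <= 0)) {
    stop("all RR durations must be finite and strictly positive")
  }
  structure(
    list(patient_id = as.character(patient_id),
         database_tag = as.character(database_tag),
         rr_ms = rr_ms,
         beat_label = as.character(beat_label),
         rhythm_label = as.character(rhythm_label)),
    class = "rr_recording")
}

#' @export
print.rr_recording <- function(x, ...) {
  cat(sprintf("<rr_recording> %s [%s]: %d intervals, %.1f min, rhythms: %s\n",
              x$patient_id, x$database_tag, length(x$rr_ms),
              sum(x$rr_ms) / 60000,
              paste(unique(x$rhythm_label), collapse = "/")))
  invisible(x)
}

#' Cohort generator configuration
#'
#' Defaults define the synthetic study conditions: a two-rhythm virtual
#' cohort in which sinus rhythm (SR) is a serially correlated, low-dispersion
#' series (lag-1 autoregression plus a respiratory sinusoid) and atrial
#' fibrillation (AF) is a weakly correlated, high-dispersion gamma series.
#' Per-patient heterogeneity (lognormal mean RR for both rhythms, lognormal
#' innovation SD for SR, truncated-normal coefficient of variation for AF)
#' makes the class distributions overlap in marginal descriptors such as mean
#' RR while successive-difference descriptors remain the cleaner separators,
#' the structure the downstream feature-ranking study assumes.
#'
#' @param n_patients_per_class virtual patients per rhythm class.
#' @param recording_duration seconds of RR data per patient.
#' @param seed master seed for the cohort.
#' @param sr_params list: `mean_rr_mu`, `mean_rr_sigma` (ms; lognormal
#'   per-patient mean), `resp_amplitude` (ms), `resp_frequency` (Hz),
#'   `ar1_coefficient` in `[0,1)`, `noise_sd` (ms, median innovation SD),
#'   `noise_sd_cv` (per-patient lognormal spread of the innovation SD),
#'   `ectopy_rate`/`ectopy_rate_sd`/`ectopy_early` (premature
#'   supraventricular beats, see Details).
#' @details
#' The SR model includes occasional premature supraventricular (ectopic)
#' beats at per-beat rate `ectopy_rate` (per-patient lognormal spread
#' `ectopy_rate_sd`, capped at 0.15): the ectopic interval is shortened to
#' `ectopy_early` of its value and the following interval absorbs the
#' difference as a compensatory pause.  Ectopy stays inside the physiologic
#' duration band, so the artifact filters do not remove it; it inflates the
#' mean-based difference statistics (RRdif, SDRR, CV, SDSuccRat) with heavy
#' tails while moving the bounded count pRR50 by at most a couple of points
#' per ectopic beat -- the mechanism that keeps the thresholded count the
#' robust separator on real Holter data.
#' @param af_params list: `mean_rr_mu`, `mean_rr_sigma` (ms),
#'   `dispersion_cv` (target coefficient of variation), `dispersion_cv_sd`
#'   and `dispersion_cv_range` (per-patient spread and truncation),
#'   `lag1_corr` in `[0, 0.2]`.
#' @param artifact_rate per-beat probability of replacing an interval by an
#'   out-of-range artifact duration.
#' @param mixed_rhythm_fraction fraction of patients per class given a single
#'   labeled AF/SR transition mid-recording.
#' @param database_tags two tags; patients alternate between them so the
#'   per-database train/test split is exercised.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_patients_per_class = 20,
                             recording_duration = 600,
                             seed = 1L,
                             sr_params = list(),
                             af_params = list(),
                             artifact_rate = 0.01,
                             mixed_rhythm_fraction = 0.10,
                             database_tags = c("SYN-A", "SYN-B")) {
  sr <- utils::modifyList(list(
    mean_rr_mu = 900, mean_rr_sigma = 160,
    resp_amplitude = 25, resp_frequency = 0.25,
    lf_amplitude = 40, lf_frequency = 0.05,
    ar1_coefficient = 0.8, noise_sd = 15, noise_sd_cv = 0.5,
    ectopy_rate = 0.03, ectopy_rate_sd = 1.2, ectopy_early = 0.75), sr_params)
  af <- utils::modifyList(list(
    mean_rr_mu = 650, mean_rr_sigma = 200,
    dispersion_cv = 0.18, dispersion_cv_sd = 0.08,
    dispersion_cv_range = c(0.04, 0.35), lag1_corr = 0.05,
    lag1_corr_range = c(0, 0.2)), af_params)
  cfg <- list(n_patients_per_class = as.integer(n_patients_per_class),
              recording_duration = recording_duration,
              seed = as.integer(seed),
              sr_params = sr, af_params = af,
              artifact_rate = artifact_rate,
              mixed_rhythm_fraction = mixed_rhythm_fraction,
              database_tags = as.character(database_tags))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  sr <- cfg$sr_params; af <- cfg$af_params
  stopifnot(
    cfg$n_patients_per_class >= 1,
    cfg$recording_duration > 0,
    sr$mean_rr_mu > 0, sr$mean_rr_sigma >= 0,
    sr$resp_amplitude >= 0, sr$resp_frequency > 0,
    sr$lf_amplitude >= 0, sr$lf_frequency > 0,
    sr$ar1_coefficient >= 0, sr$ar1_coefficient < 1,
    sr$noise_sd >= 0, sr$noise_sd_cv >= 0,
    sr$ectopy_rate >= 0, sr$ectopy_rate <= 1,
    sr$ectopy_early > 0, sr$ectopy_early < 1,
    af$mean_rr_mu > 0, af$mean_rr_sigma >= 0,
    af$dispersion_cv >= 0, af$dispersion_cv_sd >= 0,
    af$lag1_corr >= 0, af$lag1_corr <= 0.2,
    cfg$artifact_rate >= 0, cfg$artifact_rate <= 1,
    cfg$mixed_rhythm_fraction >= 0, cfg$mixed_rhythm_fraction <= 1)
  invisible(cfg)
}

# physiologic bounds of generated (non-artifact) intervals; the preprocessing
# filter bounds sit at exactly these values, so only injected artifacts can
# fall outside them
.RR_PHYS_MIN <- 240
.RR_PHYS_MAX <- 3000

#' Generate one sinus-rhythm RR series
#'
#' Mean-reverting AR(1) fluctuation around a per-patient mean (drawn
#' lognormally from `mean_rr_mu`/`mean_rr_sigma`), plus a sinusoidal
#' respiratory modulation evaluated at the cumulative beat time, plus the
#' AR(1) innovation noise.  The series is cut to the minimal prefix whose
#' cumulative duration reaches `duration_s`.
#'
#' @param params `sr_params` list as in [generator_config()].
#' @param duration_s recording duration in seconds.
#' @param seed integer seed; identical inputs give identical output.
#' @param patient_id,database_tag provenance strings.
#' @return an [rr_recording()] with all rhythm labels `"SR"`.
#' @export
generate_sr_series <- function(params, duration_s, seed,
                               patient_id = "SR01", database_tag = "SYN") {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be strictly positive")
  }
  stopifnot(params$ar1_coefficient >= 0, params$ar1_coefficient < 1,
            params$noise_sd >= 0, params$resp_amplitude >= 0,
            params$mean_rr_mu > 0)
  ect_rate <- params$ectopy_rate %||% 0
  ect_early <- params$ectopy_early %||% 0.75
  gen <- with_local_seed(seed, {
    m <- draw_lognormal_mean(params$mean_rr_mu, params$mean_rr_sigma)
    rho <- params$ar1_coefficient
    sd_innov <- params$noise_sd
    sd_stat <- if (sd_innov > 0) sd_innov / sqrt(1 - rho^2) else 0
    target_ms <- duration_s * 1000
    n_max <- ceiling(target_ms / max(.RR_PHYS_MIN, 0.5 * m)) + 8L
    out <- numeric(n_max)
    x <- if (sd_stat > 0) stats::rnorm(1, 0, sd_stat) else 0
    eps <- if (sd_innov > 0) stats::rnorm(n_max, 0, sd_innov) else numeric(n_max)
    lf_amp <- params$lf_amplitude %||% 0
    lf_freq <- params$lf_frequency %||% 0.05
    phi <- stats::runif(2, 0, 2 * pi)   # resp and low-frequency phases
    t_ms <- 0
    i <- 0L
    while (t_ms < target_ms) {
      i <- i + 1L
      if (i > length(out)) {       # artifact clamping can slow the clock
        out <- c(out, numeric(n_max))
        eps <- c(eps, if (sd_innov > 0) stats::rnorm(n_max, 0, sd_innov) else numeric(n_max))
      }
      resp <- params$resp_amplitude *
        sin(2 * pi * params$resp_frequency * t_ms / 1000 + phi[1]) +
        lf_amp * sin(2 * pi * lf_freq * t_ms / 1000 + phi[2])
      out[i] <- clamp(m + resp + x, .RR_PHYS_MIN, .RR_PHYS_MAX)
      t_ms <- t_ms + out[i]
      x <- rho * x + eps[i]
    }
    out <- out[seq_len(i)]
    beat <- rep("sinus", i)
    if (ect_rate > 0 && i > 2L) {
      # premature beat + compensatory pause: the pair sum is preserved, so
      # the total duration (and the minimal-prefix property) is unchanged
      cand <- which(stats::runif(i - 1L) < ect_rate)
      cand <- cand[c(TRUE, diff(cand) > 1L)]   # no overlapping pairs
      for (j in cand) {
        shift <- (1 - ect_early) * out[j]
        out[j] <- out[j] - shift
        out[j + 1L] <- out[j + 1L] + shift
        beat[j] <- "supraventricular"
      }
      out <- clamp(out, .RR_PHYS_MIN, .RR_PHYS_MAX)
    }
    list(rr = out, beat = beat)
  })
  rr_recording(patient_id, database_tag, gen$rr,
               beat_label = gen$beat,
               rhythm_label = rep("SR", length(gen$rr)))
}

#' Generate one atrial-fibrillation RR series
#'
#' Independent gamma-distributed intervals with a per-patient mean (lognormal
#' from `mean_rr_mu`/`mean_rr_sigma`) and target coefficient of variation
#' `dispersion_cv`; an optional small lag-1 blending (`lag1_corr`) mixes
#' consecutive draws with a variance-preserving rescale so the realized CV
#' stays on target.  Cut to the minimal prefix reaching `duration_s`.
#'
#' @inheritParams generate_sr_series
#' @param params `af_params` list as in [generator_config()].
#' @return an [rr_recording()] with all rhythm labels `"AF"`.
#' @export
generate_af_series <- function(params, duration_s, seed,
                               patient_id = "AF01", database_tag = "SYN") {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be strictly positive")
  }
  stopifnot(params$mean_rr_mu > 0, params$dispersion_cv >= 0,
            params$lag1_corr >= 0, params$lag1_corr <= 0.2)
  rr <- with_local_seed(seed, {
    m <- draw_lognormal_mean(params$mean_rr_mu, params$mean_rr_sigma)
    cv <- params$dispersion_cv
    rho <- params$lag1_corr
    target_ms <- duration_s * 1000
    n_max <- ceiling(target_ms / max(.RR_PHYS_MIN, 0.4 * m)) + 8L
    if (cv < 1e-8) {
      g <- rep(m, n_max + 1L)
    } else {
      shape <- 1 / cv^2
      g <- stats::rgamma(n_max + 1L, shape = shape, rate = shape / m)
    }
    if (rho > 0) {
      norm <- sqrt((1 - rho)^2 + rho^2)
      y <- m + ((1 - rho) * (g[-1] - m) + rho * (g[-length(g)] - m)) / norm
    } else {
      y <- g[-1]
    }
    y <- clamp(y, .RR_PHYS_MIN, .RR_PHYS_MAX)
    cum <- cumsum(y)
    n <- which(cum >= target_ms)[1]
    if (is.na(n)) {                 # extremely short draws; extend once
      extra <- generate_af_series(params, (target_ms - cum[length(cum)]) / 1000,
                                  seed + 1L, patient_id, database_tag)$rr_ms
      c(y, extra)
    } else {
      y[seq_len(n)]
    }
  })
  rr_recording(patient_id, database_tag, rr,
               beat_label = rep("sinus", length(rr)),
               rhythm_label = rep("AF", length(rr)))
}

draw_lognormal_mean <- function(mu, sigma) {
  if (sigma <= 0) return(mu)
  sdlog <- sqrt(log(1 + (sigma / mu)^2))
  meanlog <- log(mu) - sdlog^2 / 2
  stats::rlnorm(1, meanlog, sdlog)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Inject out-of-range artifact intervals into a recording
#'
#' Each interval is independently replaced, with probability
#' `artifact_rate`, by a duration outside the physiologic 240--3000 ms band
#' (too short with probability 1/2, too long otherwise) and its beat label is
#' set to `"artifact"`.  Rhythm labels are untouched: artifacts are noise on
#' top of the underlying rhythm, which is exactly what the segment-level
#' duration filter is meant to remove.
#'
#' @param recording an [rr_recording()].
#' @param artifact_rate per-beat replacement probability in `[0, 1]`.
#' @param seed integer seed.
#' @return the modified recording; the number of replacements is stored in
#'   `attr(, "n_injected")`.
#' @export
inject_artifacts <- function(recording, artifact_rate, seed) {
  stopifnot(inherits(recording, "rr_recording"),
            artifact_rate >= 0, artifact_rate <= 1)
  if (artifact_rate == 0) {
    attr(recording, "n_injected") <- 0L
    return(recording)
  }
  n <- length(recording$rr_ms)
  with_local_seed(seed, {
    hit <- stats::runif(n) < artifact_rate
    k <- sum(hit)
    if (k > 0) {
      short <- stats::runif(k) < 0.5
      dur <- ifelse(short,
                    stats::runif(k, 60, .RR_PHYS_MIN - 1),
                    stats::runif(k, .RR_PHYS_MAX + 1, 6000))
      recording$rr_ms[hit] <- dur
      recording$beat_label[hit] <- "artifact"
    }
    attr(recording, "n_injected") <- as.integer(k)
    recording
  })
}

#' Generate a full annotated cohort of virtual patients
#'
#' For each rhythm class, `n_patients_per_class` recordings are generated
#' from per-patient substream seeds derived from the master seed and the
#' patient id, so the cohort is reproducible and independent of generation
#' order.  A `mixed_rhythm_fraction` of each class's patients receive a
#' single labeled transition to the other rhythm at 60% of the recording;
#' artifacts are injected last.
#'
#' @param config a [generator_config()].
#' @return a list of [rr_recording()] objects of class `rr_cohort`, carrying
#'   the config as an attribute.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  n <- config$n_patients_per_class
  n_mixed <- floor(config$mixed_rhythm_fraction * n)
  tags <- rep_len(config$database_tags, 2L * n)
  recs <- list()
  idx <- 0L
  for (cls in c("SR", "AF")) {
    for (i in seq_len(n)) {
      idx <- idx + 1L
      pid <- sprintf("%s%03d", cls, i)
      tag <- tags[idx]
      mixed <- i > n - n_mixed
      rec <- generate_patient(config, cls, pid, tag, mixed)
      rec <- inject_artifacts(rec, config$artifact_rate,
                              derive_seed(config$seed, paste0("artifact-", pid)))
      recs[[pid]] <- rec
    }
  }
  structure(recs, class = "rr_cohort", config = config)
}

generate_patient <- function(config, cls, pid, tag, mixed) {
  dur <- config$recording_duration
  gen1 <- function(cls, dur, sub) {
    seed_i <- derive_seed(config$seed, paste0("series-", pid, "-", sub))
    if (cls == "SR") {
      p <- config$sr_params
      het <- with_local_seed(
        derive_seed(config$seed, paste0("hetero-", pid)),
        c(stats::rlnorm(1, 0, p$noise_sd_cv),
          stats::rlnorm(1, 0, p$ectopy_rate_sd)))
      p$noise_sd <- p$noise_sd * het[1]
      p$ectopy_rate <- min(0.25, p$ectopy_rate * het[2])
      generate_sr_series(p, dur, seed_i, pid, tag)
    } else {
      p <- config$af_params
      het <- with_local_seed(
        derive_seed(config$seed, paste0("hetero-", pid)),
        c(stats::rnorm(1, p$dispersion_cv, p$dispersion_cv_sd),
          stats::runif(1, p$lag1_corr_range[1], p$lag1_corr_range[2])))
      p$dispersion_cv <- clamp(het[1], p$dispersion_cv_range[1],
                               p$dispersion_cv_range[2])
      p$lag1_corr <- het[2]
      generate_af_series(p, dur, seed_i, pid, tag)
    }
  }
  if (!mixed) return(gen1(cls, dur, "a"))
  other <- if (cls == "SR") "AF" else "SR"
  a <- gen1(cls, dur * 0.6, "a")
  b <- gen1(other, dur * 0.4, "b")
  rr_recording(pid, tag,
               c(a$rr_ms, b$rr_ms),
               c(a$beat_label, b$beat_label),
               c(a$rhythm_label, b$rhythm_label))
}

#' Cohort manifest
#'
#' One row per patient: id, database tag, primary rhythm class, interval
#' count and whether the recording contains a rhythm transition.
#'
#' @param cohort an `rr_cohort`.
#' @return a data.frame.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "rr_cohort") || is.list(cohort))
  do.call(rbind, lapply(cohort, function(r) {
    data.frame(patient_id = r$patient_id,
               database_tag = r$database_tag,
               primary_rhythm = r$rhythm_label[1],
               n_intervals = length(r$rr_ms),
               mixed = length(unique(r$rhythm_label)) > 1L,
               stringsAsFactors = FALSE)
  }))
}

#' Hand-checkable fixtures for the segment filters
#'
#' Five tiny recordings, each a single nominal 60 s window, exercising one
#' branch of the segmentation rules.  Expected surviving-segment counts under
#' the default [segmentation_config()] are attached as
#' `attr(, "expected_surviving")`:
#' \describe{
#'   \item{pure_sr}{75 x 800 ms sinus beats: kept (1 segment).}
#'   \item{pure_af}{94 alternating 600/700 ms AF beats: kept (1 segment).}
#'   \item{mixed_rhythm}{40 SR then 40 AF beats in one window: excluded (0).}
#'   \item{artifact_light}{30 artifact beats of 100 ms (removed duration
#'     3000 ms < 6000 ms): kept (1 segment, 72 retained intervals).}
#'   \item{artifact_heavy}{two artifact beats of 3250 ms (removed duration
#'     6500 ms >= 6000 ms): discarded (0).}
#' }
#' @return named list of [rr_recording()] objects.
#' @export
make_filter_fixtures <- function() {
  f <- list(
    pure_sr = rr_recording(
      "FIX-SR", "FIX", rep(800, 80), rep("sinus", 80), rep("SR", 80)),
    pure_af = rr_recording(
      "FIX-AF", "FIX", rep(c(600, 700), 47), rep("sinus", 94), rep("AF", 94)),
    mixed_rhythm = rr_recording(
      "FIX-MIX", "FIX", rep(c(800, 700), c(40, 46)), rep("sinus", 86),
      rep(c("SR", "AF"), c(40, 46))),
    artifact_light = rr_recording(
      "FIX-ART1", "FIX",
      c(rep(800, 36), rep(100, 30), rep(800, 36)),
      rep(c("sinus", "artifact", "sinus"), c(36, 30, 36)),
      rep("SR", 102)),
    artifact_heavy = rr_recording(
      "FIX-ART2", "FIX",
      c(rep(800, 34), 3250, rep(800, 33), 3250, rep(800, 10)),
      rep(c("sinus", "artifact", "sinus", "artifact", "sinus"),
          c(34, 1, 33, 1, 10)),
      rep("SR", 79)))
  attr(f, "expected_surviving") <- c(pure_sr = 1L, pure_af = 1L,
                                     mixed_rhythm = 0L, artifact_light = 1L,
                                     artifact_heavy = 0L)
  f
}
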
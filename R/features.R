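#' Names of the 13 HRV descriptors
#'
#' Column order used throughout the package.  `SD2_SD1` is the ratio of the
#' Poincare dispersions SD2/SD1 (a slash is awkward in column names).
#'
#' @return character vector of length 13.
#' @export
hrv_feature_names <- function() {
  c("pRR50", "SD1", "SD2", "SD2_SD1", "SDRR", "RRdif", "CV",
    "relRRdif", "meanSuccRat", "SDSuccRat", "meanRR", "RRrange", "relRRrange")
}

#' Valid successive RR pairs of a segment
#'
#' Returns the pairs `(RR_n, RR_n+1)` whose members were adjacent in the
#' original recording; pairs spanning a removed (out-of-range) interval are
#' excluded, so difference and ratio statistics never bridge a removal gap.
#'
#' @param segment an `rr_segment` from [segment_recording()].
#' @return two-column matrix (`rr_n`, `rr_next`); zero rows when fewer than
#'   two adjacent intervals remain.
#' @export
successive_pairs <- function(segment) {
  stopifnot(inherits(segment, "rr_segment"))
  rr <- segment$rr_ms
  if (length(rr) < 2L) {
    return(matrix(numeric(), ncol = 2,
                  dimnames = list(NULL, c("rr_n", "rr_next"))))
  }
  ok <- which(segment$adjacency)
  cbind(rr_n = rr[ok], rr_next = rr[ok + 1L])
}

#' Compute the 13 HRV descriptors of one segment
#'
#' Distribution descriptors (meanRR, SDRR, RRrange and the derived CV,
#' relRRrange) are computed over all retained intervals; successive-pair
#' descriptors (pRR50, SD1, SD2, RRdif, relRRdif, meanSuccRat, SDSuccRat)
#' over the valid adjacent pairs only.  pRR50 is the percentage of pairs
#' whose absolute successive difference is at least `threshold_ms`
#' (inclusive).  SD1 and SD2 are the standard deviations of the Poincare
#' cloud rotated onto the axes across and along the identity line:
#' `SD1 = SD((RR_{n+1} - RR_n)/sqrt(2))`, `SD2 = SD((RR_{n+1} + RR_n)/sqrt(2))`.
#'
#' @param segment an `rr_segment`.
#' @param sd_type `"sample"` (denominator n-1, the default) or
#'   `"population"` (denominator n), applied to every SD in the set.
#' @param threshold_ms pRR50 threshold; 50 ms in the pipeline, exposed for
#'   sensitivity checks.
#' @return named list with the 13 features plus `valid_pair_count`;
#'   `SD2_SD1` is `NaN` when SD1 is exactly zero (flagged and excluded by
#'   [build_feature_table()]).  `NULL` when fewer than 2 valid pairs exist.
#' @export
compute_features <- function(segment, sd_type = c("sample", "population"),
                             threshold_ms = 50) {
  stopifnot(inherits(segment, "rr_segment"))
  sd_type <- match.arg(sd_type)
  sdev <- function(x) {
    if (sd_type == "sample") stats::sd(x)
    else sqrt(mean((x - mean(x))^2))
  }
  rr <- segment$rr_ms
  pairs <- successive_pairs(segment)
  if (nrow(pairs) < 2L) return(NULL)
  d <- pairs[, "rr_next"] - pairs[, "rr_n"]
  s <- pairs[, "rr_next"] + pairs[, "rr_n"]
  ratio <- pairs[, "rr_next"] / pairs[, "rr_n"]
  mean_rr <- mean(rr)
  sdrr <- sdev(rr)
  rr_range <- max(rr) - min(rr)
  rr_dif <- mean(abs(d))
  sd1 <- sdev(d / sqrt(2))
  sd2 <- sdev(s / sqrt(2))
  list(pRR50 = 100 * mean(abs(d) >= threshold_ms),
       SD1 = sd1,
       SD2 = sd2,
       SD2_SD1 = if (sd1 == 0) NaN else sd2 / sd1,
       SDRR = sdrr,
       RRdif = rr_dif,
       CV = sdrr / mean_rr,
       relRRdif = rr_dif / mean_rr,
       meanSuccRat = mean(ratio),
       SDSuccRat = sdev(ratio),
       meanRR = mean_rr,
       RRrange = rr_range,
       relRRrange = rr_range / mean_rr,
       valid_pair_count = nrow(pairs))
}

#' Build the segments-by-features table
#'
#' Applies [compute_features()] to every segment and assembles the analysis
#' table: provenance columns (`patient_id`, `database_tag`, `segment_index`),
#' the class label `rhythm_class`, the 13 features and `valid_pair_count`.
#' Segments with an undefined SD2/SD1 (zero SD1) or too few valid pairs are
#' excluded; exclusion counts are attached as `attr(, "exclusions")`.
#'
#' @param segments list of `rr_segment` objects (e.g.
#'   `segment_cohort(...)$segments`).
#' @param sd_type,threshold_ms passed to [compute_features()].
#' @return data.frame, one row per usable segment.
#' @export
build_feature_table <- function(segments, sd_type = "sample",
                                threshold_ms = 50) {
  n_undefined <- 0L
  n_short <- 0L
  rows <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    fv <- compute_features(seg, sd_type = sd_type, threshold_ms = threshold_ms)
    if (is.null(fv)) { n_short <- n_short + 1L; next }
    if (is.nan(fv$SD2_SD1)) { n_undefined <- n_undefined + 1L; next }
    rows[[i]] <- c(list(patient_id = seg$patient_id,
                        database_tag = seg$database_tag,
                        segment_index = seg$segment_index,
                        rhythm_class = seg$rhythm_class), fv)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tab <- if (length(rows)) {
    do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    empty <- c(list(patient_id = character(), database_tag = character(),
                    segment_index = integer(), rhythm_class = character()),
               stats::setNames(rep(list(numeric()), 14),
                               c(hrv_feature_names(), "valid_pair_count")))
    as.data.frame(empty, stringsAsFactors = FALSE)
  }
  if (n_undefined > 0L) {
    message(sprintf("build_feature_table: excluded %d segment(s) with undefined SD2/SD1",
                    n_undefined))
  }
  attr(tab, "exclusions") <- c(undefined_ratio = n_undefined,
                               too_few_pairs = n_short)
  tab
}
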
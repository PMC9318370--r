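#' Segmentation and artifact-filter configuration
#'
#' The rules that turn an annotated recording into analyzable 60 s windows:
#' windows tile the recording from its start (optionally offset); a window
#' survives only if its rhythm labels are purely AF or purely SR, the total
#' duration of removed out-of-range intervals stays below
#' `max_removed_fraction` of the nominal window length (removal at or above
#' the threshold discards the window), and enough intervals remain.
#'
#' @param window_s window length in seconds.
#' @param rr_min_ms,rr_max_ms retained-duration band (ms); intervals strictly
#'   below `rr_min_ms` or strictly above `rr_max_ms` are removed.
#' @param max_removed_fraction discard threshold on removed duration as a
#'   fraction of the nominal window duration (inclusive at the bound).
#' @param min_retained_intervals minimum retained intervals per window.
#' @param offset_s window anchoring offset from the recording start.
#' @return a list of class `segmentation_config`.
#' @export
segmentation_config <- function(window_s = 60, rr_min_ms = 240,
                                rr_max_ms = 3000, max_removed_fraction = 0.10,
                                min_retained_intervals = 18L, offset_s = 0) {
  stopifnot(window_s > 0, rr_min_ms > 0, rr_min_ms < rr_max_ms,
            max_removed_fraction > 0, max_removed_fraction <= 1,
            min_retained_intervals >= 2, offset_s >= 0)
  structure(list(window_s = window_s, rr_min_ms = rr_min_ms,
                 rr_max_ms = rr_max_ms,
                 max_removed_fraction = max_removed_fraction,
                 min_retained_intervals = as.integer(min_retained_intervals),
                 offset_s = offset_s),
            class = "segmentation_config")
}

#' Cut a recording into pure-rhythm 60 s segments
#'
#' Every interval is assigned to exactly one window, the one containing its
#' starting beat; only windows whose nominal span is fully covered by the
#' recording are considered.  Filtering per window: (a) discard if any
#' interval is labeled a rhythm other than AF/SR (`other_rhythm`) or if both
#' AF and SR occur (`mixed_rhythm`); (b) remove intervals outside the
#' duration band and discard the window when the removed duration reaches
#' `max_removed_fraction * window` (`excess_removed`); (c) discard when
#' fewer than `min_retained_intervals` intervals remain (`too_few_retained`).
#' Retained intervals keep adjacency flags marking consecutive pairs that
#' were adjacent in the original series, so that successive-difference
#' statistics never bridge a removal gap.
#'
#' @param recording an [rr_recording()].
#' @param config a [segmentation_config()].
#' @return list with `segments` (list of `rr_segment`) and `qc`, a
#'   data.frame with one row per considered window: window index, rhythm
#'   (`NA` for impure windows) and outcome (`kept` or a discard reason).
#' @export
segment_recording <- function(recording, config = segmentation_config()) {
  stopifnot(inherits(recording, "rr_recording"),
            inherits(config, "segmentation_config"))
  window_ms <- config$window_s * 1000
  offset_ms <- config$offset_s * 1000
  rr <- recording$rr_ms
  start_ms <- cumsum(c(0, rr[-length(rr)]))
  total_ms <- sum(rr)
  win <- floor((start_ms - offset_ms) / window_ms)
  n_complete <- floor((total_ms - offset_ms) / window_ms)
  qc <- list()
  segments <- list()
  for (w in seq_len(n_complete) - 1L) {
    sel <- which(win == w & start_ms >= offset_ms)
    if (length(sel) == 0L) next
    rhythms <- unique(recording$rhythm_label[sel])
    if (any(!rhythms %in% c("AF", "SR"))) {
      qc[[length(qc) + 1L]] <- c(w, NA, "other_rhythm"); next
    }
    if (length(rhythms) > 1L) {
      qc[[length(qc) + 1L]] <- c(w, NA, "mixed_rhythm"); next
    }
    x <- rr[sel]
    keep <- x >= config$rr_min_ms & x <= config$rr_max_ms
    removed_ms <- sum(x[!keep])
    if (removed_ms >= config$max_removed_fraction * window_ms) {
      qc[[length(qc) + 1L]] <- c(w, rhythms, "excess_removed"); next
    }
    if (sum(keep) < config$min_retained_intervals) {
      qc[[length(qc) + 1L]] <- c(w, rhythms, "too_few_retained"); next
    }
    kept_idx <- which(keep)
    adjacency <- diff(kept_idx) == 1L
    segments[[length(segments) + 1L]] <- structure(
      list(patient_id = recording$patient_id,
           database_tag = recording$database_tag,
           segment_index = w,
           rhythm_class = rhythms,
           rr_ms = x[keep],
           adjacency = adjacency,
           removed_ms_total = removed_ms,
           n_removed = sum(!keep)),
      class = "rr_segment")
    qc[[length(qc) + 1L]] <- c(w, rhythms, "kept")
  }
  qc_df <- if (length(qc)) {
    data.frame(window = as.integer(vapply(qc, `[`, "", 1L)),
               rhythm = vapply(qc, `[`, "", 2L),
               outcome = vapply(qc, `[`, "", 3L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(window = integer(), rhythm = character(),
               outcome = character(), stringsAsFactors = FALSE)
  }
  list(segments = segments, qc = qc_df)
}

#' Segment every recording in a cohort
#'
#' @param cohort an `rr_cohort` (or plain list of recordings).
#' @param config a [segmentation_config()].
#' @return list with `segments` (flat list across patients) and `qc` (row
#'   per considered window, with patient id and database tag).
#' @export
segment_cohort <- function(cohort, config = segmentation_config()) {
  segs <- list()
  qcs <- list()
  for (rec in cohort) {
    out <- segment_recording(rec, config)
    segs <- c(segs, out$segments)
    if (nrow(out$qc)) {
      out$qc$patient_id <- rec$patient_id
      out$qc$database_tag <- rec$database_tag
      qcs[[length(qcs) + 1L]] <- out$qc
    }
  }
  qc <- if (length(qcs)) do.call(rbind, qcs) else
    data.frame(window = integer(), rhythm = character(),
               outcome = character(), patient_id = character(),
               database_tag = character(), stringsAsFactors = FALSE)
  list(segments = segs, qc = qc)
}

#' Filtering bookkeeping per class (and optionally per data split)
#'
#' Summarizes the segmentation QC the way artifact-filter bookkeeping is
#' usually tabulated: for each rhythm class (and data split, when a split
#' assignment is supplied), the number of pure-rhythm windows before the
#' artifact filters (`total`) and the number surviving them (`filtered`).
#' Windows rejected for impure rhythm are not part of `total`, which counts
#' candidate AF/SR segments only.
#'
#' @param qc the `qc` data.frame from [segment_cohort()].
#' @param split optional [split_by_patient()] result; adds a `set` column
#'   (`training`/`test`).
#' @return a data.frame with columns `set` (optional), `class`, `total`,
#'   `filtered`.
#' @export
summarize_filtering <- function(qc, split = NULL) {
  pure <- qc[qc$outcome %in% c("kept", "excess_removed", "too_few_retained") &
               !is.na(qc$rhythm), , drop = FALSE]
  if (nrow(pure) == 0L) {
    cells <- expand.grid(set = if (is.null(split)) "all" else
                           c("training", "test"),
                         class = c("AF", "SR"), stringsAsFactors = FALSE)
    cells$total <- 0L; cells$filtered <- 0L
    return(cells)
  }
  pure$set <- "all"
  if (!is.null(split)) {
    pure$set <- ifelse(pure$patient_id %in% split$train_patients$patient_id,
                       "training", "test")
  }
  cells <- expand.grid(set = unique(pure$set), class = c("AF", "SR"),
                       stringsAsFactors = FALSE)
  cells$total <- mapply(function(s, cl)
    sum(pure$set == s & pure$rhythm == cl), cells$set, cells$class)
  cells$filtered <- mapply(function(s, cl)
    sum(pure$set == s & pure$rhythm == cl & pure$outcome == "kept"),
    cells$set, cells$class)
  rownames(cells) <- NULL
  cells
}
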
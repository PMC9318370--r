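#' Write a cohort as delimited text
#'
#' One row per interval (`patient_id`, `database_tag`, `rr_ms`,
#' `beat_label`, `rhythm_label`) in `recordings.tsv`, plus the generator
#' configuration in `manifest.yaml` when the cohort carries one.
#'
#' @param cohort an `rr_cohort` or list of [rr_recording()]s.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- do.call(rbind, lapply(cohort, function(r) {
    data.frame(patient_id = r$patient_id, database_tag = r$database_tag,
               rr_ms = r$rr_ms, beat_label = r$beat_label,
               rhythm_label = r$rhythm_label, stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, file.path(dir, "recordings.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) {
    yaml::write_yaml(unclass(cfg), file.path(dir, "manifest.yaml"))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `recordings.tsv`.
#' @return an `rr_cohort` (list of [rr_recording()]s).
#' @export
read_cohort <- function(dir) {
  path <- file.path(dir, "recordings.tsv")
  if (!file.exists(path)) stop("no recordings.tsv in ", dir)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  recs <- lapply(split(tab, factor(tab$patient_id, unique(tab$patient_id))),
                 function(d) rr_recording(d$patient_id[1], d$database_tag[1],
                                          d$rr_ms, d$beat_label,
                                          d$rhythm_label))
  structure(recs, class = "rr_cohort")
}

.BEAT_TO_CODE <- c(sinus = "N", supraventricular = "S", ventricular = "V",
                   artifact = "|")
.RHYTHM_TO_CODE <- c(AF = "(AFIB", SR = "(N", other = "(OTHER")

#' Write a recording as annotation-style text
#'
#' Companion format to [read_rr_annotations()]: whitespace-delimited lines
#' `time_s code aux`, with one line per QRS mark (beat codes `N`, `S`, `V`,
#' `|`) and rhythm-change lines (code `+`, rhythm string such as `(AFIB` or
#' `(N` in `aux`) emitted whenever the rhythm label changes.
#'
#' @param recording an [rr_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rr_annotations <- function(recording, path) {
  rr <- recording$rr_ms
  t_qrs <- cumsum(c(0, rr)) / 1000        # n + 1 marks for n intervals
  lines <- character()
  prev_rhythm <- ""
  for (i in seq_along(rr)) {
    if (recording$rhythm_label[i] != prev_rhythm) {
      prev_rhythm <- recording$rhythm_label[i]
      code <- .RHYTHM_TO_CODE[[prev_rhythm]] %||% "(OTHER"
      lines <- c(lines, sprintf("%.6f\t+\t%s", t_qrs[i], code))
    }
    lines <- c(lines, sprintf("%.6f\t%s\t", t_qrs[i],
                              .BEAT_TO_CODE[[recording$beat_label[i]]] %||% "N"))
  }
  lines <- c(lines, sprintf("%.6f\tN\t", t_qrs[length(t_qrs)]))
  writeLines(lines, path)
  invisible(path)
}

#' Read an annotation-style text file into a recording
#'
#' Parses whitespace-delimited annotation lines (`time_s code aux`), builds
#' RR intervals from consecutive QRS-mark times, labels each interval's beat
#' from its opening mark and carries the rhythm label forward from the most
#' recent rhythm-change line (`+`).  Rhythm strings `(AFIB` and `(N` map to
#' AF and SR; anything else maps to `"other"` with a warning.
#'
#' @param path annotation text file.
#' @param patient_id,database_tag provenance for the resulting recording
#'   (default: the file name and `"EXT"`).
#' @return an [rr_recording()].
#' @export
read_rr_annotations <- function(path, patient_id = NULL,
                                database_tag = "EXT") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- tryCatch(readLines(path), error = function(e)
    stop("cannot read annotation file ", path, ": ", conditionMessage(e)))
  raw <- raw[nzchar(trimws(raw))]
  if (!length(raw)) stop("annotation file is empty: ", path)
  parts <- strsplit(trimws(raw), "\\s+")
  times <- vapply(parts, function(p) suppressWarnings(as.numeric(p[1])),
                  numeric(1))
  codes <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "",
                  character(1))
  aux <- vapply(parts, function(p) if (length(p) >= 3) p[3] else "",
                character(1))
  if (anyNA(times)) stop("corrupt annotation file (bad time field): ", path)
  code_to_beat <- c(N = "sinus", S = "supraventricular", A = "supraventricular",
                    V = "ventricular", "|" = "artifact", "~" = "artifact",
                    Q = "artifact")
  is_rhythm <- codes == "+"
  is_qrs <- codes %in% names(code_to_beat)
  rhythm_at <- function(t) {
    prior <- which(is_rhythm & times <= t + 1e-9)
    if (!length(prior)) return("other")
    code <- aux[max(prior)]
    if (code == "(AFIB") "AF"
    else if (code == "(N") "SR"
    else {
      warning("unknown rhythm annotation '", code, "' mapped to 'other'")
      "other"
    }
  }
  qrs_t <- times[is_qrs]
  qrs_beat <- code_to_beat[codes[is_qrs]]
  if (length(qrs_t) < 2L) stop("fewer than two QRS marks in ", path)
  rr <- diff(qrs_t) * 1000
  opening <- seq_len(length(qrs_t) - 1L)
  rr_recording(patient_id %||% basename(path), database_tag,
               rr_ms = rr,
               beat_label = unname(qrs_beat[opening]),
               rhythm_label = vapply(qrs_t[opening], rhythm_at, character(1)))
}

#' Write/read delimited-text tables
#'
#' Thin wrappers fixing the package's table format: tab-separated, header,
#' no quoting or row names.
#'
#' @param x data.frame.
#' @param path file path.
#' @return `write_tsv` returns `path` invisibly; `read_tsv` a data.frame.
#' @export
write_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Serialize a ranking result as structured text
#'
#' @param ranking a `ranking_result`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(method = ranking$method,
                        criterion = ranking$criterion %||% NA,
                        binning = ranking$binning,
                        pool = ranking$pool,
                        order = ranking$order,
                        scores = as.list(ranking$scores)), path)
  invisible(path)
}

#' Write/read segments as delimited text
#'
#' One row per segment; the retained RR list and adjacency flags are packed
#' into comma-separated strings so the format stays a flat table.
#'
#' @param segments list of `rr_segment` objects.
#' @param path TSV file.
#' @return `write_segments` returns `path` invisibly; `read_segments` the
#'   list of segments.
#' @export
write_segments <- function(segments, path) {
  tab <- do.call(rbind, lapply(segments, function(s) {
    data.frame(patient_id = s$patient_id, database_tag = s$database_tag,
               segment_index = s$segment_index, rhythm_class = s$rhythm_class,
               removed_ms_total = s$removed_ms_total, n_removed = s$n_removed,
               rr_ms = paste(format(s$rr_ms, digits = 15, trim = TRUE),
                             collapse = ","),
               adjacency = paste(as.integer(s$adjacency), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  write_tsv(tab, path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  tab <- read_tsv(path)
  lapply(seq_len(nrow(tab)), function(i) {
    structure(
      list(patient_id = tab$patient_id[i], database_tag = tab$database_tag[i],
           segment_index = tab$segment_index[i],
           rhythm_class = tab$rhythm_class[i],
           rr_ms = as.numeric(strsplit(tab$rr_ms[i], ",")[[1]]),
           adjacency = as.logical(as.integer(
             strsplit(tab$adjacency[i], ",")[[1]])),
           removed_ms_total = tab$removed_ms_total[i],
           n_removed = tab$n_removed[i]),
      class = "rr_segment")
  })
}
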
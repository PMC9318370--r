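#' End-to-end run configuration
#'
#' A single structured configuration drives the whole pipeline.  Stage seeds
#' are derived deterministically from the master seed and the stage name
#' ([derive_seed()]), so any stage can be rerun independently and two runs
#' with the same configuration are identical.
#'
#' @param generator a [generator_config()] (its own seed is overridden by
#'   the derived `simulate` stage seed).
#' @param segmentation a [segmentation_config()].
#' @param ranking list: `method` (`"MRMR"` or `"AUC"`), `bins`, `criterion`,
#'   `exclude` (features dropped from the reduced pool; default `"pRR50"`).
#' @param harness list: `families`, `grids`, `k_max`, `modes`, `k_folds`,
#'   `train_fraction`, `dor_correction`.
#' @param seed master seed.
#' @param out_dir optional directory; when given, every artifact is written
#'   there as delimited/structured text.
#' @return list of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       segmentation = segmentation_config(),
                       ranking = list(),
                       harness = list(),
                       seed = 1L,
                       out_dir = NULL) {
  ranking <- utils::modifyList(
    list(method = "MRMR", bins = 16, criterion = "MIQ", exclude = "pRR50"),
    ranking)
  harness <- utils::modifyList(
    list(families = c("DT", "KNN", "SVM_linear", "SVM_RBF", "ADA", "RF", "ANN"),
         grids = compact_grids(), k_max = 6, modes = c("cv5", "blindfold"),
         k_folds = 5, train_fraction = 2 / 3, dor_correction = "haldane"),
    harness)
  structure(list(generator = generator, segmentation = segmentation,
                 ranking = ranking, harness = harness,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline: simulate, segment, extract, rank, evaluate
#'
#' Stages: (1) generate the synthetic cohort; (2) cut recordings into pure
#' 60 s segments with artifact filtering; (3) compute the 13 HRV features;
#' (4) split patients into training and test sets and rank features on the
#' training rows only, once over the full pool and once with the excluded
#' features removed; (5) tune and evaluate every classifier family over the
#' 1..k_max prefix feature sets in both validation modes.  Identical
#' configuration and master seed reproduce every artifact identically.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result`: `cohort`, `segments`, `qc`,
#'   `feature_table`, `split`, `rankings` (per pool), `eval_report`,
#'   `filtering`, `manifest` (config hash and stage seeds).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- list(simulate = derive_seed(config$seed, "simulate"),
                split = derive_seed(config$seed, "split"),
                evaluate = derive_seed(config$seed, "evaluate"))
  gen <- config$generator
  gen$seed <- seeds$simulate
  message("stage simulate: ", gen$n_patients_per_class, " patients/class")
  cohort <- generate_cohort(gen)

  message("stage segment")
  seg <- segment_cohort(cohort, config$segmentation)
  if (!length(seg$segments)) stop("stage segment produced no segments")

  message("stage features")
  table <- build_feature_table(seg$segments)
  if (!nrow(table)) stop("stage features produced an empty table")

  message("stage rank (training split only)")
  split <- split_by_patient(cohort_manifest(cohort),
                            config$harness$train_fraction, seeds$split)
  parts <- apply_split(table, split)
  pools <- list(full = hrv_feature_names())
  excl <- config$ranking$exclude
  if (length(excl) && any(nzchar(excl))) {
    pools[[paste0("no_", paste(excl, collapse = "_"))]] <-
      setdiff(hrv_feature_names(), excl)
  }
  rank_one <- function(pool) {
    if (config$ranking$method == "AUC") auc_rank(parts$train, pool)
    else mrmr_rank(parts$train, pool, bins = config$ranking$bins,
                   criterion = config$ranking$criterion)
  }
  rankings <- lapply(pools, rank_one)

  message("stage evaluate: ", length(config$harness$families), " families x k=1..",
          config$harness$k_max)
  specs <- lapply(config$harness$families, function(f)
    classifier_spec(f, grid = config$harness$grids[[f]]))
  report <- run_experiment_matrix(parts$train, parts$test, rankings,
                                  specs = specs,
                                  k_max = config$harness$k_max,
                                  modes = config$harness$modes,
                                  k_folds = config$harness$k_folds,
                                  seed = seeds$evaluate,
                                  correction = config$harness$dor_correction)
  filtering <- summarize_filtering(seg$qc, split)
  manifest <- list(config_hash = config_hash(config), master_seed = config$seed,
                   stage_seeds = seeds,
                   n_segments = length(seg$segments),
                   n_feature_rows = nrow(table))
  result <- structure(list(cohort = cohort, segments = seg$segments,
                           qc = seg$qc, feature_table = table, split = split,
                           rankings = rankings, eval_report = report,
                           filtering = filtering, manifest = manifest,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(result$feature_table, file.path(dir, "feature_table.tsv"))
  write_tsv(result$eval_report, file.path(dir, "eval_report.tsv"))
  write_tsv(result$filtering, file.path(dir, "filtering_summary.tsv"))
  write_tsv(result$qc, file.path(dir, "segment_qc.tsv"))
  for (pool in names(result$rankings)) {
    write_ranking(result$rankings[[pool]],
                  file.path(dir, sprintf("ranking_%s.yaml", pool)))
  }
  yaml::write_yaml(result$manifest, file.path(dir, "run_manifest.yaml"))
  invisible(dir)
}

#' Summary tables of a completed run
#'
#' Produces the study's reporting surfaces: per-feature oriented AUC on the
#' training split, the MRMR score tables per pool, metric-versus-k tables
#' per family and validation mode, the filtering bookkeeping, and the
#' mean (SD) cross-validated accuracy table (families by feature-set size).
#'
#' @param result a `pipeline_result`.
#' @return named list of data.frames: `auc`, `mrmr` (per pool),
#'   `metrics_by_k`, `filtering`, `cv_accuracy`.
#' @export
render_report <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  parts <- apply_split(result$feature_table, result$split)
  aucs <- auc_rank(parts$train)
  auc_tab <- data.frame(feature = aucs$order, auc = unname(aucs$scores))
  mrmr_tabs <- lapply(result$rankings, function(r)
    data.frame(rank = seq_along(r$order), feature = r$order,
               score = unname(r$scores)))
  rep <- result$eval_report
  metrics_by_k <- rep[, c("pool", "family", "mode", "n_features", "accuracy",
                          "sensitivity", "specificity", "ppv", "dor")]
  cv <- rep[rep$mode == "cv5" & rep$pool == "full", ]
  cv_tab <- stats::reshape(
    cv[, c("family", "n_features", "cv_acc_mean", "cv_acc_sd")],
    direction = "wide", idvar = "family", timevar = "n_features")
  names(cv_tab) <- sub("cv_acc_", "", names(cv_tab))
  rownames(cv_tab) <- NULL
  list(auc = auc_tab, mrmr = mrmr_tabs, metrics_by_k = metrics_by_k,
       filtering = result$filtering, cv_accuracy = cv_tab)
}
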
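#' Diagnostic odds ratio
#'
#' `DOR = (TP * TN) / (FP * FN)`, the single-number summary of a diagnostic
#' confusion table (1 = no information).  When any cell is zero the ratio is
#' undefined; under the `"haldane"` policy 0.5 is added to every cell, under
#' `"strict"` the value is reported as `NA`.
#'
#' @param TP,FP,TN,FN non-negative confusion counts (AF positive).
#' @param correction `"haldane"` (default) or `"strict"`.
#' @return unitless odds ratio (possibly `NA` under `"strict"`).
#' @export
diagnostic_odds_ratio <- function(TP, FP, TN, FN,
                                  correction = c("haldane", "strict")) {
  correction <- match.arg(correction)
  cells <- c(TP, FP, TN, FN)
  if (any(cells < 0)) stop("confusion counts must be non-negative")
  if (any(cells == 0)) {
    if (correction == "strict") return(NA_real_)
    cells <- cells + 0.5
  }
  (cells[1] * cells[3]) / (cells[2] * cells[4])
}

#' Diagnostic metrics from confusion counts
#'
#' @inheritParams diagnostic_odds_ratio
#' @return named list: the four counts, `accuracy`, `sensitivity`,
#'   `specificity`, `ppv` (percentages) and `dor`.
#' @export
confusion_metrics <- function(TP, FP, TN, FN, correction = "haldane") {
  total <- TP + FP + TN + FN
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       accuracy = 100 * (TP + TN) / total,
       sensitivity = 100 * TP / (TP + FN),
       specificity = 100 * TN / (TN + FP),
       ppv = 100 * TP / (TP + FP),
       dor = diagnostic_odds_ratio(TP, FP, TN, FN, correction))
}

confusion_counts <- function(truth, pred) {
  list(TP = sum(truth == "AF" & pred == "AF"),
       FP = sum(truth == "SR" & pred == "AF"),
       TN = sum(truth == "SR" & pred == "SR"),
       FN = sum(truth == "AF" & pred == "SR"))
}

#' Patient-disjoint train/test split
#'
#' Per database, `round(train_fraction * n)` patients are sampled without
#' replacement into the training set and the rest form the test set, so no
#' patient contributes segments to both sides.
#'
#' @param manifest data.frame with `patient_id` and `database_tag` columns
#'   (one row per patient), e.g. from [cohort_manifest()].
#' @param train_fraction fraction of each database's patients used for
#'   training (2/3 by default).
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return list of class `split_assignment` with `train_patients` and
#'   `test_patients` data.frames and the seed.
#' @export
split_by_patient <- function(manifest, train_fraction = 2 / 3, seed = 1L) {
  stopifnot(all(c("patient_id", "database_tag") %in% names(manifest)),
            !anyDuplicated(manifest$patient_id),
            train_fraction > 0, train_fraction < 1)
  train_idx <- integer()
  for (db in unique(manifest$database_tag)) {
    idx <- which(manifest$database_tag == db)
    if (length(idx) < 3L) {
      stop(sprintf("database %s has fewer than 3 patients", db))
    }
    n_train <- round(train_fraction * length(idx))
    picked <- with_local_seed(derive_seed(seed, paste0("split-", db)),
                              sample_exact(idx, n_train))
    train_idx <- c(train_idx, picked)
  }
  structure(list(seed = as.integer(seed),
                 train_patients = manifest[sort(train_idx), , drop = FALSE],
                 test_patients = manifest[-sort(train_idx), , drop = FALSE]),
            class = "split_assignment")
}

#' Split a feature table into training and test rows
#'
#' @param table feature table.
#' @param split a `split_assignment`.
#' @return list with `train` and `test` data.frames.
#' @export
apply_split <- function(table, split) {
  stopifnot(inherits(split, "split_assignment"))
  in_train <- table$patient_id %in% split$train_patients$patient_id
  in_test <- table$patient_id %in% split$test_patients$patient_id
  list(train = table[in_train, , drop = FALSE],
       test = table[in_test, , drop = FALSE])
}

# stratified fold labels: within each class, segments are shuffled and dealt
# round-robin into k folds
make_stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_local_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

grid_points <- function(grid) {
  g <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

#' Tune a classifier by stratified k-fold cross-validation
#'
#' Every grid point is evaluated by k-fold cross-validation over the
#' training segments (folds stratified by class); feature scaling, when the
#' family uses it, is fit inside each fold on the k-1 training folds only.
#' The point with the highest mean fold accuracy wins, ties going to the
#' earlier point in grid order.
#'
#' @param spec a [classifier_spec()].
#' @param train training feature table rows.
#' @param features feature-column names to use.
#' @param k_folds folds (5 by default).
#' @param seed seed for fold assignment and stochastic fits.
#' @param correction DOR zero-cell policy for the pooled confusion.
#' @return list: `params` (chosen), `cv_mean`, `cv_sd`, `fold_accuracy` (at
#'   the chosen point), pooled out-of-fold `confusion` and `metrics` at the
#'   chosen point, and the full `grid_results` data.frame.
#' @export
tune_classifier <- function(spec, train, features, k_folds = 5, seed = 1L,
                            correction = "haldane") {
  stopifnot(all(features %in% names(train)), nrow(train) >= k_folds)
  y <- train$rhythm_class
  if (length(unique(y)) < 2L) stop("training rows must contain both classes")
  fold <- make_stratified_folds(y, k_folds, derive_seed(seed, "folds"))
  if (any(tapply(y, fold, function(v) length(unique(v))) < 2L)) {
    stop("degenerate fold with a single class; need more segments per class")
  }
  X <- train[, features, drop = FALSE]
  points <- grid_points(spec$grid)
  acc <- matrix(NA_real_, length(points), k_folds)
  oof <- vector("list", length(points))
  for (p in seq_along(points)) {
    pred_all <- character(length(y))
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      fit <- fit_classifier(spec, X[tr, , drop = FALSE], y[tr], points[[p]],
                            seed = derive_seed(seed, paste0("fit-", p, "-", f)))
      pred <- predict(fit, X[!tr, , drop = FALSE])
      acc[p, f] <- mean(pred == y[!tr])
      pred_all[!tr] <- pred
    }
    oof[[p]] <- pred_all
  }
  mean_acc <- rowMeans(acc)
  best <- which.max(mean_acc)          # first point wins ties
  cc <- confusion_counts(y, oof[[best]])
  grid_df <- do.call(rbind, lapply(seq_along(points), function(p) {
    d <- as.data.frame(points[[p]], stringsAsFactors = FALSE)
    d$cv_mean <- mean_acc[p]
    d$cv_sd <- stats::sd(acc[p, ])
    d
  }))
  list(params = points[[best]],
       cv_mean = 100 * mean_acc[best],
       cv_sd = 100 * stats::sd(acc[best, ]),
       fold_accuracy = 100 * acc[best, ],
       confusion = cc,
       metrics = do.call(confusion_metrics, c(cc, list(correction = correction))),
       grid_results = grid_df)
}

#' Blindfold validation on held-out patients
#'
#' Fits the tuned classifier on the full training split and evaluates every
#' test segment.  Aborts if any patient appears on both sides: blindfold
#' validation exists precisely to rule out that leakage.
#'
#' @param spec a [classifier_spec()].
#' @param params chosen metaparameters.
#' @param train,test training and test feature-table rows.
#' @param features feature-column names.
#' @param seed seed for stochastic fits.
#' @param correction DOR zero-cell policy.
#' @return [confusion_metrics()] list for the test predictions.
#' @export
evaluate_blindfold <- function(spec, params, train, test, features,
                               seed = 1L, correction = "haldane") {
  overlap <- intersect(unique(train$patient_id), unique(test$patient_id))
  if (length(overlap)) {
    stop("patient leakage between training and test sets: ",
         paste(overlap, collapse = ", "))
  }
  fit <- fit_classifier(spec, train[, features, drop = FALSE],
                        train$rhythm_class, params,
                        seed = derive_seed(seed, "blindfold-fit"))
  pred <- predict(fit, test[, features, drop = FALSE])
  cc <- confusion_counts(test$rhythm_class, pred)
  do.call(confusion_metrics, c(cc, list(correction = correction)))
}

#' Run the full classifier-by-feature-set evaluation matrix
#'
#' The cross product of classifier families, prefix feature-set sizes
#' k = 1..k_max, validation modes (5-fold cross-validation on the training
#' split, blindfold validation on held-out patients) and feature pools (one
#' ranking per pool, e.g. the full pool and the pool without pRR50).  Each
#' (pool, family, k) cell is tuned independently; the blindfold row reuses
#' the metaparameters chosen by cross-validation, mirroring a
#' tune-then-validate protocol.
#'
#' @param train,test feature-table rows (patient-disjoint).
#' @param rankings named list of `ranking_result`s, one per pool (names
#'   become the `pool` column; rankings must come from the training rows).
#' @param specs list of [classifier_spec()]s (default: all seven families
#'   with [compact_grids()]).
#' @param k_max largest feature-set size.
#' @param modes subset of `c("cv5", "blindfold")`.
#' @param k_folds cross-validation folds.
#' @param seed master seed for folds and stochastic fits.
#' @param correction DOR zero-cell policy.
#' @return `eval_report` data.frame: one row per
#'   (pool, family, k, mode) with confusion counts, accuracy, sensitivity,
#'   specificity, PPV, DOR (all AF-positive), the chosen metaparameters
#'   (JSON) and, for cv5 rows, the per-fold accuracy mean and SD.
#' @export
run_experiment_matrix <- function(train, test, rankings,
                                  specs = NULL, k_max = 6,
                                  modes = c("cv5", "blindfold"),
                                  k_folds = 5, seed = 1L,
                                  correction = "haldane") {
  stopifnot(is.list(rankings), length(rankings) >= 1L,
            !is.null(names(rankings)), all(modes %in% c("cv5", "blindfold")))
  if (is.null(specs)) {
    fams <- c("DT", "KNN", "SVM_linear", "SVM_RBF", "ADA", "RF", "ANN")
    grids <- compact_grids()
    specs <- lapply(fams, function(f) classifier_spec(f, grid = grids[[f]]))
  }
  rows <- list()
  for (pool_name in names(rankings)) {
    ranking <- rankings[[pool_name]]
    stopifnot(inherits(ranking, "ranking_result"))
    prefixes <- ranked_prefixes(ranking, min(k_max, length(ranking$pool)))
    for (spec in specs) {
      for (k in seq_along(prefixes)) {
        feats <- prefixes[[k]]
        cell_seed <- derive_seed(seed, paste(pool_name, spec$family, k))
        tuned <- tune_classifier(spec, train, feats, k_folds = k_folds,
                                 seed = cell_seed, correction = correction)
        if ("cv5" %in% modes) {
          rows[[length(rows) + 1L]] <- eval_row(
            pool_name, spec$family, k, "cv5", tuned$metrics, tuned$params,
            tuned$cv_mean, tuned$cv_sd)
        }
        if ("blindfold" %in% modes) {
          bm <- evaluate_blindfold(spec, tuned$params, train, test, feats,
                                   seed = cell_seed, correction = correction)
          rows[[length(rows) + 1L]] <- eval_row(
            pool_name, spec$family, k, "blindfold", bm, tuned$params,
            tuned$cv_mean, tuned$cv_sd)
        }
      }
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  class(report) <- c("eval_report", "data.frame")
  report
}

eval_row <- function(pool, family, k, mode, m, params, cv_mean, cv_sd) {
  data.frame(pool = pool, family = family, n_features = k, mode = mode,
             TP = m$TP, FP = m$FP, TN = m$TN, FN = m$FN,
             accuracy = m$accuracy, sensitivity = m$sensitivity,
             specificity = m$specificity, ppv = m$ppv, dor = m$dor,
             cv_acc_mean = cv_mean, cv_acc_sd = cv_sd,
             params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE)),
             stringsAsFactors = FALSE)
}
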
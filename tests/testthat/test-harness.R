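tiny_manifest <- function(n_a = 6, n_b = 3) {
  data.frame(patient_id = c(sprintf("A%02d", seq_len(n_a)),
                            sprintf("B%02d", seq_len(n_b))),
             database_tag = rep(c("DBA", "DBB"), c(n_a, n_b)),
             stringsAsFactors = FALSE)
}

# linearly separable two-class table with patient structure
separable_table <- function(n_per_class = 30, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("AF", "SR"), each = n_per_class)
    data.frame(patient_id = rep(sprintf("P%02d", 1:6), length.out = 2 * n_per_class),
               rhythm_class = y,
               x1 = ifelse(y == "AF", 5, -5) + stats::rnorm(2 * n_per_class),
               x2 = stats::rnorm(2 * n_per_class),
               stringsAsFactors = FALSE)
  })
}

test_that("patient split is per-database, disjoint, rounded and deterministic", {
  man <- tiny_manifest()
  sp <- split_by_patient(man, 2 / 3, seed = 4)
  expect_length(intersect(sp$train_patients$patient_id,
                          sp$test_patients$patient_id), 0)
  expect_equal(sum(sp$train_patients$database_tag == "DBA"), 4)  # round(2/3*6)
  expect_equal(sum(sp$train_patients$database_tag == "DBB"), 2)  # round(2/3*3)
  expect_identical(sp, split_by_patient(man, 2 / 3, seed = 4))
  expect_false(identical(sp$train_patients,
                         split_by_patient(man, 2 / 3, seed = 5)$train_patients))
  expect_error(split_by_patient(tiny_manifest(6, 2), 2 / 3, 1), "fewer than 3")
})

test_that("diagnostic odds ratio matches direct arithmetic and correction policies", {
  expect_equal(diagnostic_odds_ratio(25, 25, 25, 25), 1)
  expect_equal(diagnostic_odds_ratio(90, 20, 80, 10), 36)
  h <- diagnostic_odds_ratio(90, 0, 80, 10, "haldane")
  expect_equal(h, (90.5 * 80.5) / (0.5 * 10.5))
  expect_true(is.na(diagnostic_odds_ratio(90, 0, 80, 10, "strict")))
  expect_error(diagnostic_odds_ratio(-1, 0, 0, 0), "non-negative")
})

test_that("metric identities hold on a stated confusion table and random ones", {
  m <- confusion_metrics(90, 20, 80, 10)
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 80)
  expect_equal(m$ppv, 100 * 90 / 110, tolerance = 1e-12)  # 81.8%
  expect_equal(m$dor, 36)
  withr::with_seed(2, {
    for (i in 1:20) {
      cc <- as.list(stats::setNames(sample(0:50, 4, TRUE), c("TP", "FP", "TN", "FN")))
      m <- do.call(confusion_metrics, cc)
      tot <- cc$TP + cc$FP + cc$TN + cc$FN
      expect_equal(m$accuracy, 100 * (cc$TP + cc$TN) / tot)
      expect_equal(m$sensitivity, 100 * cc$TP / (cc$TP + cc$FN))
      expect_equal(m$specificity, 100 * cc$TN / (cc$TN + cc$FP))
      expect_equal(m$ppv, 100 * cc$TP / (cc$TP + cc$FP))
    }
  })
})

test_that("a one-point grid is chosen as-is with fold accuracies reported", {
  tab <- separable_table()
  spec <- classifier_spec("DT", grid = list(maxdepth = 3))
  tuned <- tune_classifier(spec, tab, c("x1", "x2"), k_folds = 5, seed = 1)
  expect_equal(tuned$params$maxdepth, 3)
  expect_length(tuned$fold_accuracy, 5)
  expect_equal(tuned$cv_mean, mean(tuned$fold_accuracy))
})

test_that("a linearly separable table gives 100% CV accuracy for the linear SVM", {
  tab <- separable_table()
  spec <- classifier_spec("SVM_linear", grid = list(cost = c(0.1, 1)))
  tuned <- tune_classifier(spec, tab, c("x1", "x2"), seed = 2)
  expect_equal(tuned$cv_mean, 100)
  expect_equal(tuned$cv_sd, 0)
})

test_that("every classifier family fits, predicts and is deterministic under a seed", {
  tab <- separable_table(seed = 7)
  grids <- compact_grids()
  for (fam in c("DT", "KNN", "SVM_linear", "SVM_RBF", "ADA", "RF", "ANN")) {
    spec <- classifier_spec(fam)
    params <- lapply(grids[[fam]], `[`, 1)
    f1 <- fit_classifier(spec, tab[, c("x1", "x2")], tab$rhythm_class,
                         params, seed = 3)
    p1 <- predict(f1, tab[, c("x1", "x2")])
    expect_true(all(p1 %in% c("AF", "SR")), label = fam)
    expect_gt(mean(p1 == tab$rhythm_class), 0.95, label = fam)
    f2 <- fit_classifier(spec, tab[, c("x1", "x2")], tab$rhythm_class,
                         params, seed = 3)
    expect_identical(p1, predict(f2, tab[, c("x1", "x2")]), label = fam)
  }
})

test_that("blindfold evaluation aborts on patient leakage", {
  tab <- separable_table()
  spec <- classifier_spec("DT", grid = list(maxdepth = 3))
  train <- tab[tab$patient_id %in% c("P01", "P02", "P03", "P04"), ]
  test <- tab[tab$patient_id %in% c("P04", "P05", "P06"), ]
  expect_error(evaluate_blindfold(spec, list(maxdepth = 3), train, test,
                                  c("x1", "x2")), "leakage")
  clean <- tab[tab$patient_id %in% c("P05", "P06"), ]
  m <- evaluate_blindfold(spec, list(maxdepth = 3), train, clean, c("x1", "x2"))
  expect_equal(m$TP + m$FP + m$TN + m$FN, nrow(clean))
})

test_that("an uninformative feature yields chance accuracy and a corrected DOR", {
  tab <- separable_table()
  tab$flat <- 0
  spec <- classifier_spec("DT", grid = list(maxdepth = 2))
  train <- tab[tab$patient_id %in% c("P01", "P02", "P03", "P04"), ]
  test <- tab[tab$patient_id %in% c("P05", "P06"), ]
  m <- evaluate_blindfold(spec, list(maxdepth = 2), train, test, "flat")
  expect_equal(m$accuracy, 50)        # balanced test set, majority vote
  expect_true(is.finite(m$dor))       # haldane-corrected despite empty cells
})

test_that("the experiment matrix emits one row per cell with disjoint patients", {
  tab <- separable_table(n_per_class = 45, seed = 12)
  names(tab)[names(tab) == "x1"] <- "g1"
  names(tab)[names(tab) == "x2"] <- "g2"
  train <- tab[tab$patient_id %in% sprintf("P%02d", 1:4), ]
  test <- tab[tab$patient_id %in% sprintf("P%02d", 5:6), ]
  ranking <- mrmr_rank(train, pool = c("g1", "g2"), bins = 4)
  specs <- list(classifier_spec("DT", grid = list(maxdepth = 2)),
                classifier_spec("KNN", grid = list(k = 3)))
  rep <- run_experiment_matrix(train, test, list(full = ranking),
                               specs = specs, k_max = 2, k_folds = 3, seed = 1)
  expect_equal(nrow(rep), 8)   # 2 families x 2 k x 2 modes x 1 pool
  expect_setequal(unique(rep$mode), c("cv5", "blindfold"))
  for (i in which(rep$mode == "blindfold")) {
    expect_equal(rep$TP[i] + rep$FP[i] + rep$TN[i] + rep$FN[i], nrow(test))
  }
  # metric identities recomputed from the stored confusion counts
  for (i in seq_len(nrow(rep))) {
    tot <- rep$TP[i] + rep$FP[i] + rep$TN[i] + rep$FN[i]
    expect_equal(rep$accuracy[i], 100 * (rep$TP[i] + rep$TN[i]) / tot)
  }
})
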
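test_that("confusion counts and metrics match an exhaustive hand count", {
  # 3-class confusion matrix [[4,1,0],[0,5,0],[1,0,4]] over 15 samples
  truth <- rep(c("a", "b", "c"), each = 5)
  pred <- c(rep("a", 4), "b",            # a: 4 right, 1 -> b
            rep("b", 5),                 # b: all right
            "a", rep("c", 4))            # c: 1 -> a, 4 right
  cc <- confusion_counts(truth, pred)
  expect_equal(attr(cc, "n_total"), 15)
  expect_true(all(cc$TP + cc$FP + cc$TN + cc$FN == 15))
  expect_equal(sum(cc$TP), 13)           # total correct predictions
  expect_equal(unlist(cc[cc$class == "a", c("TP", "FP", "FN", "TN")],
                      use.names = FALSE), c(4, 1, 1, 9))
  m <- compute_metrics(cc)
  expect_equal(m$overall_accuracy, 13 / 15)
  expect_equal(m$per_class$precision, c(4 / 5, 5 / 6, 4 / 4))
  expect_equal(m$per_class$recall, c(4 / 5, 5 / 5, 4 / 5))
  expect_equal(m$macro_precision, mean(c(4 / 5, 5 / 6, 1)))

  # perfect binary case and the undefined-precision convention
  p <- compute_metrics(confusion_counts(rep(c("x", "y"), each = 5),
                                        rep(c("x", "y"), each = 5)))
  expect_equal(p$per_class$precision, c(1, 1))
  expect_equal(p$per_class$recall, c(1, 1))
  und <- compute_metrics(confusion_counts(rep("x", 4), rep("x", 4),
                                          classes = c("x", "y")))
  expect_equal(und$per_class$precision[2], 0)
  expect_true(und$per_class$precision_undefined[2])
})

test_that("metrics are invariant to class renaming", {
  set.seed(51)
  truth <- sample(letters[1:4], 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, truth, sample(letters[1:4], 60, TRUE))
  m1 <- compute_metrics(confusion_counts(truth, pred))
  ren <- c(a = "w", b = "x", c = "y", d = "z")
  m2 <- compute_metrics(confusion_counts(ren[truth], ren[pred]))
  expect_equal(m1$overall_accuracy, m2$overall_accuracy)
  expect_equal(sort(m1$per_class$precision), sort(m2$per_class$precision))
  expect_equal(m1$macro_recall, m2$macro_recall)
})

test_that("cross-validation separates separable classes and is seed-deterministic", {
  # two classes with well-separated amplitude on every channel
  cfg <- sim_config(n_channels = 2, n_classes = 2, trial_duration = 0.4,
                    trials_per_class = 10,
                    informative_map = matrix(c(1, 6, 1, 6), 2, 2))
  rec <- generate_recording(cfg, seed = 52)
  fm <- build_feature_matrix(rec, discard_transitions = TRUE)
  ev <- crossval_evaluate(fm, folds = 5, seed = 1)
  expect_equal(ev$mean_accuracy, 1.0)
  expect_equal(mean(ev$fold_accuracy), ev$mean_accuracy)
  ev2 <- crossval_evaluate(fm, folds = 5, seed = 1)
  expect_identical(ev$fold_accuracy, ev2$fold_accuracy)
  expect_error(crossval_evaluate(fm, folds = 50), "reduce `folds`")
})

test_that("fold assignment is stratified and depends only on labels and seed", {
  labels <- rep(letters[1:3], times = c(15, 10, 20))
  f1 <- semgsel:::stratified_folds(labels, 5, seed = 9)
  f2 <- semgsel:::stratified_folds(labels, 5, seed = 9)
  expect_identical(f1, f2)
  for (cl in letters[1:3]) {
    tab <- table(f1[labels == cl])
    expect_lte(max(tab) - min(tab), 1)
  }
})

test_that("evaluation reports round-trip losslessly through JSON", {
  rec <- small_recording(seed = 53, trial_duration = 0.4,
                         trials_per_class = 2)
  fm <- build_feature_matrix(rec)
  ev <- crossval_evaluate(fm, channels = c("ch3", "ch5"), folds = 2, seed = 3)
  path <- tempfile(fileext = ".json")
  write_eval_report(ev, path)
  back <- read_eval_report(path)
  expect_equal(back$fold_accuracy, ev$fold_accuracy)
  expect_equal(back$mean_accuracy, ev$mean_accuracy)
  expect_equal(back$per_class$precision, ev$per_class$precision)
  expect_equal(back$channels, ev$channels)
})
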
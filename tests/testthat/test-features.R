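test_that("hand-computable windows give the textbook feature values", {
  sp <- window_spec(length = 3, step = 1, ar_order = 1)
  v <- extract_window_features(c(1, -2, 3), sp)
  expect_equal(unname(v["IAV"]), 6)
  expect_equal(unname(v["SSI"]), 14)
  expect_equal(unname(v["WL"]), 8)        # |-3| + |5|
  expect_equal(unname(v["ZC"]), 0)        # gaps 3 and 5 are below T = 10
  expect_equal(unname(v["RMS"]), sqrt(14 / 3))

  # every adjacent pair crosses zero with gap 40 > T
  sp4 <- window_spec(length = 4, step = 1, ar_order = 1)
  v4 <- extract_window_features(c(20, -20, 20, -20), sp4)
  expect_equal(unname(v4["ZC"]), 3)
})

test_that("zero-variance windows raise the degenerate-window condition", {
  sp <- window_spec(length = 8, step = 1)
  expect_error(extract_window_features(rep(5, 8), sp),
               class = "semgsel_degenerate_window")
})

test_that("AR features match a directly solved lag regression and recover a true AR(4)", {
  phi <- c(0.5, -0.3, 0.1, -0.05)
  set.seed(11)
  x <- as.numeric(stats::filter(rnorm(456), phi, method = "recursive"))[201:456]
  sp <- window_spec(length = 256, step = 256)
  a <- extract_window_features(x, sp)[paste0("AR", 1:4)]
  # independent oracle: lm() on the four lags, no intercept
  n <- length(x)
  lags <- sapply(1:4, function(l) x[(5 - l):(n - l)])
  oracle <- unname(coef(lm(x[5:n] ~ lags - 1)))
  expect_equal(unname(a), oracle, tolerance = 1e-7)

  # consistency: long window converges to the generating coefficients
  set.seed(12)
  xl <- as.numeric(stats::filter(rnorm(4296), phi,
                                 method = "recursive"))[201:4296]
  al <- extract_window_features(xl, window_spec(length = 4096,
                                                step = 4096))[paste0("AR", 1:4)]
  expect_lt(max(abs(unname(al) - phi)), 0.1)
})

test_that("feature invariances: sign flip, positive scaling, SSI identity", {
  sp <- window_spec(length = 64, step = 64)
  set.seed(3)
  for (rep in 1:5) {
    w <- rnorm(64, sd = 20)
    v <- extract_window_features(w, sp)
    vf <- extract_window_features(-w, sp)
    expect_equal(vf[c("WL", "IAV", "ZC", "RMS", "SSI", "Kurtosis")],
                 v[c("WL", "IAV", "ZC", "RMS", "SSI", "Kurtosis")])
    expect_equal(unname(vf["Skewness"]), -unname(v["Skewness"]))
    k <- runif(1, 0.5, 3)
    vs <- extract_window_features(k * w, sp)
    expect_equal(unname(vs[c("WL", "IAV", "RMS")]),
                 k * unname(v[c("WL", "IAV", "RMS")]))
    expect_equal(unname(vs["SSI"]), k^2 * unname(v["SSI"]))
    expect_equal(unname(vs[c("Kurtosis", "Skewness")]),
                 unname(v[c("Kurtosis", "Skewness")]))
    expect_equal(unname(v["SSI"]), 64 * unname(v["RMS"])^2)
    expect_true(all(v[c("WL", "IAV", "RMS", "SSI")] >= 0))
  }
})

test_that("windowize produces the expected window count and labels", {
  rec <- recording(matrix(rnorm(1000 * 2), 1000, 2), 1000,
                   labels = rep(c("a", "b"), each = 500))
  sp <- window_spec(length = 200, step = 100)
  w <- windowize(rec, sp)
  expect_length(w$windows, 9)             # floor((1000-200)/100)+1
  expect_equal(w$labels[1:3], rep("a", 3))
  expect_equal(w$labels[8:9], rep("b", 2))

  # one window when length = total; gaps when step > length
  expect_length(windowize(rec, window_spec(length = 1000, step = 1))$windows, 1)
  expect_length(windowize(rec, window_spec(length = 100, step = 300))$windows,
                4)                         # floor((1000-100)/300)+1
  # majority vote at the transition; discard option drops mixed windows
  w2 <- windowize(rec, sp, discard_transitions = TRUE)
  expect_length(w2$windows, 8)
  expect_error(windowize(recording(matrix(1:10, 10, 1), 100), sp),
               "shorter")
})

test_that("feature matrix has channels x 11 rows in channel-major order", {
  rec <- small_recording(seed = 2, trial_duration = 0.4, trials_per_class = 1)
  fm <- build_feature_matrix(rec)
  expect_equal(nrow(fm$values), 8 * 11)
  expect_equal(fm$row_index$channel[1:11], rep("ch1", 11))
  expect_equal(fm$row_index$feature[1:11], feature_names())
  expect_false(anyDuplicated(paste(fm$row_index$channel,
                                   fm$row_index$feature)) > 0)
  expect_length(fm$col_labels, ncol(fm$values))

  rec2 <- recording(rec$samples[, 1:2], rec$sampling_rate,
                    labels = rec$labels)
  expect_equal(nrow(build_feature_matrix(rec2)$values), 22)
})

test_that("standardization z-scores rows, optionally from training stats only", {
  rec <- small_recording(seed = 4, trial_duration = 0.4, trials_per_class = 2)
  fm <- build_feature_matrix(rec, standardize = TRUE)
  mu <- rowMeans(fm$values)
  sdv <- apply(fm$values, 1, sd)
  const <- apply(fm$values, 1, function(r) all(r == r[1]))
  expect_lt(max(abs(mu)), 1e-10)
  expect_equal(unname(sdv[!const]), rep(1, sum(!const)), tolerance = 1e-10)

  mask <- seq_len(ncol(fm$values)) <= ncol(fm$values) / 2
  fm2 <- build_feature_matrix(rec, standardize = TRUE, train_mask = mask)
  expect_lt(max(abs(rowMeans(fm2$values[, mask]))), 1e-10)
  expect_false(isTRUE(all.equal(rowMeans(fm2$values), rowMeans(fm$values))))
})
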
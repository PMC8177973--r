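test_that("objective matches direct element-wise arithmetic", {
  set.seed(21)
  X <- matrix(rnorm(4 * 6), 4, 6)
  Y <- matrix(rnorm(2 * 6), 2, 6)
  W <- matrix(rnorm(4 * 2), 4, 2)
  lambda <- 0.1
  # independent oracle: explicit loops over every matrix element
  fit_term <- 0
  for (i in 1:2) for (j in 1:6) {
    pred <- 0
    for (r in 1:4) pred <- pred + W[r, i] * X[r, j]
    fit_term <- fit_term + (Y[i, j] - pred)^2
  }
  reg <- 0
  for (r in 1:4) reg <- reg + sqrt(W[r, 1]^2 + W[r, 2]^2)
  expect_equal(mtsr_objective(W, X, Y, lambda), 0.5 * fit_term + lambda * reg,
               tolerance = 1e-10)
  expect_equal(mtsr_objective(matrix(0, 4, 2), X, Y, 1), 0.5 * sum(Y^2))
  expect_error(mtsr_objective(W, X, Y[, 1:3], lambda))
})

test_that("lambda = 0 returns the least-squares solution, lambda >= lambda_max selects nothing", {
  set.seed(22)
  X <- matrix(rnorm(5 * 5), 5, 5)
  Y <- matrix(rnorm(3 * 5), 3, 5)
  fit0 <- solve_mtsr(X, Y, 0)
  expect_lt(mtsr_objective(fit0$W, X, Y, 0), 1e-8)   # invertible square system
  expect_true(fit0$converged)

  ins <- random_mtsr_instance(23, d = 10, n = 40, c = 3)
  lmax <- mtsr_lambda_max(ins$X, ins$Y)
  fit_hi <- solve_mtsr(ins$X, ins$Y, 10 * lmax)
  sel <- select_variables_mtsr(fit_hi,
                               data.frame(channel = rep("c", 10),
                                          feature = as.character(1:10)))
  expect_equal(nrow(sel), 0)
  fit_lo <- solve_mtsr(ins$X, ins$Y, 0)
  sel_lo <- select_variables_mtsr(fit_lo,
                                  data.frame(channel = rep("c", 10),
                                             feature = as.character(1:10)))
  expect_equal(nrow(sel_lo), 10)
})

test_that("solver agrees with the proximal-gradient oracle and decreases monotonically", {
  for (seed in 1:8) {
    ins <- random_mtsr_instance(seed, d = 5 + seed, n = 20 + 3 * seed,
                                c = 2 + seed %% 3)
    lam <- 0.3 * mtsr_lambda_max(ins$X, ins$Y)
    fit <- solve_mtsr(ins$X, ins$Y, lam)
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
    Wp <- semgsel:::mtsr_prox_reference(ins$X, ins$Y, lam, iters = 20000)
    op <- mtsr_objective(Wp, ins$X, ins$Y, lam)
    expect_lt(abs(fit$objective - op) / op, 1e-4)
  }
})

test_that("planted predictive rows dominate the coefficient row norms", {
  hits <- 0
  for (seed in 1:10) {
    ins <- planted_mtsr_instance(seed)
    lam <- 0.2 * mtsr_lambda_max(ins$X, ins$Y)
    fit <- solve_mtsr(ins$X, ins$Y, lam)
    top <- order(fit$row_norms, decreasing = TRUE)[seq_along(ins$support)]
    if (setequal(top, ins$support)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("solution is invariant to permuting the sample order", {
  ins <- random_mtsr_instance(31, d = 8, n = 30, c = 3)
  lam <- 0.3 * mtsr_lambda_max(ins$X, ins$Y)
  set.seed(32)
  perm <- sample(ncol(ins$X))
  f1 <- solve_mtsr(ins$X, ins$Y, lam)
  f2 <- solve_mtsr(ins$X[, perm], ins$Y[, perm], lam)
  expect_equal(f1$W, f2$W, tolerance = 1e-6)
})

test_that("lambda sweep reports sizes from full to empty and picks a sparse lambda", {
  rec <- small_recording(seed = 33, trial_duration = 0.4,
                         trials_per_class = 4)
  fm <- standardize_features(build_feature_matrix(rec))
  Y <- class_indicator(fm$col_labels)
  lmax <- mtsr_lambda_max(fm$values, Y)
  grid <- c(0, 0.2 * lmax, 10 * lmax)
  sw <- lambda_sweep(fm, grid, evaluate = TRUE, folds = 3, seed = 1)
  expect_equal(sw$n_selected[1], nrow(fm$values))
  expect_equal(sw$n_selected[3], 0)
  expect_true(is.na(sw$cv_accuracy[3]))
  expect_lte(sw$n_selected[3], sw$n_selected[1])
  expect_equal(pick_lambda(sw, margin = 1), 0.2 * lmax)  # widest margin -> sparsest evaluated
})
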
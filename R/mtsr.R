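#' One-hot class indicator matrix
#'
#' @param labels Vector of class labels, one per sample.
#' @param classes Optional class ordering; default the factor levels.
#' @return c x n matrix with a single 1 per column.
#' @export
class_indicator <- function(labels, classes = NULL) {
  f <- factor(labels, levels = if (is.null(classes)) sort(unique(as.character(labels))) else classes)
  if (anyNA(f)) stop("labels contain classes not listed in `classes`")
  Y <- matrix(0, nlevels(f), length(f),
              dimnames = list(levels(f), NULL))
  Y[cbind(as.integer(f), seq_along(f))] <- 1
  Y
}

#' l2,1-regularized multitask regression objective
#'
#' Value of 0.5 * ||Y - t(W) X||_F^2 + lambda * sum_i ||w_i||_2, the
#' row-sparse multitask least-squares objective whose zero rows of W
#' eliminate channel-feature variables jointly across all gesture classes.
#'
#' @param W d x c coefficient matrix.
#' @param X d x n variable matrix (variables in rows).
#' @param Y c x n class indicator matrix.
#' @param lambda Non-negative sparsity weight.
#' @return Non-negative scalar.
#' @export
mtsr_objective <- function(W, X, Y, lambda) {
  stopifnot(nrow(W) == nrow(X), ncol(W) == nrow(Y), ncol(X) == ncol(Y),
            lambda >= 0)
  R <- Y - crossprod(W, X)
  0.5 * sum(R^2) + lambda * sum(sqrt(rowSums(W^2)))
}

#' Smallest penalty that zeroes every coefficient row
#'
#' For the objective of [mtsr_objective()], the zero matrix is stationary
#' exactly when every row of X Y' has l2 norm at most lambda; this returns
#' that bound.
#'
#' @inheritParams mtsr_objective
#' @return Scalar lambda_max.
#' @export
mtsr_lambda_max <- function(X, Y) {
  G <- X %*% t(Y)
  max(sqrt(rowSums(G^2)))
}

#' Solve the l2,1-regularized multitask regression
#'
#' Minimizes 0.5 * ||Y - t(W) X||_F^2 + lambda * ||W||_{2,1} by
#' iteratively reweighted least squares: each iteration solves
#' (X X' + lambda * diag(1 / u_i)) W = X Y' with u_i the smoothed row
#' norm sqrt(||w_i||^2 + epsilon^2). The smoothing makes every system
#' well-posed and gives a monotonically non-increasing (smoothed)
#' objective. The cold start is the ridge least-squares solution, so the
#' result is deterministic.
#'
#' @param X d x n variable matrix.
#' @param Y c x n class indicator (or general response) matrix.
#' @param lambda Non-negative sparsity weight. At 0 the ridge-stabilized
#'   least-squares solution is returned directly.
#' @param tol Relative change in the smoothed objective at which to stop.
#' @param max_iter Iteration cap; non-convergence returns the last iterate
#'   with `converged = FALSE`.
#' @param epsilon Row-norm smoothing constant.
#' @return Object of class `mtsr_fit`: `W`, `row_norms`, `objective`
#'   (unsmoothed), `objective_trace` (smoothed, per iteration),
#'   `converged`, `iterations`, `lambda`.
#' @export
solve_mtsr <- function(X, Y, lambda, tol = 1e-7, max_iter = 200L,
                       epsilon = 1e-8) {
  stopifnot(is.matrix(X), is.matrix(Y), ncol(X) == ncol(Y), lambda >= 0)
  d <- nrow(X)
  XXt <- tcrossprod(X)
  XYt <- X %*% t(Y)
  ridge <- 1e-8 * max(diag(XXt), 1)
  W <- solve(XXt + ridge * diag(d), XYt)

  smoothed <- function(W) {
    R <- Y - crossprod(W, X)
    0.5 * sum(R^2) + lambda * sum(sqrt(rowSums(W^2) + epsilon^2))
  }
  trace <- smoothed(W)
  converged <- (lambda == 0)
  it <- 0L
  if (lambda > 0) {
    for (it in seq_len(max_iter)) {
      u <- sqrt(rowSums(W^2) + epsilon^2)
      W <- solve(XXt + lambda * diag(1 / u, d), XYt)
      f <- smoothed(W)
      trace <- c(trace, f)
      prev <- trace[length(trace) - 1L]
      if (abs(prev - f) <= tol * max(abs(prev), 1e-300)) {
        converged <- TRUE
        break
      }
    }
  }
  rn <- sqrt(rowSums(W^2))
  names(rn) <- rownames(X)
  structure(list(W = W, row_norms = rn,
                 objective = mtsr_objective(W, X, Y, lambda),
                 objective_trace = trace, converged = converged,
                 iterations = it, lambda = lambda, epsilon = epsilon),
            class = "mtsr_fit")
}

#' @export
print.mtsr_fit <- function(x, ...) {
  cat(sprintf("mtsr_fit: %d x %d coefficients, lambda = %g, %d iterations%s\n",
              nrow(x$W), ncol(x$W), x$lambda, x$iterations,
              if (x$converged) "" else " (not converged)"))
  cat(sprintf("  objective %.6g; nonzero rows (rel. 1e-6): %d\n",
              x$objective, sum(x$row_norms > 1e-6 * max(x$row_norms, 0))))
  invisible(x)
}

#' Construct a channel-feature variable set
#'
#' @param channel,feature Parallel vectors identifying the pairs.
#' @param method Provenance tag, e.g. `"mtsr"` or `"mrmr"`.
#' @param score Optional per-pair score (row norm, mRMR criterion value).
#' @return data.frame of class `semg_varset` with columns channel, feature
#'   (and score), and a `method` attribute.
#' @export
variable_set <- function(channel, feature, method = "manual", score = NULL) {
  stopifnot(length(channel) == length(feature))
  vs <- data.frame(channel = as.character(channel),
                   feature = as.character(feature),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(paste(vs$channel, vs$feature)))
    stop("duplicate (channel, feature) pairs in variable set")
  if (!is.null(score)) vs$score <- score
  structure(vs, method = method, class = c("semg_varset", "data.frame"))
}

#' @export
print.semg_varset <- function(x, ...) {
  cat(sprintf("semg_varset (%s): %d channel-feature pairs over %d channels\n",
              attr(x, "method"), nrow(x), length(unique(x$channel))))
  print.data.frame(utils::head(x, 12))
  if (nrow(x) > 12) cat("  ...\n")
  invisible(x)
}

#' Keep the variables with non-negligible coefficient rows
#'
#' A variable (channel, feature pair) survives the MTSR screen when its
#' coefficient row norm exceeds `zero_tol` times the largest row norm.
#'
#' @param fit An `mtsr_fit`.
#' @param row_index data.frame with `channel` and `feature` columns, one row
#'   per row of the coefficient matrix (e.g. `fm$row_index`).
#' @param zero_tol Relative threshold below which a row counts as zero.
#'   Independently, when even the largest row norm is of the order of the
#'   solver's smoothing constant (the fully-shrunk regime at
#'   lambda >= lambda_max, where the smoothed iteration leaves every row
#'   at O(epsilon) rather than exactly zero), the selection is empty.
#' @return A [variable_set()] with `method = "mtsr"`, ordered by descending
#'   row norm.
#' @export
select_variables_mtsr <- function(fit, row_index, zero_tol = 1e-6) {
  stopifnot(inherits(fit, "mtsr_fit"), nrow(row_index) == length(fit$row_norms))
  mx <- max(fit$row_norms)
  eps <- if (!is.null(fit$epsilon)) fit$epsilon else 1e-8
  keep <- if (mx <= 1e3 * eps) integer(0)
          else which(fit$row_norms > zero_tol * mx)
  keep <- keep[order(fit$row_norms[keep], decreasing = TRUE)]
  variable_set(row_index$channel[keep], row_index$feature[keep],
               method = "mtsr", score = unname(fit$row_norms[keep]))
}

#' Sweep the sparsity parameter
#'
#' Solves the MTSR screen over a grid of lambda values and reports, per
#' value, the number of surviving variables and (optionally) the
#' cross-validated accuracy of an SVM restricted to them.
#'
#' @param fm A `semg_features` matrix with `col_labels`.
#' @param grid Numeric vector of lambda values.
#' @param evaluate If `TRUE`, run [crossval_evaluate()] on each selection.
#' @param folds,seed,cost,gamma Passed to the evaluation.
#' @param zero_tol,tol,max_iter,epsilon Passed to the solver/selection.
#' @return data.frame of class `mtsr_sweep` with columns `lambda`,
#'   `n_selected`, `cv_accuracy` (NA where the selection is empty or
#'   evaluation is off).
#' @export
lambda_sweep <- function(fm, grid, evaluate = TRUE, folds = 5L, seed = 1L,
                         cost = 1, gamma = NULL, zero_tol = 1e-6,
                         tol = 1e-7, max_iter = 200L, epsilon = 1e-8) {
  stopifnot(inherits(fm, "semg_features"), length(grid) >= 1,
            !is.null(fm$col_labels))
  Y <- class_indicator(fm$col_labels)
  res <- data.frame(lambda = grid, n_selected = NA_integer_,
                    cv_accuracy = NA_real_)
  prev_n <- Inf
  for (i in seq_along(grid)) {
    fit <- solve_mtsr(fm$values, Y, grid[i], tol = tol,
                      max_iter = max_iter, epsilon = epsilon)
    sel <- select_variables_mtsr(fit, fm$row_index, zero_tol)
    res$n_selected[i] <- nrow(sel)
    if (i > 1 && res$n_selected[i] > prev_n && grid[i] > grid[i - 1])
      message("n_selected increased from ", prev_n, " to ", res$n_selected[i],
              " at lambda = ", grid[i], " (thresholding non-monotonicity)")
    prev_n <- res$n_selected[i]
    if (evaluate && nrow(sel) > 0) {
      ev <- crossval_evaluate(fm, pairs = sel, folds = folds, seed = seed,
                              cost = cost, gamma = gamma)
      res$cv_accuracy[i] <- ev$mean_accuracy
    }
  }
  class(res) <- c("mtsr_sweep", "data.frame")
  res
}

#' Pick a lambda from a sweep table
#'
#' Returns the largest lambda (fewest variables) whose cross-validated
#' accuracy is within `margin` of the best accuracy in the sweep — a
#' reproducible operationalization of choosing the accuracy/size knee.
#'
#' @param sweep An `mtsr_sweep` table.
#' @param margin Allowed accuracy drop from the best (default 0.01).
#' @return The chosen lambda.
#' @export
pick_lambda <- function(sweep, margin = 0.01) {
  ok <- !is.na(sweep$cv_accuracy)
  if (!any(ok)) stop("sweep has no evaluated lambda values")
  best <- max(sweep$cv_accuracy[ok])
  cand <- sweep$lambda[ok & sweep$cv_accuracy >= best - margin]
  max(cand)
}

# Proximal-gradient reference solver for the same objective; used as an
# independent oracle in the tests, deliberately sharing no code with
# solve_mtsr.
mtsr_prox_reference <- function(X, Y, lambda, iters = 5000L) {
  d <- nrow(X); c <- nrow(Y)
  XXt <- tcrossprod(X)
  XYt <- X %*% t(Y)
  Lip <- max(eigen(XXt, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / Lip
  W <- matrix(0, d, c)
  for (i in seq_len(iters)) {
    G <- XXt %*% W - XYt
    V <- W - step * G
    rn <- sqrt(rowSums(V^2))
    shrink <- pmax(0, 1 - step * lambda / pmax(rn, 1e-300))
    W <- V * shrink
  }
  W
}
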
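#' Compound sEMG channel selection
#'
#' The package's central fit: from a labeled multichannel recording (or a
#' prebuilt channel-feature matrix), screen channel-feature variables with
#' the l2,1-regularized multitask regression (MTSR) and with mRMR
#' mutual-information ranking, count shared features between channel pairs
#' for each screen, rank channels by their co-occurrence row sums, fuse
#' the two rankings into k channels, and take the features shared by a
#' majority of channels as the final feature list. Optionally the selected
#' channel/feature subset is evaluated with a cross-validated RBF SVM.
#'
#' @param x A [recording()] with labels, or a `semg_features` matrix with
#'   `col_labels`.
#' @param window A [window_spec()], used when `x` is a recording.
#' @param lambda MTSR sparsity weight. `NULL` (default) uses
#'   `lambda_rel * mtsr_lambda_max(X, Y)`, making the penalty scale-free.
#' @param lambda_rel Relative penalty used when `lambda` is `NULL`
#'   (default 0.2, which keeps roughly a third of the variables on
#'   amplitude-structured data — the retention regime this screen is
#'   typically operated in).
#' @param m Number of variables kept by mRMR; default the MTSR-selected
#'   count, so the two screens are fused on equal footing.
#' @param k Number of channels to select (default 3).
#' @param strategy Fusion strategy, see [fuse_rankings()].
#' @param criterion mRMR criterion, see [mrmr_rank()].
#' @param standardize Z-score the variable rows before MTSR (default TRUE).
#' @param evaluate Run the cross-validated SVM on the fused
#'   channels x majority features (default TRUE).
#' @param folds,cost,gamma,seed Evaluation settings, see
#'   [crossval_evaluate()].
#' @param zero_tol,tol,max_iter,epsilon MTSR solver/selection settings.
#' @return Object of class `semg_select` with the feature matrix, both
#'   screens' variable sets, co-occurrence matrices, rankings, the fusion
#'   result, the majority-feature lists and (optionally) the evaluation
#'   report.
#' @examples
#' rec <- generate_recording(sim_config(trial_duration = 0.4,
#'                                      trials_per_class = 4), seed = 1)
#' fit <- semg_select(rec, k = 3, evaluate = FALSE)
#' fit$fusion$selected_channels
#' @export
semg_select <- function(x, window = window_spec(), lambda = NULL,
                        lambda_rel = 0.2, m = NULL, k = 3L,
                        strategy = c("mutual_top", "rank_sum"),
                        criterion = c("mid", "miq"), standardize = TRUE,
                        evaluate = TRUE, folds = 5L, cost = 1, gamma = NULL,
                        seed = 1L, zero_tol = 1e-6, tol = 1e-7,
                        max_iter = 200L, epsilon = 1e-8) {
  strategy <- match.arg(strategy)
  criterion <- match.arg(criterion)
  cl <- match.call()
  fm <- if (inherits(x, "recording"))
    build_feature_matrix(x, window) else x
  stopifnot(inherits(fm, "semg_features"))
  if (is.null(fm$col_labels)) stop("windows carry no gesture labels")
  fm_std <- if (standardize && is.null(fm$standardization))
    standardize_features(fm) else fm

  Y <- class_indicator(fm_std$col_labels)
  lam <- if (is.null(lambda)) lambda_rel * mtsr_lambda_max(fm_std$values, Y)
         else lambda
  fit <- solve_mtsr(fm_std$values, Y, lam, tol = tol, max_iter = max_iter,
                    epsilon = epsilon)
  sel_mtsr <- select_variables_mtsr(fit, fm_std$row_index, zero_tol)
  if (nrow(sel_mtsr) == 0)
    stop("MTSR screen kept no variables; lower `lambda`")

  mm <- if (is.null(m)) nrow(sel_mtsr) else m
  disc <- discretize(fm_std)
  sel_mrmr <- mrmr_rank(disc, fm_std$col_labels, m = mm,
                        criterion = criterion, row_index = fm_std$row_index)

  cooc_a <- cooccurrence(sel_mtsr, fm$channel_ids)
  cooc_b <- cooccurrence(sel_mrmr, fm$channel_ids)
  rank_a <- rank_channels(cooc_a)
  rank_b <- rank_channels(cooc_b)
  fusion <- fuse_rankings(rank_a, rank_b, k, strategy = strategy)
  feats <- select_features_by_majority(sel_mtsr, sel_mrmr,
                                       n_channels = length(fm$channel_ids))
  ev <- NULL
  if (evaluate) {
    use_feats <- if (length(feats$union)) feats$union
                 else feature_names(fm$spec$ar_order)
    ev <- crossval_evaluate(fm, channels = fusion$selected_channels,
                            features = use_feats, folds = folds,
                            cost = cost, gamma = gamma, seed = seed)
  }
  structure(list(features = fm, mtsr_fit = fit, lambda = lam,
                 varset_mtsr = sel_mtsr, varset_mrmr = sel_mrmr,
                 cooc_mtsr = cooc_a, cooc_mrmr = cooc_b,
                 ranking_mtsr = rank_a, ranking_mrmr = rank_b,
                 fusion = fusion, majority_features = feats,
                 evaluation = ev, call = cl),
            class = "semg_select")
}

#' @export
print.semg_select <- function(x, ...) {
  cat("Compound sEMG channel selection\n")
  cat(sprintf("  %d channels x %d features, %d windows; lambda = %.4g\n",
              length(x$features$channel_ids),
              nrow(x$features$values) / length(x$features$channel_ids),
              ncol(x$features$values), x$lambda))
  cat(sprintf("  MTSR kept %d variables; mRMR ranked %d\n",
              nrow(x$varset_mtsr), nrow(x$varset_mrmr)))
  cat(sprintf("  fused channels (k = %d): {%s}\n", x$fusion$k,
              paste(x$fusion$selected_channels, collapse = ", ")))
  cat(sprintf("  majority features: %s\n",
              paste(x$majority_features$union, collapse = ", ")))
  if (!is.null(x$evaluation))
    cat(sprintf("  CV accuracy on selection: %.2f%%\n",
                100 * x$evaluation$mean_accuracy))
  invisible(x)
}

#' @export
summary.semg_select <- function(object, ...) {
  x <- object
  print(x)
  cat("\nChannel order (MTSR):", format(x$ranking_mtsr), "\n")
  cat("Channel order (mRMR):", format(x$ranking_mrmr), "\n")
  cat("\nPer-channel audit:\n")
  print(x$fusion$audit, row.names = FALSE)
  if (!is.null(x$evaluation)) {
    cat("\nEvaluation:\n")
    print(x$evaluation)
  }
  invisible(x)
}

#' @export
coef.semg_select <- function(object, ...) object$mtsr_fit$W

#' Plot a channel-selection fit
#'
#' Side-by-side bar charts of the co-occurrence row sums under the two
#' screening methods, with the fused channels highlighted.
#'
#' @param x A `semg_select` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.semg_select <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  sel <- x$fusion$selected_channels
  for (m in c("mtsr", "mrmr")) {
    cooc <- x[[paste0("cooc_", m)]]
    cols <- ifelse(cooc$channel_ids %in% sel, "steelblue", "grey70")
    graphics::barplot(cooc$row_sums, names.arg = cooc$channel_ids,
                      col = cols, main = toupper(m),
                      xlab = "channel", ylab = "co-occurrence row sum", ...)
  }
  invisible(x)
}
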
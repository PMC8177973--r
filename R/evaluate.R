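#' One-vs-rest confusion counts
#'
#' Per-class true/false positive/negative counts for a multiclass
#' prediction, treating each class against the rest.
#'
#' @param truth,pred Parallel vectors of true and predicted class labels.
#' @param classes Optional class universe (default: classes observed in
#'   either vector).
#' @return Object of class `semg_confusion`: data.frame with one row per
#'   class (TP, FP, TN, FN) and attribute `n_total`.
#' @export
confusion_counts <- function(truth, pred, classes = NULL) {
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  if (is.null(classes)) classes <- sort(unique(c(as.character(truth),
                                                 as.character(pred))))
  truth <- as.character(truth); pred <- as.character(pred)
  n <- length(truth)
  tab <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    data.frame(class = cl, TP = tp, FP = fp, TN = n - tp - fp - fn, FN = fn,
               stringsAsFactors = FALSE)
  }))
  structure(tab, n_total = n, class = c("semg_confusion", "data.frame"))
}

#' Precision, recall and accuracy from confusion counts
#'
#' Per class: precision = TP/(TP+FP), recall = TP/(TP+FN),
#' accuracy = (TP+TN)/n. A zero denominator (no predicted, or no actual,
#' positives for a class) makes the metric undefined; it is reported as 0
#' and flagged in the `undefined` columns. Macro averages are the plain
#' means over classes; `overall_accuracy` is the multiclass
#' correct/n_total.
#'
#' @param cc A `semg_confusion` object.
#' @return List with `per_class` (data.frame), `macro_precision`,
#'   `macro_recall`, `overall_accuracy`.
#' @export
compute_metrics <- function(cc) {
  stopifnot(inherits(cc, "semg_confusion"))
  n <- attr(cc, "n_total")
  safe_div <- function(num, den) ifelse(den > 0, num / pmax(den, 1), 0)
  per <- data.frame(
    class = cc$class,
    precision = safe_div(cc$TP, cc$TP + cc$FP),
    recall = safe_div(cc$TP, cc$TP + cc$FN),
    accuracy = (cc$TP + cc$TN) / n,
    precision_undefined = (cc$TP + cc$FP) == 0,
    recall_undefined = (cc$TP + cc$FN) == 0,
    stringsAsFactors = FALSE)
  list(per_class = per,
       macro_precision = mean(per$precision),
       macro_recall = mean(per$recall),
       overall_accuracy = sum(cc$TP) / n)
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin, so fold sizes differ by at most one per class.
stratified_folds <- function(labels, folds, seed) {
  f <- integer(length(labels))
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Cross-validated SVM evaluation of a channel/feature subset
#'
#' Restricts the feature matrix to the requested channels and features
#' (or explicit channel-feature pairs), then runs stratified k-fold
#' cross-validation with an RBF-kernel SVM. Standardization statistics are
#' fit on each training fold only. The default kernel width is
#' gamma = 1/(d * var(X_train)), with d the number of kept variables.
#'
#' @param fm A `semg_features` matrix with `col_labels`.
#' @param channels,features Keep rows whose channel / feature is listed
#'   (`NULL` = no restriction on that axis).
#' @param pairs Alternatively, a [variable_set()] of explicit rows.
#' @param folds Number of cross-validation folds (default 5).
#' @param cost SVM cost parameter C (default 1).
#' @param gamma RBF width; `NULL` for the default above.
#' @param seed Seed for the fold assignment.
#' @return Object of class `semg_eval`: fold accuracies, mean accuracy,
#'   pooled per-class metrics, macro averages, the subset used and the
#'   classifier configuration.
#' @export
crossval_evaluate <- function(fm, channels = NULL, features = NULL,
                              pairs = NULL, folds = 5L, cost = 1,
                              gamma = NULL, seed = 1L) {
  stopifnot(inherits(fm, "semg_features"))
  if (is.null(fm$col_labels)) stop("feature matrix carries no window labels")
  rows <- subset_rows(fm, channels, features, pairs)
  if (length(rows) == 0) stop("subset selects no channel-feature rows")
  X <- t(fm$values[rows, , drop = FALSE])   # n x d
  y <- factor(fm$col_labels)
  cls_n <- table(y)
  if (any(cls_n < folds))
    stop("class(es) ", paste(names(cls_n)[cls_n < folds], collapse = ", "),
         " have fewer samples than folds; reduce `folds`")
  fold_id <- stratified_folds(as.character(y), folds, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  fold_acc <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    g <- if (is.null(gamma)) 1 / (ncol(Xtr) * stats::var(as.vector(Xtr)))
         else gamma
    fit <- e1071::svm(Xtr, y[tr], kernel = "radial", cost = cost,
                      gamma = g, scale = FALSE)
    p <- stats::predict(fit, Xte)
    pred[!tr] <- p
    fold_acc[k] <- mean(p == y[!tr])
  }
  cc <- confusion_counts(y, pred, classes = levels(y))
  met <- compute_metrics(cc)
  structure(list(fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 overall_accuracy = met$overall_accuracy,
                 per_class = met$per_class,
                 macro_precision = met$macro_precision,
                 macro_recall = met$macro_recall,
                 channels = channels, features = features,
                 n_variables = length(rows),
                 config = list(folds = folds, cost = cost, gamma = gamma,
                               kernel = "radial", seed = seed)),
            class = "semg_eval")
}

#' @export
print.semg_eval <- function(x, ...) {
  cat(sprintf("semg_eval: %d-fold CV over %d variables\n",
              x$config$folds, x$n_variables))
  cat(sprintf("  mean accuracy %.2f%% (folds: %s)\n", 100 * x$mean_accuracy,
              paste(sprintf("%.1f", 100 * x$fold_accuracy), collapse = " ")))
  cat(sprintf("  macro precision %.2f%%, macro recall %.2f%%\n",
              100 * x$macro_precision, 100 * x$macro_recall))
  invisible(x)
}

#' Serialize / restore an evaluation report as JSON
#'
#' @param ev A `semg_eval` object.
#' @param path File to write / read.
#' @return `read_eval_report` returns the restored `semg_eval` object.
#' @export
write_eval_report <- function(ev, path) {
  stopifnot(inherits(ev, "semg_eval"))
  jsonlite::write_json(unclass(ev), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$per_class <- as.data.frame(obj$per_class)
  structure(obj, class = "semg_eval")
}
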
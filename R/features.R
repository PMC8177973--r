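#' Analysis-window specification
#'
#' Describes how a multichannel recording is cut into analysis windows and
#' how the per-window features are computed.
#'
#' @param length Window length in samples. Must be at least `ar_order + 2`.
#' @param step Stride between consecutive window starts, in samples.
#'   Defaults to half the window length (50\% overlap).
#' @param zc_threshold Amplitude-gap threshold for the zero-crossing count,
#'   in signal units. A crossing is counted only when the two samples change
#'   sign and differ by more than this value. Default 10.
#' @param ar_order Order of the autoregressive model fitted per window.
#'   Default 4, giving four AR-coefficient features.
#' @param ar_method Estimator for the AR coefficients: `"ls"` (conditional
#'   least squares on the lagged regression, the default) or `"burg"`.
#'
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length = 200L, step = NULL, zc_threshold = 10,
                        ar_order = 4L, ar_method = c("ls", "burg")) {
  ar_method <- match.arg(ar_method)
  length <- as.integer(length)
  if (is.null(step)) step <- length %/% 2L
  step <- as.integer(step)
  ar_order <- as.integer(ar_order)
  stopifnot(length >= ar_order + 2L, step >= 1L, zc_threshold >= 0,
            ar_order >= 1L)
  structure(list(length = length, step = step, zc_threshold = zc_threshold,
                 ar_order = ar_order, ar_method = ar_method),
            class = "window_spec")
}

#' Names of the per-channel features, in extraction order
#'
#' @param ar_order Number of autoregressive coefficients (default 4).
#' @return Character vector: WL, IAV, RMS, SSI, Kurtosis, Skewness, ZC,
#'   then AR1..ARp.
#' @export
feature_names <- function(ar_order = 4L) {
  c("WL", "IAV", "RMS", "SSI", "Kurtosis", "Skewness", "ZC",
    paste0("AR", seq_len(ar_order)))
}

degenerate_window_error <- function() {
  stop(structure(class = c("semgsel_degenerate_window", "error", "condition"),
                 list(message = paste("zero-variance window: kurtosis and",
                                      "skewness are undefined"),
                      call = sys.call(-1))))
}

# Conditional least-squares fit of x_i = sum_p a_p x_{i-p} + eps_i.
# A vanishing ridge keeps the normal equations solvable for pathological
# (perfectly predictable) windows without measurably biasing the fit.
ar_ls <- function(x, p) {
  n <- length(x)
  Z <- sapply(seq_len(p), function(lag) x[(p + 1 - lag):(n - lag)])
  y <- x[(p + 1):n]
  G <- crossprod(Z)
  delta <- 1e-10 * max(diag(G), 1)
  drop(solve(G + delta * diag(p), crossprod(Z, y)))
}

ar_burg <- function(x, p) {
  fit <- stats::ar.burg(x, aic = FALSE, order.max = p, demean = TRUE)
  as.numeric(fit$ar)
}

#' Time-domain features of one analysis window
#'
#' Computes the eleven classic time-domain features used in myoelectric
#' pattern recognition from a single channel's window: waveform length
#' (WL), integrated absolute value (IAV), root mean square (RMS), simple
#' square integral (SSI), excess kurtosis, skewness, thresholded zero
#' crossings (ZC), and the coefficients of a 4th-order autoregressive fit
#' (AR1..AR4).
#'
#' Kurtosis and skewness use the sample standard deviation (divisor L-1)
#' and L-1 in the moment numerators; kurtosis is reported in excess form
#' (minus 3). ZC counts adjacent sample pairs with opposite signs whose
#' absolute difference exceeds the threshold T of the spec.
#'
#' @param window Numeric vector of length `spec$length`.
#' @param spec A [window_spec()].
#' @return Named numeric vector of `length(feature_names(spec$ar_order))`
#'   values in the order given by [feature_names()].
#' @export
extract_window_features <- function(window, spec = window_spec()) {
  stopifnot(is.numeric(window), all(is.finite(window)))
  L <- spec$length
  if (length(window) != L)
    stop("window has length ", length(window), ", spec$length is ", L)
  xbar <- mean(window)
  sdev <- stats::sd(window)
  if (sdev == 0) degenerate_window_error()

  wl <- sum(abs(diff(window)))
  iav <- sum(abs(window))
  rms <- sqrt(mean(window^2))
  ssi <- sum(window^2)
  kurt <- sum((window - xbar)^4) / (L - 1) / sdev^4 - 3
  skew <- sum((window - xbar)^3) / (L - 1) / sdev^3
  x1 <- window[-L]; x2 <- window[-1]
  zc <- sum(x1 * x2 < 0 & abs(x1 - x2) > spec$zc_threshold)
  a <- switch(spec$ar_method,
              ls = ar_ls(window, spec$ar_order),
              burg = ar_burg(window, spec$ar_order))
  stats::setNames(c(wl, iav, rms, ssi, kurt, skew, zc, a),
                  feature_names(spec$ar_order))
}

#' Multichannel recording container
#'
#' @param samples Numeric matrix, one row per sample, one column per channel.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_ids Channel identifiers; default `ch1..chC` or the matrix
#'   column names.
#' @param labels Gesture labels: either one per sample (length `nrow(samples)`)
#'   or supplied later per window.
#' @return An object of class `recording`.
#' @export
recording <- function(samples, sampling_rate, channel_ids = NULL,
                      labels = NULL) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), ncol(samples) >= 1, nrow(samples) >= 1,
            sampling_rate > 0)
  if (is.null(channel_ids))
    channel_ids <- if (!is.null(colnames(samples))) colnames(samples)
                   else paste0("ch", seq_len(ncol(samples)))
  stopifnot(length(channel_ids) == ncol(samples))
  if (!is.null(labels) && length(labels) != nrow(samples))
    stop("per-sample labels must have one entry per sample")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_ids = as.character(channel_ids), labels = labels),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              nrow(x$samples) / x$sampling_rate))
  if (!is.null(x$labels))
    cat("  classes:", paste(levels(factor(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

window_starts <- function(n, spec) {
  if (n < spec$length) stop("recording shorter than one analysis window")
  seq.int(1L, n - spec$length + 1L, by = spec$step)
}

# Majority label of a label vector; ties go to the class occurring first.
majority_label <- function(lab) {
  tab <- table(factor(lab, levels = unique(lab)))
  names(tab)[which.max(tab)]
}

#' Slide analysis windows over a recording
#'
#' Cuts every channel into contiguous windows at stride `spec$step` and
#' attaches one gesture label per window. Per-sample labels are reduced by
#' majority vote (ties to the class occurring first in the window);
#' windows straddling a label transition can be discarded instead.
#'
#' @param rec A [recording()].
#' @param spec A [window_spec()].
#' @param window_labels Optional explicit per-window labels (overrides
#'   per-sample labels).
#' @param discard_transitions If `TRUE`, windows containing more than one
#'   per-sample label are dropped.
#' @return List with `windows` (list of L x C matrices), `labels`
#'   (one per window) and `starts` (first sample index of each window).
#' @export
windowize <- function(rec, spec = window_spec(), window_labels = NULL,
                      discard_transitions = FALSE) {
  stopifnot(inherits(rec, "recording"), inherits(spec, "window_spec"))
  starts <- window_starts(nrow(rec$samples), spec)
  labs <- NULL
  keep <- rep(TRUE, length(starts))
  if (!is.null(window_labels)) {
    if (length(window_labels) != length(starts))
      stop("window_labels must have one label per window (",
           length(starts), " windows)")
    labs <- as.character(window_labels)
  } else if (!is.null(rec$labels)) {
    labs <- character(length(starts))
    for (i in seq_along(starts)) {
      span <- rec$labels[starts[i]:(starts[i] + spec$length - 1L)]
      if (discard_transitions && length(unique(span)) > 1L) keep[i] <- FALSE
      labs[i] <- majority_label(span)
    }
  }
  starts <- starts[keep]
  if (!is.null(labs)) labs <- labs[keep]
  windows <- lapply(starts, function(s)
    rec$samples[s:(s + spec$length - 1L), , drop = FALSE])
  list(windows = windows, labels = labs, starts = starts)
}

#' Build the channel-feature variable matrix
#'
#' Extracts the eleven time-domain features for every channel of every
#' analysis window, producing the d x n variable matrix with
#' d = channels x features, rows in channel-major order
#' ((ch1, WL) ... (ch1, AR4), (ch2, WL), ...).
#'
#' @param rec A [recording()].
#' @param spec A [window_spec()].
#' @param standardize Z-score each row (variable). With a `train_mask`,
#'   means and SDs are estimated on the training windows only.
#' @param train_mask Optional logical vector over windows marking the
#'   training set used for standardization statistics.
#' @param degenerate One of `"drop"` (drop windows containing a
#'   zero-variance channel window, with a warning), `"error"`, or `"na"`
#'   (emit NA for the undefined features).
#' @param ... Passed to [windowize()].
#' @return Object of class `semg_features`: list with `values` (d x n),
#'   `row_index` (data.frame channel/feature), `col_labels`,
#'   `channel_ids`, `spec` and `standardization`.
#' @export
build_feature_matrix <- function(rec, spec = window_spec(),
                                 standardize = FALSE, train_mask = NULL,
                                 degenerate = c("drop", "error", "na"), ...) {
  degenerate <- match.arg(degenerate)
  w <- windowize(rec, spec, ...)
  C <- ncol(rec$samples)
  fn <- feature_names(spec$ar_order)
  nf <- length(fn)
  one_window <- function(mat) {
    out <- numeric(C * nf)
    for (ch in seq_len(C)) {
      v <- tryCatch(extract_window_features(mat[, ch], spec),
                    semgsel_degenerate_window = function(e) e)
      if (inherits(v, "condition")) {
        if (degenerate == "error") stop(v)
        if (degenerate == "drop") return(NULL)
        v <- rep(NA_real_, nf)
      }
      out[((ch - 1L) * nf + 1L):(ch * nf)] <- v
    }
    out
  }
  cols <- lapply(w$windows, one_window)
  kept <- !vapply(cols, is.null, logical(1))
  if (!all(kept))
    warning(sum(!kept), " degenerate (zero-variance) window(s) dropped")
  values <- do.call(cbind, cols[kept])
  row_index <- data.frame(
    channel = rep(rec$channel_ids, each = nf),
    feature = rep(fn, times = C),
    stringsAsFactors = FALSE)
  rownames(values) <- paste(row_index$channel, row_index$feature, sep = ":")
  fm <- structure(list(values = values, row_index = row_index,
                       col_labels = if (!is.null(w$labels)) w$labels[kept],
                       channel_ids = rec$channel_ids, spec = spec,
                       standardization = NULL),
                  class = "semg_features")
  if (standardize)
    fm <- standardize_features(fm, if (!is.null(train_mask)) train_mask[kept])
  fm
}

#' Z-score the rows of a feature matrix
#'
#' @param fm A `semg_features` object.
#' @param train_mask Optional logical mask over columns (windows); statistics
#'   are computed on the masked columns only and applied to all.
#' @return The feature matrix with standardized `values` and the per-row
#'   mean/scale recorded in `$standardization`. Zero-SD rows are left
#'   centred with scale 1.
#' @export
standardize_features <- function(fm, train_mask = NULL) {
  stopifnot(inherits(fm, "semg_features"))
  v <- fm$values
  ref <- if (is.null(train_mask)) v else v[, train_mask, drop = FALSE]
  mu <- rowMeans(ref)
  sdv <- apply(ref, 1, stats::sd)
  sdv[sdv == 0] <- 1
  fm$values <- (v - mu) / sdv
  fm$standardization <- data.frame(mean = mu, scale = sdv,
                                   row.names = rownames(v))
  fm
}

#' @export
print.semg_features <- function(x, ...) {
  cat(sprintf("semg_features: %d variables (%d channels x %d features) x %d windows\n",
              nrow(x$values), length(x$channel_ids),
              nrow(x$values) / length(x$channel_ids), ncol(x$values)))
  if (!is.null(x$col_labels))
    cat("  classes:", paste(levels(factor(x$col_labels)), collapse = ", "), "\n")
  if (!is.null(x$standardization)) cat("  rows standardized\n")
  invisible(x)
}

# Subset a feature matrix to given (channel, feature) rows.
subset_rows <- function(fm, channels = NULL, features = NULL, pairs = NULL) {
  idx <- fm$row_index
  keep <- rep(TRUE, nrow(idx))
  if (!is.null(channels)) keep <- keep & idx$channel %in% as.character(channels)
  if (!is.null(features)) keep <- keep & idx$feature %in% features
  if (!is.null(pairs))
    keep <- keep & paste(idx$channel, idx$feature) %in%
      paste(as.character(pairs$channel), pairs$feature)
  which(keep)
}
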
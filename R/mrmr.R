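#' Discretize a feature matrix for mutual-information estimation
#'
#' The default scheme codes each variable (row) into three states by
#' thresholds at mean +/- 0.5 SD: -1 below, 0 inside, +1 above — the
#' discretization conventional in mRMR practice. An equal-frequency
#' alternative bins each row into `bins` quantile classes.
#'
#' @param fm A `semg_features` matrix (or plain numeric matrix).
#' @param scheme `"meansd"` (default) or `"equalfreq"`.
#' @param alpha Half-width of the middle band in SD units (default 0.5).
#' @param bins Number of bins for the equal-frequency scheme.
#' @return Object of class `semg_disc`: integer `states` matrix of the same
#'   shape, the `scheme` descriptor, and per-row `alphabet_sizes`.
#'   Zero-variance rows map to the single state 0.
#' @export
discretize <- function(fm, scheme = c("meansd", "equalfreq"), alpha = 0.5,
                       bins = 3L) {
  scheme <- match.arg(scheme)
  v <- if (inherits(fm, "semg_features")) fm$values else as.matrix(fm)
  stopifnot(all(is.finite(v)))
  states <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    if (stats::sd(x) == 0) next  # constant row -> all state 0
    if (scheme == "meansd") {
      lo <- mean(x) - alpha * stats::sd(x)
      hi <- mean(x) + alpha * stats::sd(x)
      states[i, ] <- ifelse(x < lo, -1L, ifelse(x > hi, 1L, 0L))
    } else {
      qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
      states[i, ] <- as.integer(cut(x, breaks = qs, include.lowest = TRUE))
    }
  }
  structure(list(states = states,
                 scheme = list(method = scheme, alpha = alpha, bins = bins),
                 alphabet_sizes = apply(states, 1,
                                        function(r) length(unique(r)))),
            class = "semg_disc")
}

#' Plug-in mutual information of two discrete vectors
#'
#' I(A; B) = sum over observed cells of p(a,b) log2( p(a,b) / (p(a) p(b)) ),
#' with empirical frequencies; 0 log 0 terms contribute 0. Reported in bits.
#'
#' @param a,b Discrete vectors of equal length.
#' @return Non-negative scalar (up to floating-point rounding).
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  stopifnot(length(a) >= 1)
  n <- length(a)
  joint <- table(a, b) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(pa, pb)[nz]))
}

#' Rank variables by minimum-Redundancy Maximum-Relevance
#'
#' Greedy incremental mRMR over discretized variables: the first pick is
#' the variable with maximal mutual information with the class label; each
#' subsequent pick maximizes relevance minus the mean redundancy with the
#' already-selected set (MID, the difference criterion) or their ratio
#' (MIQ). Ties go to the lower variable index, making the ranking
#' deterministic.
#'
#' @param disc A `semg_disc` matrix (variables in rows).
#' @param labels Class label per column.
#' @param m Number of variables to rank (1 <= m <= d).
#' @param criterion `"mid"` (default) or `"miq"`.
#' @param row_index Optional data.frame with `channel`/`feature` columns
#'   naming the rows; required to return a proper variable set.
#' @return A [variable_set()] with `method = "mrmr"`, ordered by selection
#'   rank, with the criterion value as `score` and the selection order in
#'   attribute `order` (row indices).
#' @export
mrmr_rank <- function(disc, labels, m, criterion = c("mid", "miq"),
                      row_index = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(disc, "semg_disc"))
  S <- disc$states
  d <- nrow(S)
  if (m < 1 || m > d) stop("m must be between 1 and the number of variables")
  if (length(labels) != ncol(S)) stop("one label per sample required")
  rel <- vapply(seq_len(d), function(i) mutual_information(S[i, ], labels),
                numeric(1))
  selected <- integer(0)
  redsum <- numeric(d)  # running sum of I(x_j; x_i) over selected i
  scores <- numeric(m)
  for (step in seq_len(m)) {
    if (step == 1L) {
      crit <- rel
    } else {
      meanred <- redsum / (step - 1L)
      crit <- if (criterion == "mid") rel - meanred
              else rel / pmax(meanred, .Machine$double.eps)
    }
    crit[selected] <- -Inf
    pick <- which.max(crit)  # which.max takes the first (lowest index) tie
    scores[step] <- crit[pick]
    selected <- c(selected, pick)
    if (step < m)
      redsum <- redsum + vapply(seq_len(d), function(j)
        mutual_information(S[j, ], S[pick, ]), numeric(1))
  }
  if (is.null(row_index))
    row_index <- data.frame(channel = rep("ch1", d),
                            feature = as.character(seq_len(d)))
  vs <- variable_set(row_index$channel[selected], row_index$feature[selected],
                     method = "mrmr", score = scores)
  attr(vs, "order") <- selected
  vs
}
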
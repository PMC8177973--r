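#' Channel co-occurrence matrix of a variable set
#'
#' Counts, for every pair of channels, how many features the two channels
#' share in the selected variable set. The row sums measure how often each
#' channel is used jointly with the others and drive the channel ranking.
#'
#' @param sel A [variable_set()].
#' @param channel_ids The full ordered channel universe (so channels with
#'   no selected variables still appear with zero counts).
#' @return Object of class `semg_cooc`: integer `counts` (C x C, symmetric,
#'   zero diagonal), `row_sums`, `channel_ids`, `method`.
#' @export
cooccurrence <- function(sel, channel_ids) {
  stopifnot(inherits(sel, "semg_varset"))
  channel_ids <- as.character(channel_ids)
  if (!all(sel$channel %in% channel_ids))
    stop("variable set references channels outside `channel_ids`")
  C <- length(channel_ids)
  feats <- lapply(channel_ids, function(ch) sel$feature[sel$channel == ch])
  counts <- matrix(0L, C, C, dimnames = list(channel_ids, channel_ids))
  for (i in seq_len(C)) for (j in seq_len(C)) {
    if (i != j) counts[i, j] <- length(intersect(feats[[i]], feats[[j]]))
  }
  structure(list(counts = counts, row_sums = rowSums(counts),
                 channel_ids = channel_ids, method = attr(sel, "method")),
            class = "semg_cooc")
}

#' @export
print.semg_cooc <- function(x, ...) {
  cat(sprintf("semg_cooc (%s): %d channels; shared-feature counts\n",
              x$method, length(x$channel_ids)))
  m <- x$counts
  diag(m) <- NA
  print(rbind(m, Sum = x$row_sums), na.print = "-")
  invisible(x)
}

#' Rank channels by co-occurrence row sums
#'
#' Channels are ordered by descending row sum; ties share the best rank of
#' their block (competition ranking), so an order like 2 > 3 = 8 > 5 is
#' representable.
#'
#' @param coocc A `semg_cooc` matrix.
#' @return Object of class `semg_ranking`: data.frame `table` (channel,
#'   row_sum, rank, in descending order), `channel_ids`, `method`.
#' @export
rank_channels <- function(coocc) {
  stopifnot(inherits(coocc, "semg_cooc"))
  rs <- coocc$row_sums
  rank <- vapply(rs, function(s) 1L + sum(rs > s), integer(1))
  tab <- data.frame(channel = coocc$channel_ids, row_sum = as.integer(rs),
                    rank = rank, stringsAsFactors = FALSE)
  tab <- tab[order(tab$rank, tab$channel), ]
  rownames(tab) <- NULL
  structure(list(table = tab, channel_ids = coocc$channel_ids,
                 method = coocc$method),
            class = "semg_ranking")
}

#' Format a channel ranking as an order string
#'
#' @param x A `semg_ranking`.
#' @param ... Unused.
#' @return A string like `"2>3=8>5>7>1=4>6"`.
#' @export
format.semg_ranking <- function(x, ...) {
  tab <- x$table
  parts <- vapply(split(tab$channel, tab$rank),
                  paste, character(1), collapse = "=")
  paste(parts[order(as.integer(names(parts)))], collapse = ">")
}

#' @export
print.semg_ranking <- function(x, ...) {
  cat(sprintf("semg_ranking (%s): %s\n", x$method, format(x)))
  invisible(x)
}

#' Fuse two channel rankings into a channel subset
#'
#' Decision-level fusion of the MTSR and mRMR channel rankings.
#'
#' `mutual_top` (default): grow both top lists in lockstep — find the
#' smallest depth t at which the channels ranked within t by BOTH methods
#' number at least k — then keep the k intersection members with the
#' smallest rank-sum. `rank_sum` keeps the k channels with smallest
#' rank-sum directly (Borda-style). Ties are broken by larger combined
#' co-occurrence row sum, then lower channel id.
#'
#' @param rank_a,rank_b Two `semg_ranking` objects over the same channels.
#' @param k Number of channels to keep (1 <= k <= C).
#' @param strategy `"mutual_top"` (default) or `"rank_sum"`.
#' @return Object of class `semg_fusion`: `selected_channels` (in channel
#'   order), `strategy`, `k`, `depth` (the t used; NA for rank_sum) and an
#'   `audit` table of per-channel ranks, rank sums and combined row sums.
#' @export
fuse_rankings <- function(rank_a, rank_b, k,
                          strategy = c("mutual_top", "rank_sum")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(rank_a, "semg_ranking"), inherits(rank_b, "semg_ranking"))
  chans <- rank_a$channel_ids
  if (!setequal(chans, rank_b$channel_ids))
    stop("the two rankings cover different channel universes")
  C <- length(chans)
  if (k < 1 || k > C) stop("k must be between 1 and the number of channels")
  ra <- rank_a$table$rank[match(chans, rank_a$table$channel)]
  rb <- rank_b$table$rank[match(chans, rank_b$table$channel)]
  sa <- rank_a$table$row_sum[match(chans, rank_a$table$channel)]
  sb <- rank_b$table$row_sum[match(chans, rank_b$table$channel)]
  audit <- data.frame(channel = chans, rank_a = ra, rank_b = rb,
                      rank_sum = ra + rb, row_sum_total = sa + sb,
                      stringsAsFactors = FALSE)
  # tie order: rank_sum asc, combined row sum desc, channel id asc
  pref <- order(audit$rank_sum, -audit$row_sum_total, audit$channel)
  depth <- NA_integer_
  if (strategy == "mutual_top") {
    pool <- NULL
    for (t in seq_len(C)) {
      inter <- chans[ra <= t & rb <= t]
      if (length(inter) >= k) { pool <- inter; depth <- t; break }
    }
    keep <- audit$channel[pref][audit$channel[pref] %in% pool][seq_len(k)]
  } else {
    keep <- audit$channel[pref][seq_len(k)]
  }
  structure(list(selected_channels = chans[chans %in% keep],
                 strategy = strategy, k = k, depth = depth, audit = audit),
            class = "semg_fusion")
}

#' @export
print.semg_fusion <- function(x, ...) {
  cat(sprintf("semg_fusion (%s, k = %d): channels {%s}\n", x$strategy, x$k,
              paste(x$selected_channels, collapse = ", ")))
  invisible(x)
}

#' Features shared by a majority of channels
#'
#' For each screening method, keeps the features used by strictly more than
#' half of the channels (e.g. > 4 of 8), and reports the union across the
#' two methods — the feature list fed to the final classifier.
#'
#' @param sel_a,sel_b Variable sets from the two screening methods.
#' @param n_channels Size of the channel universe C.
#' @param all_features Optional feature ordering for the output lists
#'   (defaults to first-appearance order).
#' @return List with per-method feature vectors (named by each set's
#'   method tag), `union`, and a `counts` table of channels-per-feature.
#' @export
select_features_by_majority <- function(sel_a, sel_b, n_channels,
                                        all_features = NULL) {
  stopifnot(inherits(sel_a, "semg_varset"), inherits(sel_b, "semg_varset"))
  count_one <- function(sel) {
    tab <- tapply(sel$channel, sel$feature,
                  function(ch) length(unique(ch)))
    feats <- if (is.null(all_features)) unique(c(sel_a$feature, sel_b$feature))
             else all_features
    out <- stats::setNames(integer(length(feats)), feats)
    out[names(tab)] <- as.integer(tab)
    out
  }
  ca <- count_one(sel_a)
  cb <- count_one(sel_b)
  keep_a <- names(ca)[ca > n_channels / 2]
  keep_b <- names(cb)[cb > n_channels / 2]
  out <- list(keep_a, keep_b)
  names(out) <- c(attr(sel_a, "method"), attr(sel_b, "method"))
  out$union <- union(keep_a, keep_b)
  out$counts <- data.frame(feature = names(ca), a = as.integer(ca),
                           b = as.integer(cb[names(ca)]),
                           stringsAsFactors = FALSE)
  names(out$counts)[2:3] <- c(attr(sel_a, "method"), attr(sel_b, "method"))
  out
}
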
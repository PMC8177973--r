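#' Read / write a multichannel recording as CSV
#'
#' One row per sample, one column per channel (header row names the
#' channels), with an optional final `label` column carrying per-sample
#' gesture labels.
#'
#' @param path CSV file.
#' @param sampling_rate Sampling rate in Hz of the stored signal.
#' @return A [recording()].
#' @export
read_recording <- function(path, sampling_rate) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.character(df$label)
    df$label <- NULL
  }
  recording(as.matrix(df), sampling_rate, channel_ids = names(df),
            labels = labels)
}

#' @rdname read_recording
#' @param rec A [recording()] to write.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  df <- as.data.frame(rec$samples)
  names(df) <- rec$channel_ids
  if (!is.null(rec$labels)) df$label <- rec$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a feature matrix as TSV with a JSON sidecar
#'
#' The TSV carries one row per channel-feature variable, indexed
#' `channel:feature`, one column per window, plus a first `label` row with
#' the window labels. The sidecar (`<path>.json`) records the window spec
#' and any standardization statistics.
#'
#' @param fm A `semg_features` object.
#' @param path TSV file.
#' @return `read_feature_matrix` returns the restored `semg_features`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "semg_features"))
  df <- as.data.frame(fm$values)
  names(df) <- paste0("w", seq_len(ncol(fm$values)))
  out <- rbind(as.data.frame(as.list(stats::setNames(
    as.character(fm$col_labels), names(df))), check.names = FALSE), df)
  rownames(out) <- c("label", rownames(fm$values))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  side <- list(spec = unclass(fm$spec), channel_ids = fm$channel_ids,
               standardization = fm$standardization)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, colClasses = "character")
  labels <- as.character(raw["label", ])
  vals <- as.matrix(raw[-1, , drop = FALSE])
  storage.mode(vals) <- "double"
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  idx <- do.call(rbind, strsplit(rownames(vals), ":", fixed = TRUE))
  spec <- window_spec(length = side$spec$length, step = side$spec$step,
                      zc_threshold = side$spec$zc_threshold,
                      ar_order = side$spec$ar_order,
                      ar_method = side$spec$ar_method)
  std <- NULL
  if (!is.null(side$standardization) && length(side$standardization))
    std <- as.data.frame(side$standardization)
  structure(list(values = vals,
                 row_index = data.frame(channel = idx[, 1], feature = idx[, 2],
                                        stringsAsFactors = FALSE),
                 col_labels = labels, channel_ids = side$channel_ids,
                 spec = spec, standardization = std),
            class = "semg_features")
}

#' Read / write a variable set as TSV
#'
#' Columns: rank, channel, feature, and score when present; the method tag
#' is stored in a `# method:` header comment.
#'
#' @param vs A [variable_set()].
#' @param path TSV file.
#' @return `read_variable_set` returns the restored [variable_set()].
#' @export
write_variable_set <- function(vs, path) {
  stopifnot(inherits(vs, "semg_varset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method: ", attr(vs, "method")), con)
  df <- data.frame(rank = seq_len(nrow(vs)), as.data.frame(vs))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variable_set
#' @export
read_variable_set <- function(path) {
  first <- readLines(path, n = 1)
  method <- sub("^# method: *", "", first)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          colClasses = c(channel = "character"))
  variable_set(df$channel, df$feature, method = method,
               score = if ("score" %in% names(df)) df$score)
}

#' Write a co-occurrence matrix as TSV (counts plus Sum row)
#'
#' @param coocc A `semg_cooc`.
#' @param path TSV file.
#' @export
write_cooccurrence <- function(coocc, path) {
  stopifnot(inherits(coocc, "semg_cooc"))
  m <- rbind(coocc$counts, Sum = coocc$row_sums)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Run the full channel-selection pipeline to a directory
#'
#' Executes feature extraction, both variable screens, fusion,
#' majority-feature selection and evaluation on a recording (from file or
#' in memory), writing every intermediate artifact plus a JSON manifest
#' (configuration, seed, package version) to `out_dir`. Re-running with
#' the same configuration and seed reproduces identical outputs.
#'
#' @param rec A [recording()], or `NULL` to read `input` / simulate.
#' @param out_dir Output directory (created if missing).
#' @param input Path of a recording CSV (used when `rec` is `NULL`).
#' @param sampling_rate Sampling rate for `input`.
#' @param sim A [sim_config()] to simulate from when neither `rec` nor
#'   `input` is given.
#' @param seed Seed for simulation, folds and any other randomness.
#' @param ... Passed on to [semg_select()].
#' @return The `semg_select` fit, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_pipeline <- function(rec = NULL, out_dir, input = NULL,
                         sampling_rate = NULL, sim = NULL, seed = 1L, ...) {
  if (is.null(rec)) {
    rec <- if (!is.null(input)) {
      if (is.null(sampling_rate)) stop("sampling_rate required with `input`")
      read_recording(input, sampling_rate)
    } else if (!is.null(sim)) generate_recording(sim, seed = seed)
    else stop("provide `rec`, `input` or `sim`")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- semg_select(rec, seed = seed, ...)
  write_feature_matrix(fit$features, file.path(out_dir, "features.tsv"))
  write_variable_set(fit$varset_mtsr, file.path(out_dir, "mtsr_vars.tsv"))
  write_variable_set(fit$varset_mrmr, file.path(out_dir, "mrmr_vars.tsv"))
  write_cooccurrence(fit$cooc_mtsr, file.path(out_dir, "cooc_mtsr.tsv"))
  write_cooccurrence(fit$cooc_mrmr, file.path(out_dir, "cooc_mrmr.tsv"))
  result <- list(
    selected_channels = fit$fusion$selected_channels,
    strategy = fit$fusion$strategy, k = fit$fusion$k,
    order_mtsr = format(fit$ranking_mtsr),
    order_mrmr = format(fit$ranking_mrmr),
    majority_features = fit$majority_features[
      setdiff(names(fit$majority_features), "counts")],
    lambda = fit$lambda)
  jsonlite::write_json(result, file.path(out_dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(fit$evaluation))
    write_eval_report(fit$evaluation, file.path(out_dir, "evaluation.json"))
  args <- list(...)
  manifest <- list(
    package = "semgsel",
    version = as.character(utils::packageVersion("semgsel")),
    seed = seed,
    config = args[!vapply(args, is.function, logical(1))],
    files = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(fit)
}
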
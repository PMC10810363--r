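#' Dataset loading and result serialization
#'
#' Feature matrices arrive as delimited text (CSV/TSV), samples as rows
#' with a header of feature names and the first column holding sample ids;
#' a `--transpose` style flag accommodates genes-as-rows matrices. Empty
#' cells and `"NA"` are read as missing by default. Evaluation results are
#' serialized to `evaluation.json` (full record set), `summaries.csv`
#' (size x slice x metric summaries) and `models.csv` (one row per fitted
#' model); all indices in serialized outputs are 1-based.
#'
#' @name io
NULL

#' Load a dataset from delimited text
#'
#' @param features_path Path to a CSV/TSV file: header = feature names,
#'   first column = sample id, one sample per row.
#' @param response Either the name of a column of the features file to use
#'   (and remove from) the matrix, or the path of a one-column (optionally
#'   headered) response file aligned with the samples.
#' @param task `"classification"`, `"regression"`, or `NULL` to infer from
#'   the response type.
#' @param strata_column Optional name of a column holding stratum labels
#'   (removed from the matrix).
#' @param missing_codes Strings read as missing (default empty and "NA").
#' @param transpose Set when the file is features-as-rows.
#' @return An `ml_dataset`.
#' @export
load_dataset <- function(features_path, response, task = NULL,
                         strata_column = NULL,
                         missing_codes = c("", "NA"), transpose = FALSE) {
  dt <- data.table::fread(features_path, na.strings = missing_codes,
                          header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1L]])
  dt <- dt[, -1L, drop = FALSE]
  if (transpose) {
    feat_names <- ids
    m <- t(as.matrix(dt))
    ids <- colnames(dt)
    dimnames(m) <- list(ids, feat_names)
    dt <- as.data.frame(m)
  }
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", features_path)

  strata <- NULL
  if (!is.null(strata_column)) {
    if (!strata_column %in% names(dt))
      stop("strata column '", strata_column, "' not found")
    strata <- as.character(dt[[strata_column]])
    dt[[strata_column]] <- NULL
  }

  if (length(response) == 1L && response %in% names(dt)) {
    y <- dt[[response]]
    dt[[response]] <- NULL
  } else if (length(response) == 1L && file.exists(response)) {
    rdt <- data.table::fread(response, na.strings = missing_codes,
                             data.table = FALSE)
    y <- rdt[[ncol(rdt)]]
    if (length(y) != nrow(dt))
      stop("response length (", length(y), ") does not match the number of ",
           "samples (", nrow(dt), ")")
  } else {
    stop("response '", response, "' is neither a column of the features ",
         "file nor an existing file")
  }

  non_num <- !vapply(dt, is.numeric, logical(1))
  if (any(non_num))
    stop("non-numeric feature column(s): ",
         paste(utils::head(names(dt)[non_num], 5L), collapse = ", "))
  X <- as.matrix(dt)
  rownames(X) <- ids
  ds <- dataset(X, y, strata = strata, task = task)
  message("loaded ", nrow(X), " samples x ", ncol(X), " features; missing ",
          "fraction ", signif(mean(is.na(X)), 3),
          if (ds$task == "classification")
            paste0("; classes: ",
                   paste(names(table(ds$y)), table(ds$y), sep = "=",
                         collapse = ", ")) else "")
  ds
}

#' Write a dataset as CSV (features + response column)
#'
#' @param ds An `ml_dataset`.
#' @param path Output CSV path; the response is stored in a `.response`
#'   column, strata in `.strata`.
#' @export
write_dataset <- function(ds, path) {
  df <- data.frame(sample_id = rownames(ds$X), ds$X, check.names = FALSE)
  df$.response <- ds$y
  if (!is.null(ds$strata)) df$.strata <- ds$strata
  # format doubles at 17 significant digits so the written text parses back
  # to the exact same binary values
  for (nm in names(df))
    if (is.double(df[[nm]]))
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA_character_,
                         formatC(df[[nm]], digits = 17, format = "g"))
  data.table::fwrite(df, path)
  invisible(path)
}

strip_record <- function(r) {
  r$model <- NULL
  r
}

#' Serialize an evaluation
#'
#' Writes `evaluation.json` (the full `method_evaluation`, fitted model
#' objects excluded), `summaries.csv` and `models.csv` into `dir`. Output
#' is a pure function of the evaluation object, hence byte-identical across
#' runs and worker counts.
#'
#' @param ev A `method_evaluation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_evaluation <- function(ev, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- unclass(ev)
  out$records <- lapply(out$records, strip_record)
  if (!is.null(out$best)) out$best <- strip_record(out$best)
  out$best_model <- NULL
  out$learner <- unclass(out$learner)
  if (!is.null(out$screening)) out$screening <- unclass(out$screening)
  json_path <- file.path(dir, "evaluation.json")
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  sum_path <- file.path(dir, "summaries.csv")
  utils::write.csv(ev$summaries, sum_path, row.names = FALSE)
  mod_path <- file.path(dir, "models.csv")
  utils::write.csv(models_table(ev), mod_path, row.names = FALSE)
  invisible(c(json_path, sum_path, mod_path))
}

#' One-row-per-model table of an evaluation
#' @param ev A `method_evaluation`.
#' @return A data.frame with size, repeat, configuration, screened count
#'   and train/test/full scores.
#' @export
models_table <- function(ev) {
  do.call(rbind, lapply(ev$records, function(r) {
    if (isTRUE(r$failed))
      return(data.frame(size_index = r$size_index, size = r$size,
                        repeat_id = r$repeat_id, configuration = NA,
                        n_screened = NA, train_score = NA, test_score = NA,
                        full_score = NA, failed = TRUE))
    data.frame(size_index = r$size_index, size = r$size,
               repeat_id = r$repeat_id,
               configuration = paste(names(r$configuration),
                                     unlist(r$configuration), sep = "=",
                                     collapse = ";"),
               n_screened = r$n_screened, train_score = r$train_score,
               test_score = r$test_score, full_score = r$full_score,
               failed = FALSE)
  }))
}

#' Read back a serialized evaluation
#'
#' Reconstructs a `method_evaluation` from `evaluation.json` with enough
#' fidelity to regenerate reports and importance tables (fitted model
#' objects are not serialized).
#'
#' @param path Path to `evaluation.json`.
#' @return A `method_evaluation`.
#' @export
read_evaluation <- function(path) {
  ev <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  null_to_na <- function(x) if (is.null(x)) NA else x
  row_tbl <- function(rows) {
    do.call(rbind, lapply(rows, function(r)
      tibble::as_tibble(lapply(r, null_to_na))))
  }
  ev$summaries <- row_tbl(ev$summaries)
  ev$sizes <- as.integer(unlist(ev$sizes))
  ev$feature_names <- unlist(ev$feature_names)
  ev$records <- lapply(ev$records, function(r) {
    for (f in c("presence", "sign", "stability", "train_idx",
                "held_out_idx", "selected_features",
                "tuning_split_digests"))
      if (!is.null(r[[f]])) r[[f]] <- unlist(r[[f]])
    # JSON arrays carry no names; per-feature vectors span the full
    # feature space in order
    for (f in c("presence", "sign", "stability"))
      if (!is.null(r[[f]]) && length(r[[f]]) == length(ev$feature_names))
        names(r[[f]]) <- ev$feature_names
    for (f in c("train_score", "test_score", "full_score"))
      r[[f]] <- null_to_na(unlist(r[[f]]))
    r$failed <- isTRUE(r$failed)
    r
  })
  if (!is.null(ev$best)) {
    for (f in c("presence", "sign", "stability"))
      if (!is.null(ev$best[[f]])) ev$best[[f]] <- unlist(ev$best[[f]])
  }
  structure(ev, class = "method_evaluation")
}
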
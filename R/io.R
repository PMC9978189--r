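#' Read an ROI time-series file
#'
#' Expects delimited text (tab, comma or whitespace) with a header row of
#' ROI names and one row per time point, and returns the column-standardized
#' matrix ready for the estimators.
#'
#' @param path File path.
#' @param sep Field separator; `""` (default) autodetects tab/comma/space
#'   from the header line.
#' @param ... Passed to [standardize_timeseries()] (e.g. `on_constant`).
#' @return Standardized `fbn_timeseries` matrix with ROI column names.
#' @export
read_timeseries <- function(path, sep = "", ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (sep == "") {
    header <- readLines(path, n = 1)
    sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  }
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(df) == 0) stop("no data rows in ", path, call. = FALSE)
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) {
    col <- bad[1]
    row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
    stop(sprintf("non-numeric value in %s at column '%s' (column %d), data row %s",
                 path, names(df)[col], col,
                 ifelse(is.na(row), "?", row)), call. = FALSE)
  }
  standardize_timeseries(as.matrix(df), ...)
}

#' Write a network as TSV with a JSON metadata sidecar
#'
#' The matrix is written with 10 significant digits (round-trip error well
#' below every analysis tolerance) with ROI names as the header; estimator
#' name, hyperparameters and the observed module count go to `<path>.json`.
#'
#' @param W Adjacency matrix.
#' @param path Output TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @param roi_names ROI names (defaults to `colnames(W)` or `ROI1..`).
#' @param meta Named list of metadata (estimator, hyperparameters, ...).
#'   `k_observed` is filled in from [connected_components()] when absent and
#'   `W` is nonnegative.
#' @return `path`, invisibly.
#' @export
write_network <- function(W, path, roi_names = NULL, meta = list()) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (is.null(roi_names)) roi_names <- colnames(W) %||% paste0("ROI", seq_len(ncol(W)))
  if (length(roi_names) != ncol(W)) {
    stop("`roi_names` has length ", length(roi_names), ", need ", ncol(W),
         call. = FALSE)
  }
  if (is.null(meta$k_observed) && min(W) >= 0) {
    meta$k_observed <- connected_components(W)$k_observed
  }
  out <- matrix(format(W, digits = 10, trim = TRUE, scientific = NA),
                nrow(W), dimnames = list(NULL, roi_names))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    TRUE
  }, error = function(e) {
    stop("failed writing network to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path TSV path.
#' @return Adjacency matrix with ROI dimnames; the parsed JSON sidecar, if
#'   present, is attached as attribute `"meta"`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  W <- as.matrix(df)
  dimnames(W) <- list(colnames(df), colnames(df))
  side <- paste0(path, ".json")
  if (file.exists(side)) attr(W, "meta") <- jsonlite::read_json(side)
  W
}

#' Read a cohort manifest CSV
#'
#' Columns `scan_id`, `subject_id`, `label` (0/1) and `path` (time-series
#' files, resolved relative to the manifest's directory when not absolute).
#'
#' @param path Manifest CSV path.
#' @return Validated manifest data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(mf)
  if (!is.null(mf$path)) {
    rel <- !grepl("^(/|[A-Za-z]:)", mf$path)
    mf$path[rel] <- file.path(dirname(path), mf$path[rel])
  }
  mf
}

#' Read / write a run configuration
#'
#' YAML round-trip of the settings a pipeline run resolves to (method,
#' hyperparameters, CV protocol, seed), so every run can record its exact
#' configuration next to its outputs.
#'
#' @param path YAML file path.
#' @param config Named list.
#' @return `read_run_config`: the named list; `write_run_config`: `path`,
#'   invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Parse a `2^a..2^b` penalty-grid range
#'
#' The hyperparameter grids of the evaluation protocol are log2-spaced;
#' `"2^-5..2^5"` expands to the 11 values `2^-5, 2^-4, ..., 2^5`. Plain
#' comma-separated numbers are also accepted.
#'
#' @param text Grid specification string.
#' @return Numeric vector.
#' @export
parse_grid <- function(text) {
  text <- gsub("\\s", "", text)
  m <- regmatches(text, regexec("^2\\^(-?\\d+)\\.\\.2\\^(-?\\d+)$", text))[[1]]
  if (length(m) == 3) {
    a <- as.integer(m[2]); b <- as.integer(m[3])
    return(2^seq(min(a, b), max(a, b)))
  }
  out <- suppressWarnings(as.numeric(strsplit(text, ",")[[1]]))
  if (anyNA(out)) stop("cannot parse grid '", text,
                       "'; use e.g. 2^-5..2^5 or 0.1,0.2", call. = FALSE)
  out
}
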
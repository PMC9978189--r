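#' Column-standardize an ROI time-series matrix
#'
#' Centers every ROI signal (column) to mean zero and rescales it to unit
#' Euclidean norm, the normalization under which the inner product of two
#' columns equals their Pearson correlation. Estimators call this on their
#' input, so they accept either raw or already-standardized matrices
#' (standardization is idempotent).
#'
#' @param X Numeric matrix, `m` time points x `n` ROIs, `m >= 2`, `n >= 2`.
#' @param on_constant What to do with zero-variance (constant) columns:
#'   `"error"` (default) aborts naming the offending ROIs; `"drop"` removes
#'   them, recording their names in attribute `"dropped_rois"` and emitting a
#'   message.
#' @return The standardized matrix with class `"fbn_timeseries"` prepended;
#'   column names are preserved (ROIs are named `ROI1..ROIn` when absent).
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' S <- standardize_timeseries(X)
#' colSums(S)            # ~0
#' colSums(S^2)          # ~1
#' @export
standardize_timeseries <- function(X, on_constant = c("error", "drop")) {
  on_constant <- match.arg(on_constant)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("time series must be a numeric matrix (rows = time points, columns = ROIs)",
         call. = FALSE)
  }
  if (nrow(X) < 2 || ncol(X) < 2) {
    stop("time series needs at least 2 time points and 2 ROIs; got ",
         nrow(X), " x ", ncol(X), call. = FALSE)
  }
  if (anyNA(X)) stop("time series contains missing values", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("ROI", seq_len(ncol(X)))

  Xc <- sweep(X, 2, colMeans(X), "-")
  nrm <- sqrt(colSums(Xc^2))
  const <- nrm < 1e-12 * max(1, max(abs(X)))
  if (any(const)) {
    bad <- colnames(X)[const]
    if (on_constant == "error") {
      stop("constant (zero-variance) ROI column(s): ",
           paste(bad, collapse = ", "),
           "; use on_constant = \"drop\" to remove them", call. = FALSE)
    }
    message("dropping constant ROI column(s): ", paste(bad, collapse = ", "))
    Xc <- Xc[, !const, drop = FALSE]
    nrm <- nrm[!const]
    if (ncol(Xc) < 2) stop("fewer than 2 ROIs remain after dropping constants",
                           call. = FALSE)
  }
  out <- sweep(Xc, 2, nrm, "/")
  if (any(const)) attr(out, "dropped_rois") <- colnames(X)[const]
  class(out) <- c("fbn_timeseries", class(out))
  out
}

# internal: standardize unless already done
as_timeseries <- function(X, ...) {
  if (inherits(X, "fbn_timeseries")) X else standardize_timeseries(X, ...)
}
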
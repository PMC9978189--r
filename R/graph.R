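#' Validate an adjacency matrix
#'
#' Checks the contract shared by all network estimators: a square, symmetric,
#' real matrix with zero diagonal, optionally constrained to be nonnegative.
#' Symmetry is required to within `1e-10` in absolute value.
#'
#' @param W Square numeric matrix of edge weights.
#' @param nonnegative If `TRUE`, additionally require all entries `>= 0`.
#' @param arg Name used in error messages.
#' @return `W`, invisibly, with its diagonal zeroed.
#' @keywords internal
check_adjacency <- function(W, nonnegative = FALSE, arg = "W") {
  if (!is.matrix(W) || !is.numeric(W) || nrow(W) != ncol(W)) {
    stop(sprintf("`%s` must be a square numeric matrix", arg), call. = FALSE)
  }
  if (anyNA(W)) {
    stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  }
  asym <- max(abs(W - t(W)))
  if (asym > 1e-10) {
    stop(sprintf("`%s` is not symmetric (max |W - t(W)| = %.3g)", arg, asym),
         call. = FALSE)
  }
  if (nonnegative && min(W) < 0) {
    stop(sprintf("`%s` must be nonnegative (min entry %.3g)", arg, min(W)),
         call. = FALSE)
  }
  diag(W) <- 0
  invisible(W)
}

#' Graph Laplacian of a weighted network
#'
#' Builds the combinatorial Laplacian `L = D - W` (with `D` the diagonal
#' degree matrix) or the symmetric normalized Laplacian
#' `I - D^(-1/2) W D^(-1/2)`. Zero-degree (isolated) nodes use the convention
#' `d^(-1/2) = 0`, so in normalized form an isolated node contributes a
#' diagonal 1.
#'
#' @param W Symmetric nonnegative adjacency matrix (self-loops are ignored:
#'   the diagonal is zeroed before constructing the Laplacian).
#' @param normalized Build the symmetric normalized Laplacian? Default `FALSE`.
#' @return An `n x n` symmetric positive semi-definite matrix with attribute
#'   `"normalized"` recording which form was built.
#' @examples
#' W <- matrix(c(0, 1, 1, 0), 2, 2)
#' build_laplacian(W)  # [[1, -1], [-1, 1]]
#' @export
build_laplacian <- function(W, normalized = FALSE) {
  W <- check_adjacency(W, nonnegative = TRUE)
  d <- rowSums(W)
  if (!normalized) {
    L <- diag(d, nrow(W)) - W
  } else {
    dis <- ifelse(d > 0, 1 / sqrt(d), 0)
    L <- diag(nrow(W)) - (dis * W) * rep(dis, each = nrow(W))
  }
  L <- (L + t(L)) / 2  # kill round-off asymmetry
  attr(L, "normalized") <- normalized
  L
}

#' Eigendecomposition of a (Laplacian) matrix, ascending
#'
#' Full symmetric eigendecomposition with eigenvalues sorted ascending, the
#' order in which Laplacian spectra are read (smallest eigenvalues first).
#' When eigenvalues are degenerate any orthonormal basis of the invariant
#' subspace may be returned; downstream code must compare subspaces, not
#' individual eigenvectors.
#'
#' @param L Symmetric matrix (typically from [build_laplacian()]).
#' @param k Optional truncation: keep only the `k` smallest-eigenvalue
#'   eigenvectors (all eigenvalues are always returned). Must satisfy
#'   `k <= n`.
#' @return Object of class `"laplacian_spectrum"`: a list with `values`
#'   (length `n`, ascending), `vectors` (`n x k` orthonormal columns, or
#'   `n x n` when `k` is `NULL`), and `normalized` (flag carried over from
#'   the input, `NA` if absent).
#' @export
laplacian_spectrum <- function(L, k = NULL) {
  stopifnot(is.matrix(L), nrow(L) == ncol(L))
  n <- nrow(L)
  if (!is.null(k)) {
    if (k < 1 || k > n) stop("`k` must be between 1 and n = ", n, call. = FALSE)
  }
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- seq(n, 1)  # eigen() returns decreasing order
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  if (!is.null(k)) vectors <- vectors[, seq_len(k), drop = FALSE]
  structure(
    list(values = values, vectors = vectors,
         normalized = attr(L, "normalized") %||% NA),
    class = "laplacian_spectrum"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multiplicity of the (numerically) zero eigenvalue
#'
#' Counts eigenvalues below `tol`. For the Laplacian of a graph whose nodes
#' all have positive degree this equals the number of connected components.
#'
#' @param s A `"laplacian_spectrum"`, or a numeric vector of eigenvalues.
#' @param tol Positive absolute tolerance; default `1e-8`, chosen for the
#'   normalized Laplacian whose spectrum lies in `[0, 2]`.
#' @return Integer count.
#' @export
count_zero_eigenvalues <- function(s, tol = 1e-8) {
  stopifnot(tol > 0)
  values <- if (inherits(s, "laplacian_spectrum")) s$values else as.numeric(s)
  sum(values < tol)
}

#' Connected components of a weighted graph
#'
#' Two nodes are connected when joined by a path of edges with weight above
#' `edge_tol`. Labels are 0-based and contiguous in order of first
#' appearance.
#'
#' @param W Symmetric nonnegative adjacency matrix.
#' @param edge_tol Weights at or below this threshold are treated as absent
#'   edges. Default `1e-10`.
#' @return Object of class `"module_partition"`: list with `labels`
#'   (length-`n` integer vector, 0-based) and `k_observed` (number of
#'   components).
#' @export
connected_components <- function(W, edge_tol = 1e-10) {
  W <- check_adjacency(W, nonnegative = TRUE)
  A <- (W > edge_tol) * 1
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  memb <- igraph::components(g)$membership
  # relabel to 0-based, contiguous, in first-appearance order
  labels <- match(memb, unique(memb)) - 1L
  structure(list(labels = as.integer(labels),
                 k_observed = length(unique(labels))),
            class = "module_partition")
}

#' Component count via the Laplacian spectrum
#'
#' Spectral counterpart of [connected_components()]: the multiplicity of the
#' zero Laplacian eigenvalue. Under the normalized Laplacian an isolated node
#' sits at eigenvalue 1 rather than 0 (its diagonal entry is 1 by the
#' `d^(-1/2) = 0` convention), so zero-degree nodes are added back to the
#' count; each is its own component.
#'
#' @inheritParams build_laplacian
#' @param tol Zero-eigenvalue tolerance, see [count_zero_eigenvalues()].
#' @param spectrum Optional precomputed `"laplacian_spectrum"` of
#'   `build_laplacian(W, normalized)`, to avoid recomputing it.
#' @return Integer component count.
#' @export
spectral_component_count <- function(W, normalized = FALSE, tol = 1e-8,
                                     spectrum = NULL) {
  W <- check_adjacency(W, nonnegative = TRUE)
  if (is.null(spectrum)) {
    spectrum <- laplacian_spectrum(build_laplacian(W, normalized))
  }
  z <- count_zero_eigenvalues(spectrum, tol)
  if (normalized) z <- z + sum(rowSums(W) == 0)
  z
}

#' Squared Euclidean distances between matrix rows
#'
#' Entry `(i, j)` is `||f_i - f_j||^2` for rows `f_i`, `f_j` of `F`. This is
#' the pairwise-distance term coupling the spectral embedding to the edge
#' weights in the module-constrained estimator.
#'
#' @param F_mat Numeric matrix with `n` rows.
#' @return `n x n` symmetric nonnegative matrix with zero diagonal.
#' @export
pairwise_rowdistance_matrix <- function(F_mat) {
  stopifnot(is.matrix(F_mat), is.numeric(F_mat))
  sq <- rowSums(F_mat^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(F_mat)
  D[D < 0] <- 0  # round-off
  diag(D) <- 0
  (D + t(D)) / 2
}
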
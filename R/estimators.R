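#' Pearson correlation network
#'
#' The simplest functional-connectivity estimator: edge weights are the
#' sample Pearson correlations between ROI signals, `W = X^T X` for a
#' column-standardized time-series matrix. The diagonal (self-correlation)
#' is zeroed — self-loops carry no information and would distort node
#' degrees.
#'
#' @param X Time-series matrix (`m` time points x `n` ROIs), raw or
#'   standardized; see [standardize_timeseries()].
#' @param ... Passed to [standardize_timeseries()] (e.g. `on_constant`).
#' @return Symmetric `n x n` adjacency matrix with entries in `[-1, 1]` and
#'   zero diagonal.
#' @export
pearson_network <- function(X, ...) {
  X <- as_timeseries(X, ...)
  W <- crossprod(X)
  W[W > 1] <- 1
  W[W < -1] <- -1
  diag(W) <- 0
  (W + t(W)) / 2
}

#' Drop negative edges from a network
#'
#' Elementwise `max(W, 0)`: the "+" variant applied to estimators whose
#' output may contain negative weights. Symmetry and the zero diagonal are
#' preserved.
#'
#' @param W Symmetric adjacency matrix.
#' @return Nonnegative adjacency matrix.
#' @export
remove_negative_edges <- function(W) {
  W <- check_adjacency(W)
  pmax(W, 0)
}

#' l1-sparsified correlation network
#'
#' Regression form (the default): minimizes
#' `||X - XW||_F^2 + lam * ||W||_1` with the diagonal of `W` constrained to
#' zero, solved column by column as a lasso of each ROI signal on all the
#' others, then symmetrized as `(W + W^T)/2`. The zero-diagonal constraint
#' is essential — without it `W = I` is a trivial near-minimizer.
#'
#' The `"soft_threshold"` variant instead minimizes
#' `||W - X^T X||_F^2 + lam * ||W||_1`, whose closed-form solution
#' soft-thresholds the correlation matrix at `lam / 2`.
#'
#' @inheritParams pearson_network
#' @param lam Nonnegative sparsity weight; large values give the empty
#'   network.
#' @param variant `"regression"` (default) or `"soft_threshold"`.
#' @param thresh Coordinate-descent convergence threshold passed to
#'   [glmnet::glmnet()].
#' @return Symmetric adjacency matrix with zero diagonal.
#' @export
sparse_pc_network <- function(X, lam, variant = c("regression", "soft_threshold"),
                              thresh = 1e-12, ...) {
  variant <- match.arg(variant)
  if (lam < 0) stop("`lam` must be nonnegative", call. = FALSE)
  X <- as_timeseries(X, ...)
  n <- ncol(X)

  if (variant == "soft_threshold") {
    A <- pearson_network(X)
    W <- sign(A) * pmax(abs(A) - lam / 2, 0)
    diag(W) <- 0
    return(W)
  }

  m <- nrow(X)
  W <- matrix(0, n, n, dimnames = list(colnames(X), colnames(X)))
  for (j in seq_len(n)) {
    W[-j, j] <- lasso_column(X[, -j, drop = FALSE], X[, j], lam, thresh)
  }
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# min_w ||y - B w||^2 + lam ||w||_1 for one ROI column.
# glmnet's gaussian objective is 1/(2m) RSS + lambda ||w||_1, hence the
# lam / (2m) rescaling. Ridge-free edge cases are solved directly.
lasso_column <- function(B, y, lam, thresh = 1e-12) {
  p <- ncol(B)
  if (p == 1) {  # univariate soft threshold, closed form
    bty <- sum(B * y)
    btb <- sum(B^2)
    return(sign(bty) * pmax(abs(bty) - lam / 2, 0) / btb)
  }
  if (lam == 0) {
    fit <- stats::lm.fit(B, y)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    return(unname(co))
  }
  m <- length(y)
  lam_g <- lam / (2 * m)
  path <- lam_g * c(16, 8, 4, 2, 1)
  fit <- glmnet::glmnet(B, y, family = "gaussian", lambda = path,
                        standardize = FALSE, intercept = FALSE,
                        thresh = thresh, maxit = 1e7)
  as.numeric(stats::coef(fit, s = lam_g))[-1]  # drop (zero) intercept
}

#' Sparse plus low-rank correlation network (M-PC)
#'
#' Minimizes `||X - XW||_F^2 + lam1 ||W||_1 + lam2 ||W||_*` (trace norm,
#' the convex surrogate for rank), with the diagonal of `W` constrained to
#' zero, by ADMM with separate proximal steps for the two penalties:
#' elementwise soft-thresholding for the l1 term and singular-value
#' soft-thresholding for the trace norm. The trace-norm term encourages an
#' approximately modular (low-rank) network but does not fix the number of
#' modules; see [ampc_estimate()] for the exact-module estimator.
#'
#' @inheritParams pearson_network
#' @param lam1 Nonnegative l1 (sparsity) weight.
#' @param lam2 Nonnegative trace-norm (low-rank) weight.
#' @param rho ADMM penalty parameter (default 1).
#' @param max_iters,tol ADMM iteration cap and residual tolerance.
#' @param constrain_diagonal Enforce zero diagonal during optimization
#'   (default `TRUE`; disable only for diagnostics on unconstrained
#'   least-squares limits).
#' @param symmetrize Return `(W + W^T)/2` (default `TRUE`); the regression
#'   form is not symmetric by itself.
#' @return Adjacency matrix (symmetric with zero diagonal under the
#'   defaults), with attribute `"admm_iters"` recording the iterations used.
#' @export
mpc_network <- function(X, lam1, lam2, rho = 1, max_iters = 3000, tol = 1e-8,
                        constrain_diagonal = TRUE, symmetrize = TRUE, ...) {
  if (lam1 < 0 || lam2 < 0) stop("penalties must be nonnegative", call. = FALSE)
  X <- as_timeseries(X, ...)
  n <- ncol(X)
  A <- crossprod(X)

  # V-step solve: (2A + 2*rho I) V = 2A + rho (Z1 - U1 + Z2 - U2)
  ea <- eigen(A, symmetric = TRUE)
  inv_diag <- 1 / (2 * ea$values + 2 * rho)
  solve_v <- function(RHS) {
    ea$vectors %*% (inv_diag * crossprod(ea$vectors, RHS))
  }

  soft <- function(M, t) sign(M) * pmax(abs(M) - t, 0)
  Z1 <- Z2 <- V <- matrix(0, n, n)
  U1 <- U2 <- matrix(0, n, n)
  iters <- max_iters
  for (it in seq_len(max_iters)) {
    V <- solve_v(2 * A + rho * (Z1 - U1 + Z2 - U2))
    Z1_old <- Z1; Z2_old <- Z2
    Z1 <- soft(V + U1, lam1 / rho)
    if (constrain_diagonal) diag(Z1) <- 0
    sv <- svd(V + U2)
    Z2 <- sv$u %*% (pmax(sv$d - lam2 / rho, 0) * t(sv$v))
    U1 <- U1 + V - Z1
    U2 <- U2 + V - Z2
    r_prim <- max(sqrt(sum((V - Z1)^2)), sqrt(sum((V - Z2)^2)))
    r_dual <- rho * max(sqrt(sum((Z1 - Z1_old)^2)), sqrt(sum((Z2 - Z2_old)^2)))
    if (r_prim < tol * n && r_dual < tol * n) { iters <- it; break }
  }
  W <- Z1  # satisfies the sparsity pattern and diagonal constraint exactly
  if (symmetrize) { W <- (W + t(W)) / 2; diag(W) <- 0 }
  dimnames(W) <- list(colnames(X), colnames(X))
  attr(W, "admm_iters") <- iters
  W
}

#' Objective value of the regression-form network estimators
#'
#' `||X - XW||_F^2 + lam1 ||W||_1 + lam2 ||W||_*`, the criterion minimized
#' by [sparse_pc_network()] (`lam2 = 0`) and [mpc_network()]. Exposed so
#' solver output can be compared against independent solvers.
#'
#' @inheritParams mpc_network
#' @param W Candidate weight matrix.
#' @return Scalar objective value.
#' @export
regression_objective <- function(X, W, lam1 = 0, lam2 = 0) {
  X <- as_timeseries(X)
  val <- sum((X - X %*% W)^2) + lam1 * sum(abs(W))
  if (lam2 > 0) val <- val + lam2 * sum(svd(W)$d)
  val
}
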
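# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths: components by union-find instead of
# igraph/spectra, lasso by ISTA instead of coordinate descent, the composite
# sparse + low-rank problem by Douglas-Rachford instead of ADMM, and the
# weight-step QP by 1-D numerical minimization instead of the closed form.

`%||%` <- function(a, b) if (is.null(a)) b else a

# connected components by union-find on edges with weight > tol
union_find_components <- function(W, tol = 1e-10) {
  n <- nrow(W)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (W[i, j] > tol) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots)) - 1L
}

# proximal-gradient (ISTA) solve of min ||y - B w||^2 + lam ||w||_1
ista_lasso <- function(B, y, lam, iters = 100000, tol = 1e-14) {
  p <- ncol(B); w <- rep(0, p)
  step <- 1 / (2 * max(eigen(crossprod(B), symmetric = TRUE,
                             only.values = TRUE)$values))
  obj_old <- Inf
  for (it in seq_len(iters)) {
    g <- 2 * crossprod(B, B %*% w - y)
    w <- as.numeric(sign(w - step * g) * pmax(abs(w - step * g) - step * lam, 0))
    if (it %% 200 == 0) {
      obj <- sum((y - B %*% w)^2) + lam * sum(abs(w))
      if (abs(obj_old - obj) < tol * max(1, obj)) break
      obj_old <- obj
    }
  }
  w
}

# columnwise ISTA solve of the full regression-form l1 network problem
ista_sparse_network <- function(X, lam) {
  n <- ncol(X)
  W <- matrix(0, n, n)
  for (j in seq_len(n)) {
    W[-j, j] <- ista_lasso(X[, -j, drop = FALSE], X[, j], lam)
  }
  W
}

# product-space Douglas-Rachford splitting for
# min ||X - XV||^2 + lam1 ||offdiag V||_1 + lam2 ||V||_*  s.t. diag(V) = 0
dr_mpc_oracle <- function(X, lam1, lam2, t = 0.5, iters = 5000) {
  n <- ncol(X); A <- crossprod(X)
  ea <- eigen(A, symmetric = TRUE)
  inv_d <- 1 / (2 * t * ea$values + 1)
  prox1 <- function(M) ea$vectors %*% (inv_d * crossprod(ea$vectors, M + 2 * t * A))
  prox2 <- function(M) { Z <- sign(M) * pmax(abs(M) - t * lam1, 0); diag(Z) <- 0; Z }
  prox3 <- function(M) { s <- svd(M); s$u %*% (pmax(s$d - t * lam2, 0) * t(s$v)) }
  Z <- replicate(3, matrix(0, n, n), simplify = FALSE)
  for (it in seq_len(iters)) {
    V <- (Z[[1]] + Z[[2]] + Z[[3]]) / 3
    Y <- list(prox1(2 * V - Z[[1]]), prox2(2 * V - Z[[2]]), prox3(2 * V - Z[[3]]))
    for (i in 1:3) Z[[i]] <- Z[[i]] + Y[[i]] - V
  }
  (Z[[1]] + Z[[2]] + Z[[3]]) / 3
}

# generic 1-D numerical solve of min_{w >= 0} (w - a)^2 + (alpha/2) f w + lam w
qp_entry_oracle <- function(a, f, alpha, lam) {
  obj <- function(w) (w - a)^2 + (alpha / 2) * f * w + lam * w
  ub <- abs(a) + 1
  opt <- stats::optimize(obj, c(0, ub), tol = 1e-12)
  if (obj(0) <= opt$objective) 0 else opt$minimum
}

qp_matrix_oracle <- function(A, Fdist, alpha, lam) {
  n <- nrow(A)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) W[i, j] <- qp_entry_oracle(A[i, j], Fdist[i, j], alpha, lam)
  }
  W
}

# random symmetric nonnegative sparse adjacency matrix
random_sparse_graph <- function(n, p_edge = 0.1) {
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  on <- up[stats::runif(length(up)) < p_edge]
  W[on] <- stats::runif(length(on), 0.1, 1)
  W + t(W)
}

# random matrix with orthonormal columns
random_orthonormal <- function(n, k) {
  qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))
}

# small high-SNR modular cohort spec for fast tests
tiny_cohort_spec <- function(n_rois = 30, k_true = 3, n_subjects = c(6, 6),
                             scans_per_subject = 1, m = 60, edges = 6,
                             effect = 0.3, seed = 1, ...) {
  modular_cohort_spec(
    n_rois = n_rois, n_timepoints = m, k_true = k_true,
    n_subjects_per_class = n_subjects, scans_per_subject = scans_per_subject,
    n_discriminative_edges = edges, effect_size = effect, seed = seed, ...)
}
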
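test_that("weight step solves the separable nonnegative QP exactly", {
  set.seed(31)
  # penalty-free case: clipped correlations
  A <- matrix(rnorm(36), 6, 6); A <- (A + t(A)) / 2; diag(A) <- 1
  Fd <- pairwise_rowdistance_matrix(matrix(rnorm(18), 6, 3))
  W <- ampc_update_W(A, Fd, alpha = 0, lam = 0)
  expect_equal(W, {
    M <- pmax(A, 0); diag(M) <- 0; M
  })

  # one-variable instance against the numerical oracle
  expect_equal(qp_entry_oracle(0.5, 0, 0, 0.4), 0.3, tolerance = 1e-6)
  W1 <- ampc_update_W(matrix(c(1, .5, .5, 1), 2, 2), matrix(0, 2, 2),
                      alpha = 1, lam = 0.4)
  expect_equal(W1[1, 2], 0.3, tolerance = 1e-12)

  # random instances, entrywise agreement with the generic QP oracle
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    A <- matrix(rnorm(n * n), n, n); A <- (A + t(A)) / 2; diag(A) <- 1
    Fd <- pairwise_rowdistance_matrix(matrix(rnorm(n * 3), n, 3))
    alpha <- runif(1, 0, 2); lam <- runif(1, 0, 1)
    W <- ampc_update_W(A, Fd, alpha, lam)
    expect_lt(max(abs(W - qp_matrix_oracle(A, Fd, alpha, lam))), 1e-6)
  }
  expect_error(ampc_update_W(diag(3), diag(4), 1, 1), "identical dimensions")
})

test_that("weight-step sparsity is monotone in both penalties", {
  set.seed(32)
  A <- matrix(rnorm(100), 10, 10); A <- (A + t(A)) / 2; diag(A) <- 1
  Fd <- pairwise_rowdistance_matrix(matrix(rnorm(30), 10, 3))
  nnz <- function(W) sum(W[upper.tri(W)] > 0)
  lam_grid <- c(0, 0.1, 0.3, 0.6, 1, 2)
  n_lam <- vapply(lam_grid, function(l) nnz(ampc_update_W(A, Fd, 0.5, l)), numeric(1))
  expect_true(all(diff(n_lam) <= 0))
  alpha_grid <- c(0, 0.5, 1, 2, 4, 8)
  n_alpha <- vapply(alpha_grid, function(a) nnz(ampc_update_W(A, Fd, a, 0.1)), numeric(1))
  expect_true(all(diff(n_alpha) <= 0))
})

test_that("spectral step attains the Ky Fan minimum", {
  set.seed(33)
  # block-diagonal graph with k components: k zero eigenvalues, zero trace
  W <- matrix(0, 9, 9)
  for (b in 0:2) { idx <- b * 3 + 1:3; W[idx, idx] <- 0.5 }
  diag(W) <- 0
  F3 <- ampc_update_F(W, 3)
  L <- build_laplacian(W)
  expect_lt(sum(diag(crossprod(F3, L %*% F3))), 1e-10)

  # random graph: no random orthonormal competitor beats the eigenvector basis
  W <- random_sparse_graph(12, 0.4)
  L <- build_laplacian(W)
  F_k <- ampc_update_F(W, 3)
  t_opt <- sum(diag(crossprod(F_k, L %*% F_k)))
  worst <- min(vapply(1:1000, function(i) {
    G <- random_orthonormal(12, 3)
    sum(diag(crossprod(G, L %*% G)))
  }, numeric(1)))
  expect_lte(t_opt, worst + 1e-10)

  expect_error(ampc_update_F(W, 12), "smaller than the node count")
})

test_that("the solver reduces to clipped correlation without penalties", {
  set.seed(34)
  X <- matrix(rnorm(200), 20, 10)
  fit <- ampc_estimate(X, k = 2, lam = 0, alpha0 = 1e-14,
                       max_outer_iters = 1, adapt_alpha = FALSE)
  expect_equal(fit$W, remove_negative_edges(pearson_network(X)),
               tolerance = 1e-10)
})

test_that("objective is non-increasing across alternating steps at fixed alpha", {
  set.seed(35)
  sc <- generate_scan(tiny_cohort_spec(n_rois = 24, k_true = 3, edges = 0), 0)
  # combinatorial Laplacian at fixed alpha: the full objective chain is monotone
  fit <- ampc_estimate(sc$X, k = 3, lam = 0.05, alpha0 = 0.5,
                       adapt_alpha = FALSE, normalized_laplacian = FALSE,
                       max_outer_iters = 25)
  tr <- fit$step_trace
  chain <- as.numeric(rbind(tr$obj_after_F, tr$obj_after_W))
  expect_true(all(diff(chain) <= 1e-9))

  # normalized Laplacian (lagged degrees): each weight step still minimizes
  # the recorded criterion exactly
  fit_n <- ampc_estimate(sc$X, k = 3, lam = 0.05)
  expect_true(all(fit_n$step_trace$obj_after_W <=
                    fit_n$step_trace$obj_after_F + 1e-9))
})

test_that("converged fits have exactly k modules, spectrally and combinatorially", {
  set.seed(36)
  spec <- tiny_cohort_spec(n_rois = 40, k_true = 4, edges = 0)
  sc <- generate_scan(spec, 0)
  fit <- ampc_estimate(sc$X, k = 4)
  expect_true(fit$converged)
  expect_equal(fit$k_observed, 4)
  expect_equal(connected_components(fit$W)$k_observed, 4)
  expect_equal(spectral_component_count(fit$W, normalized = TRUE), 4)
  expect_true(all(fit$W >= 0))
  expect_equal(fit$W, t(fit$W))
  expect_equal(diag(fit$W), rep(0, 40), ignore_attr = TRUE)

  # planted modules are recovered essentially perfectly at high SNR
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(fit$partition$labels, sc$partition)
  expect_gte(ari, 0.9)
})

test_that("failure to reach k modules reports non-convergence without error", {
  set.seed(37)
  X <- matrix(rnorm(20 * 12), 20, 12)
  fit <- ampc_estimate(X, k = 5, max_outer_iters = 1)
  expect_false(fit$converged)
  expect_s3_class(fit$step_trace, "data.frame")
  expect_error(ampc_estimate(X, k = 12), "at least k \\+ 1")
})

test_that("alpha adaptation follows the doubling/halving heuristic", {
  set.seed(38)
  sc <- generate_scan(tiny_cohort_spec(n_rois = 30, k_true = 3, edges = 0), 0)
  fit <- ampc_estimate(sc$X, k = 3)
  tr <- fit$step_trace
  for (i in seq_len(nrow(tr) - 1)) {
    if (tr$zero_eigs[i] < 3) expect_equal(tr$alpha[i + 1], tr$alpha[i] * 2)
    if (tr$zero_eigs[i] > 3) expect_equal(tr$alpha[i + 1], tr$alpha[i] / 2)
    if (tr$zero_eigs[i] == 3) expect_equal(tr$alpha[i + 1], tr$alpha[i])
  }
})
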
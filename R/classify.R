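#' Flatten a symmetric network to its upper-triangle feature vector
#'
#' Because estimated networks are symmetric, the strict upper triangle holds
#' every distinct edge exactly once: `n (n - 1) / 2` features (6670 for the
#' 116-ROI atlas). Features are ordered column-wise with `i < j`, i.e.
#' (1,2), (1,3), (2,3), (1,4), ...
#'
#' @param W Symmetric matrix.
#' @return Numeric vector of length `n (n - 1) / 2` with attribute
#'   `"feature_index"`, a two-column matrix of (row, column) ROI indices.
#' @seealso [unvectorize_upper_triangle()], [upper_triangle_index()]
#' @export
vectorize_upper_triangle <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    stop("`W` must be a square matrix", call. = FALSE)
  }
  if (max(abs(W - t(W))) > 1e-10) {
    stop("`W` must be symmetric to vectorize a single triangle", call. = FALSE)
  }
  v <- W[upper.tri(W)]
  attr(v, "feature_index") <- upper_triangle_index(nrow(W))
  v
}

#' Upper-triangle feature-to-edge index map
#'
#' @param n Node count.
#' @return `n (n - 1) / 2 x 2` integer matrix: feature `k` is the edge
#'   between ROI `[k, 1]` and ROI `[k, 2]` (`i < j`).
#' @export
upper_triangle_index <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
  dimnames(idx) <- list(NULL, c("roi_i", "roi_j"))
  idx
}

#' Rebuild a symmetric zero-diagonal matrix from its upper triangle
#'
#' Inverse of [vectorize_upper_triangle()] (up to the diagonal, restored as
#' zero).
#'
#' @param v Feature vector of length `n (n - 1) / 2`.
#' @return Symmetric `n x n` matrix.
#' @export
unvectorize_upper_triangle <- function(v) {
  p <- length(v)
  n <- (1 + sqrt(1 + 8 * p)) / 2
  if (abs(n - round(n)) > 1e-9) {
    stop("length ", p, " is not n(n-1)/2 for any integer n", call. = FALSE)
  }
  n <- round(n)
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- v
  W + t(W)
}

#' Two-sample t-test edge selection
#'
#' Screens every edge feature with a two-sided two-sample t-test between the
#' classes and keeps those with `p < p_threshold`. The unqualified test is
#' the pooled-variance Student form; Welch's unequal-variance form is
#' available as an option. Selection must be fitted on training scans only —
#' the cross-validation driver enforces this.
#'
#' Degenerate features get explicit conventions: zero pooled variance with
#' equal class means (e.g. a feature constant across all scans) gives
#' `t = 0, p = 1` and is never selected; zero variance with unequal means is
#' infinitely significant (`p = 0`). If nothing passes the threshold the
#' single smallest-p feature is kept (with a message) so a classifier can
#' always be trained.
#'
#' @param features Scans x features numeric matrix.
#' @param labels Binary vector (0 / 1) of length `nrow(features)`; both
#'   classes must be present.
#' @param p_threshold Selection level in (0, 1); default 0.05.
#' @param var_equal Pooled-variance Student test (default `TRUE`) or Welch.
#' @param p_adjust Multiple-testing correction applied before thresholding:
#'   `"none"` (default; selection is a screening step) or any method of
#'   [stats::p.adjust()] such as `"fdr"`.
#' @return List: `selected` (integer feature indices), `p_values` (raw),
#'   `p_adjusted` (after correction; equal to `p_values` under `"none"`),
#'   `t_stats`, `fallback` (`TRUE` when the smallest-p fallback fired).
#' @export
ttest_select <- function(features, labels, p_threshold = 0.05,
                         var_equal = TRUE, p_adjust = "none") {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (p_threshold <= 0 || p_threshold >= 1) {
    stop("`p_threshold` must be in (0, 1)", call. = FALSE)
  }
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 < 2 || n0 < 2) {
    stop("both classes need at least 2 scans for a t-test (got ",
         n0, " and ", n1, ")", call. = FALSE)
  }
  x0 <- features[labels == 0, , drop = FALSE]
  x1 <- features[labels == 1, , drop = FALSE]
  m0 <- colMeans(x0); m1 <- colMeans(x1)
  v0 <- colSums(sweep(x0, 2, m0)^2) / (n0 - 1)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  diff <- m1 - m0
  if (var_equal) {
    sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
    se <- sqrt(sp2 * (1 / n0 + 1 / n1))
    df <- rep(n0 + n1 - 2, length(se))
  } else {
    se <- sqrt(v0 / n0 + v1 / n1)
    df <- (v0 / n0 + v1 / n1)^2 /
      ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  }
  t_stats <- diff / se
  p <- 2 * stats::pt(abs(t_stats), df, lower.tail = FALSE)
  zero_se <- se == 0 | !is.finite(se)
  t_stats[zero_se] <- ifelse(diff[zero_se] == 0, 0, Inf * sign(diff[zero_se]))
  p[zero_se] <- ifelse(diff[zero_se] == 0, 1, 0)

  p_adj <- stats::p.adjust(p, method = p_adjust)
  selected <- which(p_adj < p_threshold)
  fallback <- FALSE
  if (length(selected) == 0) {
    selected <- which.min(p_adj)
    fallback <- TRUE
    message("no feature passed p < ", p_threshold,
            "; keeping the single smallest-p feature")
  }
  list(selected = selected, p_values = p, p_adjusted = p_adj,
       t_stats = t_stats, fallback = fallback)
}

#' Binary classification metrics
#'
#' Accuracy, sensitivity, specificity and area under the ROC curve, with
#' class 1 (the patient group) as the positive class:
#' `ACC = (TP + TN) / (TP + FP + TN + FN)`, `SEN = TP / (TP + FN)`,
#' `SPE = TN / (TN + FP)`. AUC is computed by the rank (Mann-Whitney)
#' construction over all thresholds of the decision scores, with ties
#' counted half.
#'
#' @param labels True binary labels (0 / 1).
#' @param predictions Predicted binary labels.
#' @param scores Real-valued decision scores (larger means more class-1).
#' @return Named list `acc`, `sen`, `spe`, `auc`. With single-class truth
#'   the AUC is undefined and returned as `NA` with a warning.
#' @export
compute_metrics <- function(labels, predictions, scores = NULL) {
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  stopifnot(length(labels) == length(predictions))
  tp <- sum(labels == 1 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  acc <- (tp + tn) / length(labels)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- NA_real_
  if (!is.null(scores)) {
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    if (n1 == 0 || n0 == 0) {
      warning("AUC undefined: only one class present in the truth labels")
    } else {
      r <- rank(scores)
      auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  list(acc = acc, sen = sen, spe = spe, auc = auc)
}

#' Rank edges by class discriminability
#'
#' Per-edge two-sample t-test over all scans, returned as a table of ROI
#' pairs sorted by ascending p-value — the package's view of "most
#' informative connections".
#'
#' @param features Scans x edges matrix from [vectorize_upper_triangle()].
#' @param labels Binary labels per scan.
#' @param roi_names Optional ROI names (length `n`).
#' @param p_cutoff Keep edges with `p <= p_cutoff` (default 1: all).
#' @param var_equal See [ttest_select()].
#' @return Data frame with columns `roi_i`, `roi_j`, `t`, `p`, ascending in
#'   `p`.
#' @export
rank_edges <- function(features, labels, roi_names = NULL, p_cutoff = 1,
                       var_equal = TRUE) {
  p_feat <- ncol(features)
  n <- round((1 + sqrt(1 + 8 * p_feat)) / 2)
  idx <- upper_triangle_index(n)
  tt <- ttest_select(features, labels, p_threshold = 0.999999,
                     var_equal = var_equal)
  out <- data.frame(
    roi_i = if (is.null(roi_names)) idx[, 1] else roi_names[idx[, 1]],
    roi_j = if (is.null(roi_names)) idx[, 2] else roi_names[idx[, 2]],
    t = tt$t_stats, p = tt$p_values
  )
  out <- out[out$p <= p_cutoff, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}

# ---- cross-validation driver -----------------------------------------------

validate_manifest <- function(manifest, folds = 1) {
  req <- c("scan_id", "subject_id", "label")
  miss <- setdiff(req, names(manifest))
  if (length(miss)) stop("manifest lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(manifest$scan_id)) {
    stop("scan_id values must be unique", call. = FALSE)
  }
  if (!all(manifest$label %in% c(0, 1))) {
    stop("labels must be 0 (control) or 1 (patient)", call. = FALSE)
  }
  lab_by_subj <- tapply(manifest$label, manifest$subject_id,
                        function(x) length(unique(x)))
  if (any(lab_by_subj > 1)) {
    stop("subject(s) with inconsistent labels: ",
         paste(names(lab_by_subj)[lab_by_subj > 1], collapse = ", "),
         call. = FALSE)
  }
  subj_label <- tapply(manifest$label, manifest$subject_id, function(x) x[1])
  n_per_class <- table(factor(subj_label, levels = c(0, 1)))
  if (any(n_per_class == 0)) stop("both classes must be present", call. = FALSE)
  if (any(n_per_class < folds)) {
    stop("need at least ", folds, " subjects per class for ", folds,
         "-fold subject-level CV (have ",
         paste(n_per_class, collapse = " and "), ")", call. = FALSE)
  }
  invisible(subj_label)
}

# stratified subject-level fold assignment; returns named fold id per subject
assign_subject_folds <- function(subj_label, folds) {
  fold <- integer(length(subj_label))
  names(fold) <- names(subj_label)
  for (cl in unique(subj_label)) {
    idx <- which(subj_label == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

load_scan_matrix <- function(manifest, i) {
  if (!is.null(manifest$data)) return(manifest$data[[i]])
  if (!is.null(manifest$path)) return(read_timeseries(manifest$path[i]))
  stop("manifest needs a `data` list-column or a `path` column", call. = FALSE)
}

#' Estimate a network with a named method
#'
#' Dispatch shared by the cross-validation driver and the command-line
#' interface. The "+" suffix removes negative edges from the corresponding
#' base estimator.
#'
#' @param X Time-series matrix for one scan.
#' @param method One of `"pc"`, `"pc+"`, `"sparse-pc"`, `"sparse-pc+"`,
#'   `"m-pc"`, `"m-pc+"`, `"am-pc"`.
#' @param params Method hyperparameters: `lam` for the sparse estimators and
#'   AM-PC, `c(lam1, lam2)` for M-PC; ignored for plain correlation.
#' @param k,normalized AM-PC module count and Laplacian choice.
#' @return Adjacency matrix (for `"am-pc"`, the `W` of the fit; the full fit
#'   is attached as attribute `"fit"`).
#' @export
estimate_network <- function(X, method, params = NULL, k = 8,
                             normalized = TRUE) {
  method <- match.arg(method, c("pc", "pc+", "sparse-pc", "sparse-pc+",
                                "m-pc", "m-pc+", "am-pc"))
  base <- sub("\\+$", "", method)
  W <- switch(base,
    "pc" = pearson_network(X),
    "sparse-pc" = sparse_pc_network(X, lam = params[[1]]),
    "m-pc" = mpc_network(X, lam1 = params[[1]], lam2 = params[[2]]),
    "am-pc" = {
      fit <- ampc_estimate(X, k = k, lam = params[[1]],
                           normalized_laplacian = normalized)
      out <- fit$W
      attr(out, "fit") <- fit
      out
    })
  if (grepl("\\+$", method)) W <- remove_negative_edges(W)
  W
}

# features (scans x p) for each grid point; networks estimated once per
# (scan, grid point) and reused across folds/repeats
grid_feature_tables <- function(manifest, method, grid, k, normalized,
                                verbose = FALSE) {
  if (method %in% c("pc", "pc+")) grid <- list(NULL)
  if (is.null(grid)) {
    grid <- if (method == "am-pc") list(2^-7) else list(2^-2)
  }
  if (is.numeric(grid)) grid <- as.list(grid)
  if (is.data.frame(grid)) grid <- lapply(seq_len(nrow(grid)),
                                          function(i) as.numeric(grid[i, ]))
  scans <- lapply(seq_len(nrow(manifest)),
                  function(i) as_timeseries(load_scan_matrix(manifest, i)))
  tables <- lapply(seq_along(grid), function(g) {
    if (verbose) message("estimating networks, grid point ", g, "/", length(grid))
    t(vapply(scans, function(X) {
      as.numeric(vectorize_upper_triangle(
        estimate_network(X, method, grid[[g]], k, normalized)))
    }, numeric(ncol(scans[[1]]) * (ncol(scans[[1]]) - 1) / 2)))
  })
  list(tables = tables, grid = grid)
}

# train on train_idx rows, evaluate on test_idx rows of one feature table
fit_eval_fold <- function(features, labels, train_idx, test_idx,
                          p_threshold, cost) {
  sel <- suppressMessages(
    ttest_select(features[train_idx, , drop = FALSE], labels[train_idx],
                 p_threshold = p_threshold))
  tr <- features[train_idx, sel$selected, drop = FALSE]
  te <- features[test_idx, sel$selected, drop = FALSE]
  y <- factor(labels[train_idx], levels = c(0, 1))
  fit <- e1071::svm(tr, y, kernel = "linear", cost = cost, scale = FALSE)
  pred <- stats::predict(fit, te, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  if (colnames(dv)[1] == "0/1") dv <- -dv  # orient: larger = class 1
  list(pred = as.integer(as.character(pred)), scores = as.numeric(dv),
       n_selected = length(sel$selected))
}

#' Repeated subject-level cross-validated classification
#'
#' The full evaluation protocol: networks are estimated per scan for every
#' candidate hyperparameter, vectorized to edge features, and classified
#' with t-test edge selection followed by a linear support vector machine
#' (fixed `C = 1`). Folds partition *subjects*, never scans, so repeated
#' scans of one person cannot straddle the train/test boundary; folds are
#' stratified by class. When the grid has more than one point, the value
#' used in each outer fold is chosen by an inner subject-level
#' cross-validation on the training portion only (highest inner accuracy,
#' ties to the sparser/first candidate). The whole procedure is repeated
#' with `repeats` independent fold randomizations and summarized as
#' mean +/- standard deviation of the per-repeat mean metrics.
#'
#' @param manifest Data frame with columns `scan_id`, `subject_id`, `label`
#'   (0 = control, 1 = patient) and either a `path` column of time-series
#'   files or a `data` list-column of matrices.
#' @param method Estimator name, see [estimate_network()].
#' @param grid Hyperparameter candidates: numeric vector (sparse estimators,
#'   AM-PC) or data frame / list of pairs (M-PC). `NULL` uses a single
#'   default value.
#' @param k AM-PC module count (default 8).
#' @param folds,repeats Outer folds (default 5) and repeat count.
#' @param seed Integer seed; repeat `r` draws its folds from seed + r.
#' @param p_threshold t-test selection level (default 0.05).
#' @param cost SVM regularization constant (default 1).
#' @param normalized AM-PC Laplacian choice.
#' @param inner_folds Inner CV folds for grid search (default 5).
#' @param verbose Progress messages.
#' @return Object of class `"cv_report"`: list with `fold_metrics` (one row
#'   per repeat x fold: metrics, chosen grid point, selected feature count),
#'   `repeat_means`, `summary` (mean and sd per metric), and the protocol
#'   settings.
#' @export
run_cv <- function(manifest, method = "am-pc", grid = NULL, k = 8, folds = 5,
                   repeats = 10, seed = 1, p_threshold = 0.05, cost = 1,
                   normalized = TRUE, inner_folds = 5, verbose = FALSE) {
  manifest <- as.data.frame(manifest)
  subj_label <- validate_manifest(manifest, folds)
  ft <- grid_feature_tables(manifest, method, grid, k, normalized, verbose)
  tables <- ft$tables
  labels <- as.integer(manifest$label)
  subjects <- as.character(manifest$subject_id)

  rows <- list()
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    fold_of_subj <- assign_subject_folds(subj_label, folds)
    for (f in seq_len(folds)) {
      test_subj <- names(fold_of_subj)[fold_of_subj == f]
      test_idx <- which(subjects %in% test_subj)
      train_idx <- setdiff(seq_along(labels), test_idx)

      g_best <- 1L
      if (length(tables) > 1) {
        inner_subj <- subj_label[setdiff(names(subj_label), test_subj)]
        inner_fold <- assign_subject_folds(inner_subj, inner_folds)
        acc_g <- vapply(seq_along(tables), function(g) {
          accs <- vapply(seq_len(inner_folds), function(fi) {
            val_subj <- names(inner_fold)[inner_fold == fi]
            val_idx <- which(subjects %in% val_subj)
            fit_idx <- setdiff(train_idx, val_idx)
            res <- fit_eval_fold(tables[[g]], labels, fit_idx, val_idx,
                                 p_threshold, cost)
            mean(res$pred == labels[val_idx])
          }, numeric(1))
          mean(accs)
        }, numeric(1))
        g_best <- which.max(acc_g)
      }

      res <- fit_eval_fold(tables[[g_best]], labels, train_idx, test_idx,
                           p_threshold, cost)
      m <- compute_metrics(labels[test_idx], res$pred, res$scores)
      rows[[length(rows) + 1]] <- data.frame(
        rep = r, fold = f, acc = m$acc, sen = m$sen, spe = m$spe, auc = m$auc,
        grid_index = g_best, n_selected = res$n_selected,
        test_subjects = paste(sort(test_subj), collapse = ","),
        train_subjects = paste(sort(unique(subjects[train_idx])),
                               collapse = ","))
    }
    if (verbose) message("repeat ", r, "/", repeats, " done")
  }
  fold_metrics <- do.call(rbind, rows)
  repeat_means <- stats::aggregate(
    fold_metrics[c("acc", "sen", "spe", "auc")],
    by = list(rep = fold_metrics$rep), FUN = mean, na.rm = TRUE)
  summ <- data.frame(
    metric = c("acc", "sen", "spe", "auc"),
    mean = vapply(c("acc", "sen", "spe", "auc"),
                  function(m) mean(repeat_means[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(c("acc", "sen", "spe", "auc"),
                function(m) stats::sd(repeat_means[[m]]), numeric(1)),
    row.names = NULL)
  structure(list(fold_metrics = fold_metrics, repeat_means = repeat_means,
                 summary = summ, method = method, grid = ft$grid, k = k,
                 folds = folds, repeats = repeats, seed = seed,
                 p_threshold = p_threshold, cost = cost),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validated classification (%s, %d-fold x %d repeats)\n",
              x$method, x$folds, x$repeats))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %.4f +/- %.4f\n", toupper(s$metric[i]),
                s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Sweep the module count k
#'
#' Runs the full cross-validated pipeline for each candidate module count
#' and collects the summary metrics in one tidy table, for studying how the
#' modularity constraint affects discrimination.
#'
#' @inheritParams run_cv
#' @param k_values Integer vector of module counts, all `< n`.
#' @return Data frame with one row per k: mean and sd of ACC, SEN, SPE, AUC.
#' @export
k_sweep <- function(manifest, k_values, method = "am-pc", ...) {
  out <- lapply(k_values, function(kk) {
    rep_ <- run_cv(manifest, method = method, k = kk, ...)
    s <- rep_$summary
    stats::setNames(
      data.frame(k = kk, t(s$mean), t(s$sd)),
      c("k", paste0(s$metric, "_mean"), paste0(s$metric, "_sd")))
  })
  do.call(rbind, out)
}
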
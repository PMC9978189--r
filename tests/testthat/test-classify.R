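test_that("upper-triangle vectorization enumerates each edge once and inverts", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.1
  W[1, 3] <- W[3, 1] <- 0.2
  W[2, 3] <- W[3, 2] <- 0.3
  v <- vectorize_upper_triangle(W)
  expect_equal(as.numeric(v), c(0.1, 0.2, 0.3))
  idx <- attr(v, "feature_index")
  expect_equal(idx[, "roi_i"], c(1, 1, 2), ignore_attr = TRUE)
  expect_equal(idx[, "roi_j"], c(2, 3, 3), ignore_attr = TRUE)

  set.seed(41)
  M <- matrix(rnorm(64), 8, 8); M <- M + t(M); diag(M) <- 0
  expect_equal(unvectorize_upper_triangle(vectorize_upper_triangle(M)), M)
  expect_equal(length(vectorize_upper_triangle(M)), 8 * 7 / 2)

  expect_error(vectorize_upper_triangle(matrix(rnorm(9), 3, 3)), "symmetric")
  expect_error(unvectorize_upper_triangle(rnorm(4)), "not n\\(n-1\\)/2")
})

test_that("t-test selection matches stats::t.test and handles degenerate features", {
  set.seed(42)
  labels <- rep(c(0, 1), each = 10)
  feats <- cbind(const = rep(1, 20),
                 same = rep(c(1, 2, 3), length.out = 20),
                 sig = c(rnorm(10), rnorm(10, 3)),
                 noise = rnorm(20))
  # class-identical feature: t = 0, p = 1
  f_same <- matrix(c(1, 2, 3, 1, 2, 3), 6, 1)
  tt0 <- ttest_select(cbind(f_same, rnorm(6)), rep(c(0, 1), each = 3),
                      p_threshold = 0.5)
  expect_equal(tt0$t_stats[1], 0)
  expect_equal(tt0$p_values[1], 1)

  tt <- ttest_select(feats, labels)
  expect_equal(tt$p_values[["const"]], 1)
  expect_false(1 %in% tt$selected)
  expect_true(3 %in% tt$selected)
  # agreement with the reference implementation, pooled and Welch
  for (var_equal in c(TRUE, FALSE)) {
    tt <- ttest_select(feats, labels, var_equal = var_equal)
    for (j in 3:4) {
      ref <- t.test(feats[labels == 1, j], feats[labels == 0, j],
                    var.equal = var_equal)
      expect_equal(unname(tt$t_stats[j]), unname(ref$statistic), tolerance = 1e-10)
      expect_equal(unname(tt$p_values[j]), ref$p.value, tolerance = 1e-10)
    }
  }
  expect_error(ttest_select(feats, rep(0, 20)), "both classes")
  expect_error(ttest_select(feats, labels, p_threshold = 1.2), "in \\(0, 1\\)")

  # FDR switch: adjusted p-values are BH and selection is more conservative
  tt_fdr <- suppressMessages(ttest_select(feats, labels, p_adjust = "fdr"))
  expect_equal(tt_fdr$p_adjusted, p.adjust(tt_fdr$p_values, "fdr"))
  expect_true(all(tt_fdr$selected %in%
                    suppressMessages(ttest_select(feats, labels))$selected))
})

test_that("selection finds planted effects and keeps the nominal false-positive level", {
  set.seed(43)
  n_scan <- 200; p <- 2000; planted <- 1:10
  hits <- fps <- numeric(20)
  for (r in 1:20) {
    labels <- rep(c(0, 1), each = n_scan / 2)
    feats <- matrix(rnorm(n_scan * p), n_scan, p)
    feats[labels == 1, planted] <- feats[labels == 1, planted] + 2  # Cohen's d = 2
    tt <- ttest_select(feats, labels)
    hits[r] <- mean(planted %in% tt$selected)
    fps[r] <- mean(setdiff(seq_len(p), planted) %in% tt$selected)
  }
  expect_equal(mean(hits), 1)
  expect_equal(mean(fps), 0.05, tolerance = 0.02)
})

test_that("selection falls back to the single best feature when nothing passes", {
  set.seed(44)
  feats <- matrix(rnorm(40), 20, 2)
  expect_message(tt <- ttest_select(feats, rep(c(0, 1), each = 10),
                                    p_threshold = 1e-12), "smallest-p")
  expect_length(tt$selected, 1)
  expect_true(tt$fallback)
})

test_that("classification metrics follow their printed definitions", {
  # TP=3 TN=2 FP=1 FN=2
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0)
  preds  <- c(1, 1, 1, 0, 0, 0, 0, 1)
  m <- compute_metrics(labels, preds)
  expect_equal(m$acc, 0.625)
  expect_equal(m$sen, 0.6)
  expect_equal(m$spe, 2 / 3)
  # identity ACC = (SEN * P + SPE * N) / (P + N)
  expect_equal(m$acc, (m$sen * 5 + m$spe * 3) / 8)

  m2 <- compute_metrics(labels, preds, scores = labels)
  expect_equal(m2$auc, 1)

  set.seed(45)
  labels <- rbinom(2000, 1, 0.5)
  scores <- rnorm(2000)
  m3 <- compute_metrics(labels, as.integer(scores > 0), scores)
  expect_equal(m3$auc, 0.5, tolerance = 0.03)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(m3$auc, ref, tolerance = 1e-10)

  expect_warning(compute_metrics(c(1, 1), c(1, 0), c(0.2, 0.1)), "one class")
})

test_that("edge ranking orders ROI pairs by p-value", {
  set.seed(46)
  n <- 6; n_scan <- 40
  labels <- rep(c(0, 1), each = n_scan / 2)
  feats <- matrix(rnorm(n_scan * n * (n - 1) / 2), n_scan)
  feats[labels == 1, 4] <- feats[labels == 1, 4] + 3
  tab <- rank_edges(feats, labels, roi_names = LETTERS[1:n])
  expect_equal(nrow(tab), n * (n - 1) / 2)
  expect_false(is.unsorted(tab$p))
  idx <- upper_triangle_index(n)
  expect_equal(c(tab$roi_i[1], tab$roi_j[1]),
               c(LETTERS[idx[4, 1]], LETTERS[idx[4, 2]]))
})

test_that("manifest validation rejects malformed cohorts", {
  mf <- data.frame(scan_id = c("a", "b", "c", "d"),
                   subject_id = c("s1", "s1", "s2", "s2"),
                   label = c(0, 0, 1, 1))
  expect_silent(ampcnet:::validate_manifest(mf))
  bad <- mf; bad$label[2] <- 1
  expect_error(ampcnet:::validate_manifest(bad), "inconsistent labels")
  dup <- mf; dup$scan_id[2] <- "a"
  expect_error(ampcnet:::validate_manifest(dup), "unique")
  one <- mf; one$label <- 0
  expect_error(ampcnet:::validate_manifest(one), "both classes")
  expect_error(ampcnet:::validate_manifest(mf, folds = 5), "at least 5 subjects")
})

test_that("a perfectly separable cohort is classified perfectly", {
  set.seed(47)
  # classes with entirely different module layouts at zero noise: disjoint
  # strong-edge supports, trivially separable correlation features
  spec0 <- tiny_cohort_spec(n_rois = 20, k_true = 2, n_subjects = c(8, 8),
                            edges = 0, seed = 10)
  spec1 <- modular_cohort_spec(n_rois = 20, n_timepoints = 60, k_true = 5,
                               n_subjects_per_class = c(8, 8),
                               scans_per_subject = 1,
                               n_discriminative_edges = 0, seed = 11)
  c0 <- generate_cohort(spec0, seed = 100)
  c1 <- generate_cohort(spec1, seed = 101)
  mf <- rbind(c0$manifest[c0$manifest$label == 0, ],
              c1$manifest[c1$manifest$label == 0, ])
  mf$label <- rep(c(0, 1), each = 8)
  mf$subject_id <- paste0(rep(c("a", "b"), each = 8), mf$subject_id)
  mf$scan_id <- paste0(rep(c("a", "b"), each = 8), mf$scan_id)
  rep_ <- run_cv(mf, method = "pc", folds = 4, repeats = 3, seed = 7)
  expect_equal(rep_$fold_metrics$acc, rep(1, nrow(rep_$fold_metrics)))
  expect_equal(rep_$summary$mean, rep(1, 4))
})

test_that("subjects never straddle the train/test boundary in any split", {
  set.seed(48)
  spec <- tiny_cohort_spec(n_rois = 12, k_true = 2, n_subjects = c(6, 6),
                           scans_per_subject = 2, edges = 2, m = 40)
  cohort <- generate_cohort(spec, seed = 5)
  rep_ <- run_cv(cohort$manifest, method = "pc", folds = 3, repeats = 4, seed = 9)
  fm <- rep_$fold_metrics
  for (i in seq_len(nrow(fm))) {
    test_s <- strsplit(fm$test_subjects[i], ",")[[1]]
    train_s <- strsplit(fm$train_subjects[i], ",")[[1]]
    expect_length(intersect(test_s, train_s), 0)
  }
  # folds within one repeat partition the subject set
  for (r in unique(fm$rep)) {
    covered <- sort(unlist(strsplit(fm$test_subjects[fm$rep == r], ",")))
    expect_equal(covered, sort(unique(cohort$manifest$subject_id)))
  }
})

test_that("permuted labels drive accuracy to the majority-class rate", {
  set.seed(49)
  spec <- tiny_cohort_spec(n_rois = 16, k_true = 2, n_subjects = c(7, 7),
                           edges = 4, effect = 0.4, m = 50)
  cohort <- generate_cohort(spec, seed = 3)
  mf <- cohort$manifest
  # permute labels at the subject level, averaging over permutation draws
  # (one draw can align with the true classes by chance at this n)
  subj <- unique(mf$subject_id)
  perm_acc <- vapply(1:5, function(p) {
    new_lab <- setNames(sample(rep(c(0, 1), length.out = length(subj))), subj)
    mf$label <- new_lab[mf$subject_id]
    rep_ <- run_cv(mf, method = "pc", folds = 5, repeats = 2, seed = 17 + p)
    mean(rep_$repeat_means$acc)
  }, numeric(1))
  expect_lt(abs(mean(perm_acc) - 0.5), 3 * max(sd(perm_acc), 0.05))
})

test_that("grid search selects hyperparameters by inner cross-validation only", {
  set.seed(50)
  spec <- tiny_cohort_spec(n_rois = 14, k_true = 2, n_subjects = c(6, 6),
                           edges = 4, effect = 0.4, m = 50)
  cohort <- generate_cohort(spec, seed = 2)
  rep_ <- run_cv(cohort$manifest, method = "sparse-pc", grid = c(0.05, 0.2),
                 folds = 3, repeats = 2, seed = 21, inner_folds = 3)
  expect_true(all(rep_$fold_metrics$grid_index %in% 1:2))
  expect_equal(nrow(rep_$fold_metrics), 6)
  expect_true(all(rep_$summary$mean >= 0 & rep_$summary$mean <= 1))
})

test_that("k sweep reproduces a single run and errors on invalid k", {
  set.seed(51)
  spec <- tiny_cohort_spec(n_rois = 15, k_true = 3, n_subjects = c(5, 5),
                           edges = 3, effect = 0.4, m = 50)
  cohort <- generate_cohort(spec, seed = 6)
  tab <- k_sweep(cohort$manifest, k_values = 3, method = "am-pc",
                 folds = 5, repeats = 2, seed = 30)
  one <- run_cv(cohort$manifest, method = "am-pc", k = 3,
                folds = 5, repeats = 2, seed = 30)
  expect_equal(tab$acc_mean, one$summary$mean[one$summary$metric == "acc"])
  expect_equal(tab$auc_mean, one$summary$mean[one$summary$metric == "auc"])
  expect_error(k_sweep(cohort$manifest, k_values = 15, method = "am-pc",
                       folds = 5, repeats = 1, seed = 1))
})
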
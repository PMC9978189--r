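#' Specification of a synthetic modular cohort
#'
#' Describes a two-class cohort of ROI time series with planted modular
#' correlation structure: ROIs fall into `k_true` modules, signals correlate
#' at `within_corr` inside a module and `between_corr` across modules, and
#' the patient class additionally carries elevated correlation on a small
#' set of discriminative between-module edges. Defaults mirror the shapes of
#' a typical resting-state study: 116 atlas ROIs, 137 retained volumes per
#' scan, 8 modules, and a cohort of 48 control and 95 patient subjects with
#' 2 scans each.
#'
#' @param n_rois Number of ROIs (default 116).
#' @param n_timepoints Time points per scan (default 137).
#' @param k_true Planted module count (default 8).
#' @param module_sizes Integer partition of `n_rois` into modules; default
#'   splits as evenly as possible.
#' @param within_corr Within-module correlation in (0, 1); default 0.7.
#' @param between_corr Between-module baseline correlation; default 0.
#' @param noise_sd Standard deviation of additional white observation noise
#'   (default 0; the block covariance already sets the signal-to-noise
#'   contrast through `within_corr` / `between_corr`).
#' @param n_subjects_per_class Length-2 vector `(controls, patients)`;
#'   default `c(48, 95)`.
#' @param scans_per_subject Scans per subject (default 2).
#' @param n_discriminative_edges Number of within-module ROI pairs whose
#'   correlation is weakened in the patient class (default 20). Within-module
#'   pairs are used because module-constrained estimators retain those edges,
#'   so the class contrast survives network estimation.
#' @param effect_size Correlation reduction on discriminative edges in the
#'   patient class (default 0.3). Must stay below
#'   `within_corr - between_corr` so the weakened edges remain above the
#'   between-module baseline; the shifted covariance is projected back to
#'   positive definite if needed, and an error asks for a smaller effect when
#'   the shift is too large to repair.
#' @param subject_jitter Standard deviation of the per-subject symmetric
#'   covariance perturbation (default 0.02), which makes scans cluster by
#'   subject so that subject-level and scan-level cross-validation differ.
#' @param seed Integer seed fixing the ground truth (module assignment and
#'   discriminative edges) and, in [generate_cohort()], the data.
#' @return List of class `"modular_cohort_spec"`, including the planted
#'   `partition` (0-based module labels) and `discriminative_edges`
#'   (two-column index matrix).
#' @export
modular_cohort_spec <- function(n_rois = 116, n_timepoints = 137, k_true = 8,
                                module_sizes = NULL, within_corr = 0.7,
                                between_corr = 0, noise_sd = 0,
                                n_subjects_per_class = c(48, 95),
                                scans_per_subject = 2,
                                n_discriminative_edges = 20,
                                effect_size = 0.3, subject_jitter = 0.02,
                                seed = 1) {
  if (is.null(module_sizes)) {
    base <- n_rois %/% k_true
    module_sizes <- rep(base, k_true) +
      c(rep(1, n_rois %% k_true), rep(0, k_true - n_rois %% k_true))
  }
  stopifnot(sum(module_sizes) == n_rois, length(module_sizes) == k_true,
            within_corr > between_corr, between_corr >= 0, within_corr < 1,
            n_timepoints >= 2, length(n_subjects_per_class) == 2,
            scans_per_subject >= 1, effect_size >= 0, noise_sd >= 0)
  partition <- rep(seq_along(module_sizes) - 1L, module_sizes)

  # ground truth drawn from a private RNG stream keyed by `seed`
  edges <- matrix(integer(0), 0, 2)
  if (n_discriminative_edges > 0) {
    if (effect_size >= within_corr - between_corr) {
      stop("effect_size must be smaller than within_corr - between_corr; ",
           "reduce effect_size", call. = FALSE)
    }
    within <- which(outer(partition, partition, "==") &
                      upper.tri(diag(n_rois)), arr.ind = TRUE)
    if (nrow(within) < n_discriminative_edges) {
      stop("not enough within-module pairs for ", n_discriminative_edges,
           " discriminative edges", call. = FALSE)
    }
    pick <- with_local_seed(seed, sample.int(nrow(within),
                                             n_discriminative_edges))
    edges <- within[pick, , drop = FALSE]
    colnames(edges) <- c("roi_i", "roi_j")
  }

  spec <- structure(
    list(n_rois = n_rois, n_timepoints = n_timepoints, k_true = k_true,
         module_sizes = module_sizes, within_corr = within_corr,
         between_corr = between_corr, noise_sd = noise_sd,
         n_subjects_per_class = n_subjects_per_class,
         scans_per_subject = scans_per_subject,
         n_discriminative_edges = n_discriminative_edges,
         effect_size = effect_size, subject_jitter = subject_jitter,
         seed = as.integer(seed), partition = partition,
         discriminative_edges = edges),
    class = "modular_cohort_spec")
  # both class covariances must be positive definite at construction
  for (cl in 0:1) class_covariance(spec, cl)
  spec
}

# run expr under a temporary RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# block correlation matrix for one class (0 control, 1 patient)
class_covariance <- function(spec, class_label) {
  n <- spec$n_rois
  S <- matrix(spec$between_corr, n, n)
  for (md in unique(spec$partition)) {
    idx <- which(spec$partition == md)
    S[idx, idx] <- spec$within_corr
  }
  diag(S) <- 1
  if (class_label == 1 && nrow(spec$discriminative_edges) > 0) {
    for (e in seq_len(nrow(spec$discriminative_edges))) {
      i <- spec$discriminative_edges[e, 1]; j <- spec$discriminative_edges[e, 2]
      S[i, j] <- S[i, j] - spec$effect_size
      S[j, i] <- S[i, j]
    }
  }
  project_pd(S, context = "class covariance (reduce effect_size)")
}

# clip eigenvalues to keep the matrix positive definite; error when the
# repair would distort it badly
project_pd <- function(S, floor = 1e-6, context = "covariance") {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= floor) return(S)
  if (min(e$values) < -0.5) {
    stop("matrix is far from positive definite while building the ", context,
         call. = FALSE)
  }
  v <- pmax(e$values, floor)
  S2 <- e$vectors %*% (v * t(e$vectors))
  (S2 + t(S2)) / 2
}

# per-subject covariance: class covariance plus a small symmetric jitter
subject_covariance <- function(spec, class_label) {
  S <- class_covariance(spec, class_label)
  if (spec$subject_jitter > 0) {
    n <- spec$n_rois
    E <- matrix(stats::rnorm(n * n, sd = spec$subject_jitter), n, n)
    E <- (E + t(E)) / 2
    diag(E) <- 0
    S <- project_pd(S + E, context = "subject covariance")
  }
  S
}

#' Draw one synthetic scan
#'
#' Samples `n_timepoints` observations from a zero-mean Gaussian with the
#' planted block covariance (plus optional white noise), using the current
#' RNG state. Two scans of the same subject should share a
#' `subject_covariance` draw; [generate_cohort()] arranges this.
#'
#' @param spec A [modular_cohort_spec()].
#' @param class_label 0 (control) or 1 (patient).
#' @param subject_cov Optional precomputed subject covariance; when `NULL` a
#'   fresh subject is drawn.
#' @return List: `X` (time points x ROIs matrix, columns named `ROI1..`),
#'   `partition` (the planted module labels, 0-based).
#' @export
generate_scan <- function(spec, class_label = 0, subject_cov = NULL) {
  stopifnot(inherits(spec, "modular_cohort_spec"), class_label %in% 0:1)
  if (is.null(subject_cov)) subject_cov <- subject_covariance(spec, class_label)
  n <- spec$n_rois; m <- spec$n_timepoints
  R <- chol(subject_cov)
  X <- matrix(stats::rnorm(m * n), m, n) %*% R
  if (spec$noise_sd > 0) X <- X + matrix(stats::rnorm(m * n, sd = spec$noise_sd), m, n)
  colnames(X) <- paste0("ROI", seq_len(n))
  list(X = X, partition = spec$partition)
}

#' Generate a full two-class cohort
#'
#' Draws every subject's covariance once and then `scans_per_subject` scans
#' from it, for both classes. Optionally writes the cohort to disk as one
#' TSV per scan plus `manifest.csv` and `ground_truth.json`; the whole
#' cohort is reproducible from the spec and its seed.
#'
#' @param spec A [modular_cohort_spec()].
#' @param dir Optional output directory (created if missing). When `NULL`,
#'   nothing is written and scans are only returned in memory.
#' @param seed Seed for the cohort draw; defaults to `spec$seed`.
#' @return List: `manifest` (data frame with `scan_id`, `subject_id`,
#'   `label`, a `data` list-column of matrices and, when written, `path`),
#'   `partition`, `discriminative_edges`, `spec`.
#' @export
generate_cohort <- function(spec, dir = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "modular_cohort_spec"))
  set.seed(seed)
  rows <- list(); data <- list()
  for (cl in 0:1) {
    n_subj <- spec$n_subjects_per_class[cl + 1]
    for (s in seq_len(n_subj)) {
      subject_id <- sprintf("%s%03d", c("nc", "pt")[cl + 1], s)
      S <- subject_covariance(spec, cl)
      for (sc in seq_len(spec$scans_per_subject)) {
        scan <- generate_scan(spec, cl, subject_cov = S)
        scan_id <- sprintf("%s_scan%d", subject_id, sc)
        rows[[length(rows) + 1]] <- data.frame(
          scan_id = scan_id, subject_id = subject_id, label = cl)
        data[[length(data) + 1]] <- scan$X
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$data <- data

  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
      stop("cannot create output directory ", dir, call. = FALSE)
    }
    paths <- character(nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      paths[i] <- file.path(dir, paste0(manifest$scan_id[i], ".tsv"))
      utils::write.table(format(data[[i]], digits = 10, trim = TRUE),
                         paths[i], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    manifest$path <- paths
    # CSV paths are relative to the manifest's own directory
    on_disk <- manifest[c("scan_id", "subject_id", "label", "path")]
    on_disk$path <- basename(paths)
    utils::write.csv(on_disk, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    gt <- list(partition = spec$partition,
               discriminative_edges = spec$discriminative_edges,
               spec = spec[setdiff(names(spec),
                                   c("partition", "discriminative_edges"))],
               seed = seed)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(manifest = manifest, partition = spec$partition,
       discriminative_edges = spec$discriminative_edges, spec = spec)
}
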
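#' Construct a single-modality feature matrix
#'
#' A feature matrix holds one modality's subjects-by-features table (one row
#' per subject, one column per ROI feature). Entries must be finite; subject
#' ids and feature labels must be unique.
#'
#' @param values Numeric matrix, subjects in rows, ROI features in columns.
#' @param subject_ids Character vector of subject identifiers, one per row.
#' @param feature_labels Character vector of ROI feature labels, one per
#'   column.
#' @param modality Short modality tag, e.g. `"sMRI"` or `"PET"`.
#' @return An object of class `fc2fs_feature_matrix`: a list with elements
#'   `values` (dimnamed matrix), `subject_ids`, `feature_labels`, `modality`.
#' @examples
#' X <- matrix(rnorm(12), 4, 3)
#' fm <- feature_matrix(X, paste0("S", 1:4), paste0("ROI", 1:3), "sMRI")
#' dim(fm$values)
#' @export
feature_matrix <- function(values, subject_ids = NULL, feature_labels = NULL,
                           modality = "modality1") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(subject_ids)) subject_ids <- rownames(values)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n))
  if (is.null(feature_labels)) feature_labels <- colnames(values)
  if (is.null(feature_labels)) feature_labels <- sprintf("F%03d", seq_len(p))
  subject_ids <- as.character(subject_ids)
  feature_labels <- as.character(feature_labels)
  if (n < 2L || p < 2L) {
    stop(sprintf("feature matrix must be at least 2 x 2, got %d x %d", n, p),
         call. = FALSE)
  }
  if (length(subject_ids) != n) {
    stop("length of 'subject_ids' must equal nrow(values)", call. = FALSE)
  }
  if (length(feature_labels) != p) {
    stop("length of 'feature_labels' must equal ncol(values)", call. = FALSE)
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-finite value at subject '%s', feature '%s' (modality '%s')",
      subject_ids[bad[1L, 1L]], feature_labels[bad[1L, 2L]], modality
    ), call. = FALSE)
  }
  if (anyDuplicated(subject_ids)) {
    stop(sprintf("duplicate subject id '%s'",
                 subject_ids[anyDuplicated(subject_ids)]), call. = FALSE)
  }
  if (anyDuplicated(feature_labels)) {
    stop(sprintf("duplicate feature label '%s'",
                 feature_labels[anyDuplicated(feature_labels)]),
         call. = FALSE)
  }
  dimnames(values) <- list(subject_ids, feature_labels)
  structure(
    list(values = values, subject_ids = subject_ids,
         feature_labels = feature_labels, modality = as.character(modality)),
    class = "fc2fs_feature_matrix"
  )
}

#' @export
print.fc2fs_feature_matrix <- function(x, ...) {
  cat(sprintf("<fc2fs_feature_matrix> modality '%s': %d subjects x %d features\n",
              x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a binary label vector
#'
#' Labels are coded -1/+1 so they can serve directly as least-squares
#' regression targets; +1 is the positive (disease) class.
#'
#' @param values Vector coercible to integer with entries in \{-1, +1\}.
#' @param positive_class_name Human-readable name of the +1 class.
#' @return An object of class `fc2fs_labels`.
#' @export
label_vector <- function(values, positive_class_name = "positive") {
  values <- as.integer(values)
  if (any(is.na(values)) || !all(values %in% c(-1L, 1L))) {
    stop("labels must be -1 or +1 with no missing values", call. = FALSE)
  }
  if (length(unique(values)) < 2L) {
    stop("both classes must be present in the labels", call. = FALSE)
  }
  structure(list(values = values,
                 positive_class_name = as.character(positive_class_name)),
            class = "fc2fs_labels")
}

#' Bundle aligned modalities and labels into a multi-modal dataset
#'
#' @param modalities List of [feature_matrix()] objects sharing identical
#'   subjects (same ids, same order) and identical feature labels.
#' @param labels A [label_vector()] with one entry per subject.
#' @return An object of class `fc2fs_dataset` with elements `modalities`,
#'   `labels`, `n_subjects`, `n_features`, `n_modalities`.
#' @seealso [validate_dataset()]
#' @export
multimodal_dataset <- function(modalities, labels) {
  if (inherits(modalities, "fc2fs_feature_matrix")) modalities <- list(modalities)
  if (!is.list(modalities) || length(modalities) < 1L) {
    stop("'modalities' must be a non-empty list of feature matrices",
         call. = FALSE)
  }
  for (mm in modalities) {
    if (!inherits(mm, "fc2fs_feature_matrix")) {
      stop("every modality must be a feature_matrix", call. = FALSE)
    }
  }
  if (!inherits(labels, "fc2fs_labels")) {
    stop("'labels' must be a label_vector", call. = FALSE)
  }
  d <- structure(
    list(modalities = modalities, labels = labels,
         n_subjects = nrow(modalities[[1L]]$values),
         n_features = ncol(modalities[[1L]]$values),
         n_modalities = length(modalities)),
    class = "fc2fs_dataset"
  )
  validate_dataset(d)
}

#' @export
print.fc2fs_dataset <- function(x, ...) {
  cat(sprintf("<fc2fs_dataset> %d modalities (%s), %d subjects, %d features\n",
              x$n_modalities,
              paste(vapply(x$modalities, `[[`, "", "modality"), collapse = ", "),
              x$n_subjects, x$n_features))
  invisible(x)
}

#' Validate a multi-modal dataset
#'
#' Checks that all modalities share identical subject ids in identical order,
#' identical feature labels, and that labels match the subject count with
#' both classes present. Accepted datasets are returned unchanged.
#'
#' @param d An `fc2fs_dataset`.
#' @return `d`, invisibly identical, if all invariants hold; otherwise an
#'   error describing the first violation.
#' @export
validate_dataset <- function(d) {
  if (!inherits(d, "fc2fs_dataset")) stop("not an fc2fs_dataset", call. = FALSE)
  ref <- d$modalities[[1L]]
  for (i in seq_along(d$modalities)) {
    mi <- d$modalities[[i]]
    if (ncol(mi$values) != ncol(ref$values)) {
      stop(sprintf(
        "modality '%s' has %d features but modality '%s' has %d",
        mi$modality, ncol(mi$values), ref$modality, ncol(ref$values)
      ), call. = FALSE)
    }
    if (!identical(mi$feature_labels, ref$feature_labels)) {
      stop(sprintf("feature labels of modality '%s' differ from '%s'",
                   mi$modality, ref$modality), call. = FALSE)
    }
    if (!identical(mi$subject_ids, ref$subject_ids)) {
      stop(sprintf(
        "subject ids of modality '%s' differ (or are ordered differently) from '%s'",
        mi$modality, ref$modality
      ), call. = FALSE)
    }
  }
  if (length(d$labels$values) != nrow(ref$values)) {
    stop(sprintf("label vector has %d entries but modalities have %d subjects",
                 length(d$labels$values), nrow(ref$values)), call. = FALSE)
  }
  d
}

#' Z-score normalize the columns of a feature matrix
#'
#' Standardizes each feature to mean 0 and unit standard deviation (sample
#' convention, denominator N-1). When `stats` is supplied — as it is for test
#' folds during cross-validation — the supplied transform is applied verbatim
#' instead of refitting, so no test-row information leaks into the scaling.
#'
#' @param X A [feature_matrix()] or plain numeric matrix.
#' @param stats Optional list with numeric vectors `mean` and `sd` (one entry
#'   per feature) from a previous call.
#' @return A list with `matrix` (same class as `X`, standardized) and `stats`
#'   (the per-feature `mean` and `sd` used).
#' @examples
#' fm <- feature_matrix(matrix(rnorm(20), 5, 4))
#' z <- zscore_normalize(fm)
#' colMeans(z$matrix$values)  # ~0
#' @export
zscore_normalize <- function(X, stats = NULL) {
  is_fm <- inherits(X, "fc2fs_feature_matrix")
  vals <- if (is_fm) X$values else X
  labs <- if (is_fm) X$feature_labels else colnames(vals)
  if (is.null(labs)) labs <- sprintf("F%03d", seq_len(ncol(vals)))
  if (is.null(stats)) {
    mu <- colMeans(vals)
    sdv <- apply(vals, 2L, stats::sd)
    zero <- which(sdv < .Machine$double.eps * 1e3)
    if (length(zero) > 0L) {
      stop(sprintf("feature '%s' has zero variance; cannot standardize",
                   labs[zero[1L]]), call. = FALSE)
    }
    stats <- list(mean = mu, sd = sdv)
  } else {
    if (length(stats$mean) != ncol(vals) || length(stats$sd) != ncol(vals)) {
      stop("supplied normalization stats do not match the number of features",
           call. = FALSE)
    }
  }
  out <- sweep(sweep(vals, 2L, stats$mean, "-"), 2L, stats$sd, "/")
  if (is_fm) {
    out <- feature_matrix(out, X$subject_ids, X$feature_labels, X$modality)
  }
  list(matrix = out, stats = stats)
}

#' Normalize every modality of a dataset
#'
#' Convenience wrapper applying [zscore_normalize()] per modality. Statistics
#' are fit on the full dataset; inside cross-validation use
#' [zscore_normalize()] with training-row statistics instead.
#'
#' @param d An `fc2fs_dataset`.
#' @param stats Optional list of per-modality stats (as returned previously).
#' @return List with `dataset` (standardized) and `stats` (per-modality).
#' @export
normalize_dataset <- function(d, stats = NULL) {
  validate_dataset(d)
  zs <- lapply(seq_along(d$modalities), function(i) {
    zscore_normalize(d$modalities[[i]], stats = stats[[i]])
  })
  d$modalities <- lapply(zs, `[[`, "matrix")
  list(dataset = d, stats = lapply(zs, `[[`, "stats"))
}

#' Hyperparameters for the feature-selection model
#'
#' Defaults follow the regime explored in the method's sensitivity analysis:
#' `alpha` and `beta` (the correlation and structure penalty weights) default
#' to 2^-2, the trace-norm weight `gamma` to 2^-1, and the modality fusion
#' coefficient `tau` to 0.3 (the sMRI weight; the second modality gets
#' 1 - tau). `top_k = 15` selected features mirrors the discriminative-region
#' reporting convention.
#'
#' @param alpha Weight of the feature-correlation penalty (>= 0).
#' @param beta Weight of the feature-structure (Laplacian) penalty (>= 0).
#' @param gamma Weight of the trace-norm penalty (>= 0; 0 disables the
#'   low-rank prox and reduces the solver to plain gradient descent).
#' @param tau Fusion coefficient in \[0, 1\] blending modality 1 and 2.
#' @param corr_method One of `"pearson"`, `"spearman"`, `"kendall"`.
#' @param knn_k Number of cosine nearest neighbours in the feature graph.
#' @param max_iter Maximum proximal-gradient iterations.
#' @param tol Relative loss-change convergence tolerance.
#' @param top_k Number of features to select.
#' @return An object of class `fc2fs_hyperparams`.
#' @export
hyperparams <- function(alpha = 2^-2, beta = 2^-2, gamma = 2^-1, tau = 0.3,
                        corr_method = c("pearson", "spearman", "kendall"),
                        knn_k = 5L, max_iter = 1000L, tol = 1e-6,
                        top_k = 15L) {
  corr_method <- match.arg(corr_method)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(beta), length(beta) == 1L, beta >= 0,
            is.numeric(gamma), length(gamma) == 1L, gamma >= 0,
            is.numeric(tau), length(tau) == 1L, tau >= 0, tau <= 1,
            knn_k >= 1L, max_iter >= 1L, tol > 0, top_k >= 1L)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, tau = tau,
                 corr_method = corr_method, knn_k = as.integer(knn_k),
                 max_iter = as.integer(max_iter), tol = tol,
                 top_k = as.integer(top_k)),
            class = "fc2fs_hyperparams")
}

#' @export
print.fc2fs_hyperparams <- function(x, ...) {
  cat(sprintf(
    "<fc2fs_hyperparams> alpha=%g beta=%g gamma=%g tau=%g corr=%s k=%d top_k=%d\n",
    x$alpha, x$beta, x$gamma, x$tau, x$corr_method, x$knn_k, x$top_k))
  invisible(x)
}
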
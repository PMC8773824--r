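# Regularizer constructions: per-modality feature-feature correlation
# matrices and their fusion, the tau-fused feature matrix, the cosine k-NN
# feature adjacency H, degree S, Laplacian L = S - H, and the two quadratic
# penalties tr(W'RW) and tr(W'LW).

#' Feature-feature correlation matrix of one modality
#'
#' Pairwise correlations between feature columns across subjects. The result
#' is symmetrized as (C + C')/2 with a unit diagonal to absorb floating-point
#' asymmetry. Spearman uses average ranks; Kendall is tau-b.
#'
#' @param X A [feature_matrix()] or numeric matrix (subjects x features).
#' @param method Correlation type: `"pearson"`, `"spearman"`, or `"kendall"`.
#' @param absolute If `TRUE`, take absolute values (signed correlations are
#'   the default).
#' @return p x p correlation matrix with attributes `method` and `modality`.
#' @export
correlation_matrix <- function(X, method = c("pearson", "spearman", "kendall"),
                               absolute = FALSE) {
  method <- match.arg(method)
  is_fm <- inherits(X, "fc2fs_feature_matrix")
  vals <- if (is_fm) X$values else X
  labs <- if (is_fm) X$feature_labels else colnames(vals)
  if (nrow(vals) < 2L) stop("need at least 2 subjects for correlations",
                            call. = FALSE)
  sdv <- apply(vals, 2L, stats::sd)
  cst <- which(sdv < .Machine$double.eps * 1e3)
  if (length(cst) > 0L) {
    lab <- if (!is.null(labs)) labs[cst[1L]] else as.character(cst[1L])
    stop(sprintf("feature '%s' is constant; correlation undefined", lab),
         call. = FALSE)
  }
  C <- stats::cor(vals, method = method)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  if (absolute) C <- abs(C)
  attr(C, "method") <- method
  attr(C, "modality") <- if (is_fm) X$modality else NA_character_
  C
}

#' Fuse per-modality correlation matrices
#'
#' Weighted average R = sum_i w_i R_i of the modality correlation matrices;
#' weights default to uniform 1/m.
#'
#' @param Rs List of p x p correlation matrices sharing dimensions.
#' @param weights Nonnegative weights, one per matrix, summing to 1; default
#'   uniform.
#' @return Symmetric p x p fused correlation matrix.
#' @export
fuse_correlations <- function(Rs, weights = NULL) {
  if (!is.list(Rs) || length(Rs) < 1L) stop("'Rs' must be a non-empty list",
                                            call. = FALSE)
  p <- ncol(Rs[[1L]])
  for (R in Rs) {
    if (!all(dim(R) == c(p, p))) {
      stop(sprintf("correlation matrices differ in shape: %dx%d vs %dx%d",
                   nrow(R), ncol(R), p, p), call. = FALSE)
    }
  }
  m <- length(Rs)
  if (is.null(weights)) weights <- rep(1 / m, m)
  if (length(weights) != m || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop("'weights' must be nonnegative, one per matrix, and sum to 1",
         call. = FALSE)
  }
  R <- matrix(0, p, p)
  for (i in seq_len(m)) R <- R + weights[i] * unclass(Rs[[i]])
  attributes(R) <- list(dim = dim(R))
  (R + t(R)) / 2
}

#' Blend aligned modality feature matrices
#'
#' For two modalities, returns `tau * X1 + (1 - tau) * X2`; for general m,
#' supply explicit `weights`. The blended matrix feeds the cosine feature
#' graph.
#'
#' @param Xs List of aligned [feature_matrix()] objects or numeric matrices.
#' @param tau Fusion coefficient in \[0, 1\] (weight of modality 1; two
#'   modalities only).
#' @param weights Explicit nonnegative per-modality weights summing to 1
#'   (overrides `tau`).
#' @return Numeric N x p blended matrix.
#' @export
fuse_feature_matrices <- function(Xs, tau = NULL, weights = NULL) {
  vals <- lapply(Xs, function(x) {
    if (inherits(x, "fc2fs_feature_matrix")) x$values else x
  })
  m <- length(vals)
  d1 <- dim(vals[[1L]])
  for (v in vals) {
    if (!all(dim(v) == d1)) stop("modality matrices are not aligned",
                                 call. = FALSE)
  }
  if (is.null(weights)) {
    if (m == 1L) {
      weights <- 1
    } else if (m == 2L) {
      if (is.null(tau)) stop("supply 'tau' (m = 2) or 'weights'", call. = FALSE)
      if (!is.numeric(tau) || tau < 0 || tau > 1) {
        stop(sprintf("tau must lie in [0, 1], got %g", tau), call. = FALSE)
      }
      weights <- c(tau, 1 - tau)
    } else {
      stop("for m > 2 modalities supply explicit 'weights'", call. = FALSE)
    }
  }
  if (length(weights) != m || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop("'weights' must be nonnegative, one per modality, and sum to 1",
         call. = FALSE)
  }
  out <- matrix(0, d1[1L], d1[2L])
  for (i in seq_len(m)) out <- out + weights[i] * vals[[i]]
  dimnames(out) <- dimnames(vals[[1L]])
  out
}

#' Cosine k-nearest-neighbour feature adjacency
#'
#' H_ij is the cosine similarity between feature columns i and j when either
#' is among the other's k most cosine-similar features (union
#' symmetrization), and 0 otherwise. Negative similarities are clipped to 0
#' by default so the resulting graph Laplacian is positive semidefinite.
#' The diagonal is 0.
#'
#' @param X Numeric N x p matrix (typically the tau-blended feature matrix).
#' @param k Number of nearest neighbours, `1 <= k < p`.
#' @param clip_negative Clip negative similarities to 0 (default `TRUE`).
#' @return Symmetric nonnegative p x p adjacency with zero diagonal.
#' @export
cosine_adjacency <- function(X, k = 5L, clip_negative = TRUE) {
  if (inherits(X, "fc2fs_feature_matrix")) X <- X$values
  p <- ncol(X)
  k <- as.integer(k)
  if (k < 1L || k >= p) {
    stop(sprintf("k must satisfy 1 <= k < p (= %d), got %d", p, k),
         call. = FALSE)
  }
  nrm <- sqrt(colSums(X^2))
  zero <- which(nrm < .Machine$double.eps * 1e3)
  if (length(zero) > 0L) {
    lab <- if (!is.null(colnames(X))) colnames(X)[zero[1L]]
           else as.character(zero[1L])
    stop(sprintf("feature '%s' has zero norm; cosine similarity undefined",
                 lab), call. = FALSE)
  }
  C <- crossprod(X) / tcrossprod(nrm)
  C <- (C + t(C)) / 2
  # union k-NN mask by similarity, self excluded
  mask <- matrix(FALSE, p, p)
  Cq <- C
  diag(Cq) <- -Inf
  for (i in seq_len(p)) {
    nb <- order(Cq[i, ], decreasing = TRUE)[seq_len(k)]
    mask[i, nb] <- TRUE
  }
  mask <- mask | t(mask)
  H <- ifelse(mask, C, 0)
  if (clip_negative) H <- pmax(H, 0)
  diag(H) <- 0
  dimnames(H) <- dimnames(C)
  H
}

#' Degree matrix and graph Laplacian of a feature adjacency
#'
#' S is diagonal with the row sums of H; the Laplacian is L = S - H. For a
#' symmetric nonnegative H the Laplacian is positive semidefinite with zero
#' row sums.
#'
#' @param H Symmetric nonnegative adjacency with zero diagonal.
#' @param tol Symmetry tolerance.
#' @return List with `S` (diagonal degree matrix) and `L` (Laplacian).
#' @export
graph_laplacian <- function(H, tol = 1e-8) {
  if (!is.matrix(H) || nrow(H) != ncol(H)) {
    stop("'H' must be a square matrix", call. = FALSE)
  }
  if (max(abs(H - t(H))) > tol) {
    stop("adjacency matrix is not symmetric within tolerance", call. = FALSE)
  }
  deg <- rowSums(H)
  S <- diag(deg, nrow = nrow(H))
  L <- S - H
  dimnames(S) <- dimnames(H)
  dimnames(L) <- dimnames(H)
  list(S = S, L = L)
}

#' Feature-correlation penalty tr(W' R W)
#'
#' @param W p x m weight matrix.
#' @param R Fused p x p correlation matrix.
#' @return Scalar penalty value.
#' @export
correlation_penalty <- function(W, R) {
  if (nrow(W) != nrow(R) || nrow(R) != ncol(R)) {
    stop(sprintf("shape mismatch: W is %dx%d, R is %dx%d",
                 nrow(W), ncol(W), nrow(R), ncol(R)), call. = FALSE)
  }
  sum(W * (R %*% W))
}

#' Feature-structure penalty tr(W' L W)
#'
#' Equals half the adjacency-weighted sum of squared row differences of W:
#' features adjacent in the graph are pushed toward similar weight rows.
#'
#' @param W p x m weight matrix.
#' @param L p x p graph Laplacian.
#' @return Scalar penalty value (>= 0 for a PSD Laplacian).
#' @export
structure_penalty <- function(W, L) {
  if (nrow(W) != nrow(L) || nrow(L) != ncol(L)) {
    stop(sprintf("shape mismatch: W is %dx%d, L is %dx%d",
                 nrow(W), ncol(W), nrow(L), ncol(L)), call. = FALSE)
  }
  sum(W * (L %*% W))
}

#' Build the regularizer bundle for a dataset
#'
#' Computes per-modality feature correlation matrices and their weighted
#' average R, blends the modality feature matrices with `tau`, and builds the
#' cosine k-NN adjacency H, degree S, and Laplacian L from the blend.
#' Expects normalized modalities.
#'
#' @param d A validated, normalized `fc2fs_dataset`.
#' @param hp A [hyperparams()] object (`corr_method`, `tau`, `knn_k` used).
#' @param modality_weights Weights for the correlation fusion (default
#'   uniform) and, for m > 2, for the feature-matrix blend.
#' @param absolute_correlation Use |r| instead of signed correlations.
#' @param clip_negative Clip negative cosine similarities in H.
#' @return An object of class `fc2fs_bundle`: list with `R`, `H`, `S`, `L`,
#'   `tau`, `modality_weights`, `corr_method`, `per_modality_R`.
#' @export
build_regularizers <- function(d, hp = hyperparams(), modality_weights = NULL,
                               absolute_correlation = FALSE,
                               clip_negative = TRUE) {
  validate_dataset(d)
  m <- d$n_modalities
  if (is.null(modality_weights)) modality_weights <- rep(1 / m, m)
  Rs <- lapply(d$modalities, correlation_matrix, method = hp$corr_method,
               absolute = absolute_correlation)
  R <- fuse_correlations(Rs, modality_weights)
  Xf <- if (m == 2L) {
    fuse_feature_matrices(d$modalities, tau = hp$tau)
  } else {
    fuse_feature_matrices(d$modalities, weights = modality_weights)
  }
  H <- cosine_adjacency(Xf, k = hp$knn_k, clip_negative = clip_negative)
  lap <- graph_laplacian(H)
  structure(list(R = R, H = H, S = lap$S, L = lap$L, tau = hp$tau,
                 modality_weights = modality_weights,
                 corr_method = hp$corr_method, per_modality_R = Rs),
            class = "fc2fs_bundle")
}

#' @export
print.fc2fs_bundle <- function(x, ...) {
  cat(sprintf(
    "<fc2fs_bundle> p=%d features, corr=%s, tau=%g, %d graph edges\n",
    nrow(x$R), x$corr_method, x$tau, sum(x$H > 0) / 2))
  invisible(x)
}
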
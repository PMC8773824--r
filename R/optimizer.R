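# The joint loss and its proximal-gradient solver. The objective over the
# p x m weight matrix W = [w_1, ..., w_m] is
#
#   sum_i ||Y - X_i w_i||^2 + alpha tr(W'RW) + beta tr(W'LW) + gamma ||W||_*
#
# with X_i the (normalized) modality matrices, Y the -1/+1 labels, R the
# fused feature-correlation matrix, L the feature-graph Laplacian and
# ||.||_* the trace (nuclear) norm. The smooth part is handled by gradient
# steps with backtracking; the trace norm by its prox, singular-value
# soft-thresholding.

#' Trace (nuclear) norm
#'
#' Sum of the singular values of a matrix — the convex surrogate for rank
#' used by the low-rank penalty.
#'
#' @param W Numeric matrix.
#' @return Nonnegative scalar.
#' @examples
#' trace_norm(diag(c(3, 1)))  # 4
#' @export
trace_norm <- function(W) {
  if (!is.matrix(W)) W <- as.matrix(W)
  sum(svd(W, nu = 0L, nv = 0L)$d)
}

#' Singular-value soft-thresholding (prox of the trace norm)
#'
#' Computes `U max(D - t, 0) V'` from the thin SVD `U D V'` of `Z`. This is
#' the unique minimizer of `0.5 ||W - Z||_F^2 + t ||W||_*`, so it shrinks
#' singular values and can only lower rank.
#'
#' @param Z Numeric matrix.
#' @param t Nonnegative threshold.
#' @return Matrix of the same shape as `Z`.
#' @examples
#' svt_prox(diag(c(3, 1)), 1)  # diag(2, 0)
#' @export
svt_prox <- function(Z, t) {
  if (!is.matrix(Z)) Z <- as.matrix(Z)
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop("threshold 't' must be a single nonnegative number", call. = FALSE)
  }
  sv <- svd(Z)
  dshr <- pmax(sv$d - t, 0)
  out <- sv$u %*% (dshr * t(sv$v))
  dimnames(out) <- dimnames(Z)
  out
}

# spectral norm (largest singular value) by power iteration on A'A
.spectral_norm <- function(A, iter = 100L, tol = 1e-10) {
  A <- as.matrix(A)
  v <- rep(1 / sqrt(ncol(A)), ncol(A))
  lam <- 0
  for (i in seq_len(iter)) {
    w <- crossprod(A, A %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v_new <- w / nw
    if (sqrt(sum((v_new - v)^2)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  sqrt(sum((A %*% v)^2))
}

.eta_parts <- function(W, Xs, y, bundle, hp) {
  resid <- 0
  for (i in seq_along(Xs)) {
    r <- y - Xs[[i]] %*% W[, i]
    resid <- resid + sum(r^2)
  }
  corr <- hp$alpha * correlation_penalty(W, bundle$R)
  struct <- hp$beta * structure_penalty(W, bundle$L)
  c(residual = resid, correlation = corr, structure = struct)
}

#' Evaluate the full loss and its four components
#'
#' @param W p x m weight matrix.
#' @param d Validated, normalized `fc2fs_dataset`.
#' @param bundle Regularizer bundle from [build_regularizers()].
#' @param hp [hyperparams()] supplying `alpha`, `beta`, `gamma`.
#' @return List with `total`, `residual`, `correlation`, `structure`,
#'   `trace_norm` (each already weighted by its coefficient).
#' @export
fc2fs_loss <- function(W, d, bundle, hp = hyperparams()) {
  Xs <- lapply(d$modalities, `[[`, "values")
  if (nrow(W) != d$n_features || ncol(W) != d$n_modalities) {
    stop(sprintf("W must be %d x %d, got %d x %d",
                 d$n_features, d$n_modalities, nrow(W), ncol(W)),
         call. = FALSE)
  }
  y <- as.numeric(d$labels$values)
  parts <- .eta_parts(W, Xs, y, bundle, hp)
  tn <- hp$gamma * trace_norm(W)
  list(total = sum(parts) + tn,
       residual = unname(parts["residual"]),
       correlation = unname(parts["correlation"]),
       structure = unname(parts["structure"]),
       trace_norm = tn)
}

#' Gradient of the smooth part of the loss
#'
#' Column i is `2 X_i'(X_i w_i - Y) + 2 alpha (R W)_i + 2 beta (L W)_i`; the
#' trace norm is excluded (it is handled by the prox).
#'
#' @inheritParams fc2fs_loss
#' @return p x m gradient matrix.
#' @export
smooth_gradient <- function(W, d, bundle, hp = hyperparams()) {
  if (nrow(W) != d$n_features || ncol(W) != d$n_modalities) {
    stop(sprintf("W must be %d x %d, got %d x %d",
                 d$n_features, d$n_modalities, nrow(W), ncol(W)),
         call. = FALSE)
  }
  y <- as.numeric(d$labels$values)
  G <- matrix(0, nrow(W), ncol(W))
  for (i in seq_along(d$modalities)) {
    Xi <- d$modalities[[i]]$values
    G[, i] <- 2 * crossprod(Xi, Xi %*% W[, i] - y)
  }
  G + 2 * hp$alpha * (bundle$R %*% W) + 2 * hp$beta * (bundle$L %*% W)
}

#' Fit the multi-modal feature-selection model
#'
#' Proximal-gradient descent on the joint loss: at each iteration a gradient
#' step on the smooth part is followed by singular-value soft-thresholding
#' with threshold `gamma / s` (the step-scaled prox of the trace norm). The
#' step length `s` starts at a Lipschitz estimate
#' `2 (max_i sigma_max(X_i)^2 + alpha sigma_max(R) + beta sigma_max(L))` and
#' is doubled (backtracking) whenever the smooth part exceeds its quadratic
#' majorizer, which guarantees a non-increasing loss. Iteration stops when
#' the relative loss change falls below `hp$tol` or after `hp$max_iter`
#' iterations.
#'
#' @param d Validated, normalized `fc2fs_dataset`.
#' @param bundle Regularizer bundle from [build_regularizers()]; built from
#'   `d` if `NULL`.
#' @param hp A [hyperparams()] object.
#' @param W0 Optional p x m starting matrix (default all zeros).
#' @param backtrack_factor Multiplier applied to `s` on a failed
#'   majorization check (default 2).
#' @return An object of class `fc2fs_model`: list with `W`, `hyperparams`,
#'   `loss_history` (loss at `W0` followed by one value per iteration),
#'   `n_iter`, `converged`, `step_lengths`, `feature_labels`, `modalities`.
#' @examples
#' sim <- generate_dataset(synthetic_spec(n_subjects = 40, n_features = 10,
#'                                        support_size = 3, block_size = 5,
#'                                        seed = 1))
#' d <- normalize_dataset(sim$dataset)$dataset
#' fit <- fit_fc2fs(d, hp = hyperparams(max_iter = 50))
#' fit$converged
#' @export
fit_fc2fs <- function(d, bundle = NULL, hp = hyperparams(), W0 = NULL,
                      backtrack_factor = 2) {
  validate_dataset(d)
  if (is.null(bundle)) bundle <- build_regularizers(d, hp)
  p <- d$n_features
  m <- d$n_modalities
  Xs <- lapply(d$modalities, `[[`, "values")
  y <- as.numeric(d$labels$values)
  if (is.null(W0)) W0 <- matrix(0, p, m)
  if (!all(dim(W0) == c(p, m))) {
    stop(sprintf("W0 must be %d x %d", p, m), call. = FALSE)
  }

  lam_min <- min(eigen(bundle$R, symmetric = TRUE, only.values = TRUE)$values)
  if (lam_min < -1e-8) {
    warning(sprintf(
      "fused correlation matrix is indefinite (lambda_min = %.3e); loss may be locally nonconvex",
      lam_min))
  }

  XtX <- lapply(Xs, crossprod)
  Xty <- lapply(Xs, function(X) crossprod(X, y))
  eta <- function(W) {
    v <- 0
    for (i in seq_len(m)) {
      r <- y - Xs[[i]] %*% W[, i]
      v <- v + sum(r^2)
    }
    v + hp$alpha * sum(W * (bundle$R %*% W)) +
      hp$beta * sum(W * (bundle$L %*% W))
  }
  grad <- function(W) {
    G <- matrix(0, p, m)
    for (i in seq_len(m)) G[, i] <- 2 * (XtX[[i]] %*% W[, i] - Xty[[i]])
    G + 2 * hp$alpha * (bundle$R %*% W) + 2 * hp$beta * (bundle$L %*% W)
  }

  s <- 2 * (max(vapply(Xs, .spectral_norm, 0)^2) +
              hp$alpha * .spectral_norm(bundle$R) +
              hp$beta * .spectral_norm(bundle$L))
  if (!is.finite(s) || s <= 0) s <- 1

  W <- W0
  eta_W <- eta(W)
  loss <- eta_W + hp$gamma * trace_norm(W)
  loss_history <- loss
  step_lengths <- numeric(0)
  converged <- FALSE
  n_iter <- 0L

  for (k in seq_len(hp$max_iter)) {
    G <- grad(W)
    repeat {
      Z <- W - G / s
      Wn <- svt_prox(Z, hp$gamma / s)
      dW <- Wn - W
      eta_Wn <- eta(Wn)
      Qval <- eta_W + sum(G * dW) + (s / 2) * sum(dW^2)
      if (eta_Wn <= Qval + 1e-12 * max(1, abs(Qval))) break
      s <- s * backtrack_factor
      if (!is.finite(s)) {
        stop(sprintf("backtracking diverged at iteration %d (s = %g)", k, s),
             call. = FALSE)
      }
    }
    loss_new <- eta_Wn + hp$gamma * trace_norm(Wn)
    if (!is.finite(loss_new)) {
      stop(sprintf("non-finite loss at iteration %d (step length s = %g)",
                   k, s), call. = FALSE)
    }
    step_lengths <- c(step_lengths, s)
    n_iter <- k
    W <- Wn
    eta_W <- eta_Wn
    rel <- abs(loss - loss_new) / max(1, abs(loss))
    loss <- loss_new
    loss_history <- c(loss_history, loss_new)
    if (rel < hp$tol) {
      converged <- TRUE
      break
    }
  }

  dimnames(W) <- list(d$modalities[[1L]]$feature_labels,
                      vapply(d$modalities, `[[`, "", "modality"))
  structure(
    list(W = W, hyperparams = hp, loss_history = loss_history,
         n_iter = n_iter, converged = converged, step_lengths = step_lengths,
         feature_labels = d$modalities[[1L]]$feature_labels,
         modalities = vapply(d$modalities, `[[`, "", "modality")),
    class = "fc2fs_model"
  )
}

#' @export
print.fc2fs_model <- function(x, ...) {
  cat(sprintf(
    "<fc2fs_model> W: %d x %d; %d iterations (%s); final loss %.6g\n",
    nrow(x$W), ncol(x$W), x$n_iter,
    if (x$converged) "converged" else "max_iter reached",
    x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' One-call pipeline: normalize, build regularizers, fit, rank
#'
#' Standalone fit on a full dataset (normalization statistics are computed on
#' all rows; inside cross-validation the pipeline is instead refit per
#' training fold). Returns the fitted model together with the feature
#' ranking.
#'
#' @param d An `fc2fs_dataset` (raw scale).
#' @param hp A [hyperparams()] object.
#' @param ... Passed to [build_regularizers()].
#' @return List with `model`, `selection`, `bundle`, `norm_stats`.
#' @export
fc2fs <- function(d, hp = hyperparams(), ...) {
  nz <- normalize_dataset(d)
  bundle <- build_regularizers(nz$dataset, hp, ...)
  model <- fit_fc2fs(nz$dataset, bundle, hp)
  sel <- select_top_k(rank_features(model), hp$top_k)
  list(model = model, selection = sel, bundle = bundle,
       norm_stats = nz$stats)
}

#' Save a fitted model to a portable JSON file
#'
#' Serializes `W`, the hyperparameters, loss history, convergence state and
#' labels; [load_model()] restores an equivalent `fc2fs_model`.
#'
#' @param model An `fc2fs_model`.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fc2fs_model"))
  obj <- list(
    W = unname(model$W),
    feature_labels = model$feature_labels,
    modalities = model$modalities,
    hyperparams = unclass(model$hyperparams),
    loss_history = model$loss_history,
    n_iter = model$n_iter,
    converged = model$converged,
    step_lengths = model$step_lengths
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Path to the JSON file.
#' @return An `fc2fs_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(obj$W)
  dimnames(W) <- list(obj$feature_labels, obj$modalities)
  hp <- do.call(hyperparams, as.list(obj$hyperparams))
  structure(
    list(W = W, hyperparams = hp, loss_history = as.numeric(obj$loss_history),
         n_iter = as.integer(obj$n_iter), converged = isTRUE(obj$converged),
         step_lengths = as.numeric(obj$step_lengths),
         feature_labels = obj$feature_labels, modalities = obj$modalities),
    class = "fc2fs_model"
  )
}
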
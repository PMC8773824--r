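# Seeded generator of multi-modal datasets with planted structure: features
# drawn from a block-equicorrelated Gaussian model (so feature-correlation
# and feature-graph penalties are non-trivial), a second modality formed by
# mixing the first with an independent draw (controllable cross-modal
# correlation), and labels from the sign of a noisy linear score through a
# known low-rank, row-sparse weight matrix.

#' Specification of a synthetic multi-modal dataset
#'
#' Defaults mirror the scale of ROI-level neuroimaging studies: 120 subjects,
#' 90 ROI features (one per atlas region), two modalities, 15 truly
#' informative ROIs, correlated feature blocks of 5 with pairwise correlation
#' 0.5, a rank-2 weight matrix, label-noise sd 0.5, and cross-modal mixing
#' 0.5.
#'
#' @param n_subjects Number of subjects N.
#' @param n_features Number of ROI features p (block_size must divide it).
#' @param n_modalities Number of modalities m.
#' @param support_size Number of truly informative features k (<= p).
#' @param block_size Size of each equicorrelated feature block.
#' @param within_block_rho Pairwise correlation inside a block, in \[0, 1).
#' @param weight_rank Rank of the planted weight matrix,
#'   <= min(support_size, n_modalities).
#' @param noise_sd Standard deviation of the additive label noise (>= 0).
#' @param mixing_tau Mixing weight in \[0, 1\]: modality i > 1 equals
#'   `mixing_tau * modality1 + (1 - mixing_tau) * independent draw`.
#' @param seed Integer RNG seed.
#' @return An object of class `fc2fs_synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 120L, n_features = 90L,
                           n_modalities = 2L, support_size = 15L,
                           block_size = 5L, within_block_rho = 0.5,
                           weight_rank = 2L, noise_sd = 0.5,
                           mixing_tau = 0.5, seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               n_features = as.integer(n_features),
               n_modalities = as.integer(n_modalities),
               support_size = as.integer(support_size),
               block_size = as.integer(block_size),
               within_block_rho = within_block_rho,
               weight_rank = as.integer(weight_rank),
               noise_sd = noise_sd, mixing_tau = mixing_tau,
               seed = as.integer(seed))
  if (spec$n_subjects < 2L || spec$n_features < 2L || spec$n_modalities < 1L) {
    stop("need at least 2 subjects, 2 features, and 1 modality", call. = FALSE)
  }
  if (spec$support_size < 1L || spec$support_size > spec$n_features) {
    stop("support_size must lie in [1, n_features]", call. = FALSE)
  }
  if (spec$n_features %% spec$block_size != 0L) {
    stop(sprintf("block_size (%d) must divide n_features (%d)",
                 spec$block_size, spec$n_features), call. = FALSE)
  }
  if (spec$within_block_rho < 0 || spec$within_block_rho >= 1) {
    stop("within_block_rho must lie in [0, 1)", call. = FALSE)
  }
  if (spec$weight_rank < 1L ||
      spec$weight_rank > min(spec$support_size, spec$n_modalities)) {
    stop("weight_rank must lie in [1, min(support_size, n_modalities)]",
         call. = FALSE)
  }
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (spec$mixing_tau < 0 || spec$mixing_tau > 1) {
    stop("mixing_tau must lie in [0, 1]", call. = FALSE)
  }
  structure(spec, class = "fc2fs_synthetic_spec")
}

#' Planted low-rank, row-sparse weight matrix
#'
#' Builds `W = A B'` with A (p x rank) zero outside the support rows and
#' Gaussian inside, and B (m x rank) Gaussian — so W has exactly the given
#' rank and its nonzero rows are exactly the support.
#'
#' @param p Number of features.
#' @param m Number of modalities.
#' @param support Integer indices of the informative features.
#' @param rank Desired rank, <= min(length(support), m).
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return p x m numeric matrix.
#' @export
generate_true_weights <- function(p, m, support, rank, seed = NULL) {
  support <- sort(unique(as.integer(support)))
  if (any(support < 1L) || any(support > p)) {
    stop("support indices must lie in [1, p]", call. = FALSE)
  }
  if (rank < 1L || rank > min(length(support), m)) {
    stop("rank must lie in [1, min(|support|, m)]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  repeat {
    A <- matrix(0, p, rank)
    A[support, ] <- stats::rnorm(length(support) * rank)
    B <- matrix(stats::rnorm(m * rank), m, rank)
    W <- A %*% t(B)
    sv <- svd(W, nu = 0L, nv = 0L)$d
    # Gaussian draws are almost surely rank-complete; guard the null set
    if (sum(sv > 1e-10 * max(sv, 1)) == rank &&
        all(rowSums(abs(W[support, , drop = FALSE])) > 0)) {
      return(W)
    }
  }
}

# n x p draw with equicorrelated blocks: unit variance, correlation rho
# inside each block of size bs, independent across blocks
.block_gaussian <- function(n, p, bs, rho) {
  nb <- p %/% bs
  common <- matrix(stats::rnorm(n * nb), n, nb)
  idio <- matrix(stats::rnorm(n * p), n, p)
  sqrt(rho) * common[, rep(seq_len(nb), each = bs), drop = FALSE] +
    sqrt(1 - rho) * idio
}

#' Generate a synthetic multi-modal dataset with known ground truth
#'
#' Modality 1 is a block-equicorrelated Gaussian draw; each further modality
#' mixes modality 1 with an independent draw using `mixing_tau`. Labels are
#' `sign(mean_i X_i w_i + eps)` with Gaussian noise of sd `noise_sd` through
#' the planted weight matrix; an exact zero score is resolved to +1.
#' Identical seeds give identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (an `fc2fs_dataset`) and `truth` (list with
#'   `true_support`, `true_W`, `scores`, `noise`, `spec`).
#' @examples
#' sim <- generate_dataset(synthetic_spec(n_subjects = 40, n_features = 10,
#'                                        support_size = 3, block_size = 5,
#'                                        seed = 42))
#' sim$truth$true_support
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "fc2fs_synthetic_spec")) {
    stop("'spec' must come from synthetic_spec()", call. = FALSE)
  }
  n <- spec$n_subjects; p <- spec$n_features; m <- spec$n_modalities
  set.seed(spec$seed)
  support <- sort(sample.int(p, spec$support_size))
  true_W <- generate_true_weights(p, m, support, spec$weight_rank)

  mats <- vector("list", m)
  mats[[1L]] <- .block_gaussian(n, p, spec$block_size, spec$within_block_rho)
  if (m > 1L) {
    for (i in 2:m) {
      fresh <- .block_gaussian(n, p, spec$block_size, spec$within_block_rho)
      mats[[i]] <- spec$mixing_tau * mats[[1L]] +
        (1 - spec$mixing_tau) * fresh
    }
  }

  score <- rowMeans(vapply(seq_len(m),
                           function(i) as.numeric(mats[[i]] %*% true_W[, i]),
                           numeric(n)))
  noise <- stats::rnorm(n, 0, spec$noise_sd)
  y <- sign(score + noise)
  y[y == 0] <- 1
  if (length(unique(y)) < 2L) {
    stop("degenerate draw: one class is empty; change the seed or spec",
         call. = FALSE)
  }

  ids <- sprintf("S%03d", seq_len(n))
  labs <- sprintf("ROI%03d", seq_len(p))
  mod_names <- if (m == 2L) c("sMRI", "PET") else sprintf("modality%d",
                                                          seq_len(m))
  modalities <- lapply(seq_len(m), function(i) {
    feature_matrix(mats[[i]], ids, labs, mod_names[i])
  })
  dataset <- multimodal_dataset(
    modalities, label_vector(y, positive_class_name = "case"))
  list(dataset = dataset,
       truth = list(true_support = support, true_W = true_W, scores = score,
                    noise = noise, spec = spec))
}

#' Write a synthetic dataset to disk
#'
#' One CSV per modality, a labels CSV, and a ground-truth JSON sidecar
#' (support indices, planted W, spec) — the on-disk layout the readers in
#' this package expect.
#'
#' @param sim Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- sim$dataset
  paths <- character(0)
  for (mm in d$modalities) {
    pth <- file.path(dir, paste0(mm$modality, ".csv"))
    write_modality_matrix(mm, pth)
    paths <- c(paths, pth)
  }
  lab_path <- file.path(dir, "labels.csv")
  write_labels(d$labels, d$modalities[[1L]]$subject_ids, lab_path)
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(true_support = sim$truth$true_support,
         true_W = unname(sim$truth$true_W),
         spec = unclass(sim$truth$spec)),
    truth_path, digits = NA, auto_unbox = TRUE)
  invisible(c(paths, lab_path, truth_path))
}
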
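# Evaluation layer: confusion-matrix metrics, rank-based AUC, stratified
# k-fold cross-validation around the full selection pipeline with a linear
# SVM back-end, and hyperparameter grid search. Inside cross-validation
# every data-dependent step (normalization statistics, correlation matrices,
# feature graph, model fit, feature selection) is computed from training
# rows only.

#' Confusion counts for -1/+1 labels
#'
#' @param y_true True labels in \{-1, +1\} (+1 is the positive class).
#' @param y_pred Predicted labels in \{-1, +1\}.
#' @return List of class `fc2fs_confusion` with integer `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% c(-1L, 1L)) || !all(y_pred %in% c(-1L, 1L))) {
    stop("labels must be -1 or +1", call. = FALSE)
  }
  structure(list(
    TP = sum(y_true == 1L & y_pred == 1L),
    TN = sum(y_true == -1L & y_pred == -1L),
    FP = sum(y_true == -1L & y_pred == 1L),
    FN = sum(y_true == 1L & y_pred == -1L)
  ), class = "fc2fs_confusion")
}

#' Rank-based AUC
#'
#' Probability that a random positive subject scores higher than a random
#' negative one, with ties credited 0.5 — computed from average ranks
#' (Mann–Whitney form), which equals brute-force enumeration over all
#' (negative, positive) pairs.
#'
#' @param scores Real decision scores, larger = more positive.
#' @param y_true Labels in \{-1, +1\}; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, y_true) {
  y_true <- as.integer(y_true)
  if (length(scores) != length(y_true)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == -1L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[y_true == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics from confusion counts
#'
#' ACC = (TP+TN)/total, SEN = TP/(TP+FN), SPE = TN/(TN+FP),
#' F1 = 2TP/(2TP+FP+FN), GMean = sqrt(SEN * SPE), and AUC from `scores` when
#' provided. A ratio with a zero denominator is returned as 0 and its name
#' recorded in `degenerate`. `gmean_as_printed = TRUE` instead returns the
#' plain sum SEN + SPE (an alternative definition that can exceed 1; kept
#' for comparability, not recommended).
#'
#' @param counts An `fc2fs_confusion` from [confusion_counts()].
#' @param scores Optional decision scores for AUC.
#' @param y_true Labels matching `scores` (required when `scores` given).
#' @param gmean_as_printed Use SEN + SPE instead of sqrt(SEN * SPE).
#' @return List with `ACC`, `AUC` (`NA` without scores), `SEN`, `SPE`,
#'   `GMean`, `F1`, and `degenerate` (character vector of zero-denominator
#'   metrics).
#' @examples
#' m <- compute_metrics(confusion_counts(rep(c(1, -1), c(10, 10)),
#'                                       rep(c(1, -1, 1, -1), c(9, 1, 2, 8))))
#' @export
compute_metrics <- function(counts, scores = NULL, y_true = NULL,
                            gmean_as_printed = FALSE) {
  stopifnot(inherits(counts, "fc2fs_confusion"))
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total <= 0L) stop("no evaluated subjects", call. = FALSE)
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else num / den
  }
  sen <- safe(TP, TP + FN, "SEN")
  spe <- safe(TN, TN + FP, "SPE")
  f1 <- safe(2 * TP, 2 * TP + FP + FN, "F1")
  gmean <- if (gmean_as_printed) sen + spe else sqrt(sen * spe)
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(y_true)) stop("y_true is required to compute AUC from scores",
                              call. = FALSE)
    auc <- rank_auc(scores, y_true)
  }
  list(ACC = (TP + TN) / total, AUC = auc, SEN = sen, SPE = spe,
       GMean = gmean, F1 = f1, degenerate = degenerate)
}

#' Stratified fold assignments
#'
#' Assigns each subject to one of `n_folds` folds, separately within each
#' class so class proportions are preserved, reshuffled independently per
#' repeat. Fully determined by `seed` and the labels (feature values are
#' never consulted).
#'
#' @param y Labels in \{-1, +1\}.
#' @param n_folds Number of folds.
#' @param n_repeats Number of independent reshuffles.
#' @param seed RNG seed.
#' @return List of length `n_repeats`; each element is an integer vector of
#'   fold ids (1..n_folds), one per subject.
#' @export
make_stratified_folds <- function(y, n_folds = 10L, n_repeats = 10L,
                                  seed = 1L) {
  y <- as.integer(y)
  n_folds <- as.integer(n_folds)
  for (cls in c(-1L, 1L)) {
    if (sum(y == cls) < n_folds) {
      stop(sprintf(
        "class %d has only %d members; cannot stratify into %d folds",
        cls, sum(y == cls), n_folds), call. = FALSE)
    }
  }
  set.seed(seed)
  lapply(seq_len(n_repeats), function(r) {
    fold <- integer(length(y))
    for (cls in c(-1L, 1L)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

# fused selected-feature block from plain value matrices (used per CV fold,
# where the test split may be arbitrarily small)
.fused_selected <- function(values_list, sel, tau, mode) {
  if (mode == "blend") {
    Xf <- if (length(values_list) == 1L) {
      values_list[[1L]]
    } else if (length(values_list) == 2L) {
      tau * values_list[[1L]] + (1 - tau) * values_list[[2L]]
    } else {
      Reduce(`+`, values_list) / length(values_list)
    }
    Xf[, sel, drop = FALSE]
  } else {
    do.call(cbind, lapply(values_list, function(v) v[, sel, drop = FALSE]))
  }
}

# linear-SVM decision scores oriented so that larger = class +1
.svm_scores <- function(fit, newx) {
  pred <- stats::predict(fit, newx, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  score <- dv[, 1L]
  if (first != "1") score <- -score
  list(pred = as.integer(as.character(pred)), score = as.numeric(score))
}

#' Cross-validated evaluation of the full pipeline
#'
#' Repeated stratified k-fold cross-validation. For every fold the pipeline
#' is refit from scratch on the training rows only: z-score statistics,
#' correlation matrices, the feature graph, the weight-matrix fit, feature
#' ranking and selection. Test rows are standardized with the training
#' statistics, reduced to the selected fused features, and scored by a
#' linear SVM (cost `svm_cost`) trained on the fused training features;
#' decision values feed the AUC.
#'
#' @param d An `fc2fs_dataset` on its raw scale.
#' @param hp A [hyperparams()] object.
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats Number of repeats with reshuffled folds (default 10).
#' @param seed RNG seed controlling the fold assignments (the only source of
#'   randomness).
#' @param svm_cost Linear-SVM cost parameter (default 1).
#' @param fusion_mode `"blend"` or `"concat"` for the selected features.
#' @return An object of class `fc2fs_eval`: `folds` (one row per
#'   repeat x fold with counts and metrics), `aggregate` (mean and sd per
#'   metric over all folds x repeats), `W_per_fold` (fitted weight matrices,
#'   for audit), `selected_per_fold`, and `config`.
#' @export
cross_validate <- function(d, hp = hyperparams(), n_folds = 10L,
                           n_repeats = 10L, seed = 1L, svm_cost = 1,
                           fusion_mode = c("blend", "concat")) {
  fusion_mode <- match.arg(fusion_mode)
  validate_dataset(d)
  y <- d$labels$values
  folds <- make_stratified_folds(y, n_folds, n_repeats, seed)
  vals <- lapply(d$modalities, `[[`, "values")
  mods <- vapply(d$modalities, `[[`, "", "modality")

  rows <- list()
  W_per_fold <- list()
  selected_per_fold <- list()
  for (r in seq_len(n_repeats)) {
    for (f in seq_len(n_folds)) {
      test <- which(folds[[r]] == f)
      train <- which(folds[[r]] != f)

      norm <- lapply(vals, function(v) {
        tr <- zscore_normalize(v[train, , drop = FALSE])
        te <- zscore_normalize(v[test, , drop = FALSE], stats = tr$stats)
        list(train = tr$matrix, test = te$matrix)
      })
      train_d <- multimodal_dataset(
        lapply(seq_along(norm), function(i) {
          feature_matrix(norm[[i]]$train,
                         d$modalities[[i]]$subject_ids[train],
                         d$modalities[[i]]$feature_labels, mods[i])
        }),
        label_vector(y[train], d$labels$positive_class_name)
      )
      bundle <- build_regularizers(train_d, hp)
      model <- fit_fc2fs(train_d, bundle, hp)
      sel <- select_top_k(rank_features(model),
                          min(hp$top_k, d$n_features))

      F_train <- .fused_selected(lapply(norm, `[[`, "train"), sel$selected,
                                 hp$tau, fusion_mode)
      F_test <- .fused_selected(lapply(norm, `[[`, "test"), sel$selected,
                                hp$tau, fusion_mode)
      fit <- e1071::svm(F_train, factor(y[train], levels = c(-1L, 1L)),
                        kernel = "linear", cost = svm_cost, scale = FALSE)
      out <- .svm_scores(fit, F_test)
      counts <- confusion_counts(y[test], out$pred)
      met <- compute_metrics(counts, scores = out$score, y_true = y[test])

      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, fold = f, n_test = length(test),
        TP = counts$TP, TN = counts$TN, FP = counts$FP, FN = counts$FN,
        ACC = met$ACC, AUC = met$AUC, SEN = met$SEN, SPE = met$SPE,
        GMean = met$GMean, F1 = met$F1
      )
      W_per_fold[[length(W_per_fold) + 1L]] <- model$W
      selected_per_fold[[length(selected_per_fold) + 1L]] <- sel$selected
    }
  }
  folds_df <- do.call(rbind, rows)
  metric_names <- c("ACC", "AUC", "SEN", "SPE", "GMean", "F1")
  aggregate <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(mn) mean(folds_df[[mn]]), 0),
    sd = vapply(metric_names, function(mn) stats::sd(folds_df[[mn]]), 0),
    row.names = NULL
  )
  structure(
    list(folds = folds_df, aggregate = aggregate, W_per_fold = W_per_fold,
         selected_per_fold = selected_per_fold,
         config = list(hyperparams = hp, n_folds = n_folds,
                       n_repeats = n_repeats, seed = seed,
                       svm_cost = svm_cost, fusion_mode = fusion_mode)),
    class = "fc2fs_eval"
  )
}

#' @export
print.fc2fs_eval <- function(x, ...) {
  agg <- x$aggregate
  cat(sprintf("<fc2fs_eval> %d folds x %d repeats\n",
              x$config$n_folds, x$config$n_repeats))
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-5s %.4f +/- %.4f\n", agg$metric[i], agg$mean[i],
                agg$sd[i]))
  }
  invisible(x)
}

#' Hyperparameter grid search by cross-validated accuracy
#'
#' Evaluates every combination of the supplied grids with
#' [cross_validate()], all sharing the same fold seed so points are
#' comparable. The winner maximizes mean ACC; ties are broken toward larger
#' `alpha`, then `beta`, then `gamma`, then smaller `tau`.
#'
#' @param d An `fc2fs_dataset`.
#' @param alpha,beta,gamma,tau,corr_method Grid values (each may be a single
#'   value); defaults come from `hp_base`.
#' @param hp_base Baseline [hyperparams()] supplying everything not swept.
#' @param n_folds,n_repeats,seed,svm_cost Passed to [cross_validate()].
#' @return List with `best` (a [hyperparams()]), `best_row`, and `results`
#'   (one row per grid point: the grid values plus mean/sd of ACC and AUC).
#' @export
grid_search <- function(d, alpha = NULL, beta = NULL, gamma = NULL,
                        tau = NULL, corr_method = NULL,
                        hp_base = hyperparams(), n_folds = 10L,
                        n_repeats = 10L, seed = 1L, svm_cost = 1) {
  if (is.null(alpha)) alpha <- hp_base$alpha
  if (is.null(beta)) beta <- hp_base$beta
  if (is.null(gamma)) gamma <- hp_base$gamma
  if (is.null(tau)) tau <- hp_base$tau
  if (is.null(corr_method)) corr_method <- hp_base$corr_method
  grid <- expand.grid(alpha = alpha, beta = beta, gamma = gamma, tau = tau,
                      corr_method = corr_method, stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid", call. = FALSE)

  acc_mean <- acc_sd <- auc_mean <- auc_sd <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hp <- hyperparams(alpha = grid$alpha[i], beta = grid$beta[i],
                      gamma = grid$gamma[i], tau = grid$tau[i],
                      corr_method = grid$corr_method[i],
                      knn_k = hp_base$knn_k, max_iter = hp_base$max_iter,
                      tol = hp_base$tol, top_k = hp_base$top_k)
    ev <- cross_validate(d, hp, n_folds = n_folds, n_repeats = n_repeats,
                         seed = seed, svm_cost = svm_cost)
    agg <- ev$aggregate
    acc_mean[i] <- agg$mean[agg$metric == "ACC"]
    acc_sd[i] <- agg$sd[agg$metric == "ACC"]
    auc_mean[i] <- agg$mean[agg$metric == "AUC"]
    auc_sd[i] <- agg$sd[agg$metric == "AUC"]
  }
  results <- cbind(grid, acc_mean = acc_mean, acc_sd = acc_sd,
                   auc_mean = auc_mean, auc_sd = auc_sd)
  ord <- order(-results$acc_mean, -results$alpha, -results$beta,
               -results$gamma, results$tau)
  best_row <- results[ord[1L], , drop = FALSE]
  best <- hyperparams(alpha = best_row$alpha, beta = best_row$beta,
                      gamma = best_row$gamma, tau = best_row$tau,
                      corr_method = best_row$corr_method,
                      knn_k = hp_base$knn_k, max_iter = hp_base$max_iter,
                      tol = hp_base$tol, top_k = hp_base$top_k)
  list(best = best, best_row = best_row, results = results)
}
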
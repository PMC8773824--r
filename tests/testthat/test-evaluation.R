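test_that("confusion counts match a brute-force tally", {
  y <- rep(c(1L, -1L), c(5, 5))
  expect_identical(confusion_counts(y, y)[c("TP", "TN", "FP", "FN")],
                   list(TP = 5L, TN = 5L, FP = 0L, FN = 0L))
  allpos <- confusion_counts(y, rep(1L, 10))
  expect_identical(allpos$TP, 5L)
  expect_identical(allpos$FP, 5L)
  expect_identical(allpos$TN + allpos$FN, 0L)

  set.seed(61)
  for (case in 1:10) {
    yt <- sample(c(-1L, 1L), 30, replace = TRUE)
    yp <- sample(c(-1L, 1L), 30, replace = TRUE)
    cc <- confusion_counts(yt, yp)
    expect_identical(cc$TP, sum(yt == 1 & yp == 1))
    expect_identical(cc$TN, sum(yt == -1 & yp == -1))
    expect_identical(cc$FP, sum(yt == -1 & yp == 1))
    expect_identical(cc$FN, sum(yt == 1 & yp == -1))
    expect_identical(cc$TP + cc$TN + cc$FP + cc$FN, 30L)
  }
  expect_error(confusion_counts(c(1, -1), c(1, -1, 1)), "equal length")
  expect_error(confusion_counts(c(1, 0), c(1, -1)), "-1 or \\+1")
})

test_that("metric arithmetic follows the confusion-count definitions", {
  cc <- structure(list(TP = 9L, TN = 8L, FP = 2L, FN = 1L),
                  class = "fc2fs_confusion")
  m <- compute_metrics(cc)
  expect_equal(m$ACC, 0.850)
  expect_equal(m$SEN, 0.900)
  expect_equal(m$SPE, 0.800)
  expect_equal(m$F1, 18 / 21)
  expect_equal(m$GMean, sqrt(0.72))
  expect_identical(m$degenerate, character(0))

  # perfect classifier
  perf <- compute_metrics(confusion_counts(rep(c(1, -1), 5), rep(c(1, -1), 5)))
  for (nm in c("ACC", "SEN", "SPE", "GMean", "F1")) {
    expect_equal(perf[[nm]], 1, label = nm)
  }

  # degenerate denominator: no negatives evaluated
  deg <- compute_metrics(structure(list(TP = 5L, TN = 0L, FP = 0L, FN = 0L),
                                   class = "fc2fs_confusion"))
  expect_equal(deg$SPE, 0)
  expect_equal(deg$GMean, 0)
  expect_true("SPE" %in% deg$degenerate)

  # the sum variant kept behind a flag
  expect_equal(compute_metrics(cc, gmean_as_printed = TRUE)$GMean, 1.7)
})

test_that("rank AUC equals brute-force pair enumeration and handles ties", {
  y <- rep(c(-1L, 1L), each = 4)
  expect_equal(rank_auc(c(1, 2, 3, 4, 5, 6, 7, 8), y), 1)
  expect_equal(rank_auc(rep(0, 8), y), 0.5)
  set.seed(62)
  for (case in 1:20) {
    y <- sample(rep(c(-1L, 1L), c(3, 5)))
    s <- sample(round(rnorm(8), 1))  # rounding forces occasional ties
    expect_equal(rank_auc(s, y), auc_oracle(s, y))
  }
  expect_error(rank_auc(1:4, rep(1L, 4)), "both classes")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(63)
  y <- sample(rep(c(-1L, 1L), c(10, 10)))
  s <- rnorm(20)
  a <- rank_auc(s, y)
  expect_equal(rank_auc(exp(s), y), a)
  expect_equal(rank_auc(3 * s + 7, y), a)
})

test_that("stratified folds preserve class balance and are seeded", {
  y <- rep(c(-1L, 1L), c(24, 16))
  folds <- make_stratified_folds(y, n_folds = 4, n_repeats = 3, seed = 9)
  expect_length(folds, 3)
  for (r in 1:3) {
    for (f in 1:4) {
      idx <- folds[[r]] == f
      expect_identical(sum(y[idx] == -1L), 6L)
      expect_identical(sum(y[idx] == 1L), 4L)
    }
  }
  expect_identical(folds, make_stratified_folds(y, 4, 3, seed = 9))
  expect_false(identical(folds, make_stratified_folds(y, 4, 3, seed = 10)))
  expect_error(make_stratified_folds(rep(c(-1L, 1L), c(30, 3)), n_folds = 5),
               "cannot stratify")
})

test_that("a noise-free single-feature signal is classified perfectly", {
  set.seed(64)
  n <- 60
  X1 <- matrix(rnorm(n * 5), n, 5)
  X2 <- matrix(rnorm(n * 5), n, 5)
  X1[, 3] <- X1[, 3] + 0.5 * sign(X1[, 3])  # margin around the boundary
  X2[, 3] <- X1[, 3]  # shared signal feature across modalities
  y <- ifelse(X1[, 3] > 0, 1L, -1L)
  d <- multimodal_dataset(
    list(feature_matrix(X1, modality = "m1"),
         feature_matrix(X2, modality = "m2")),
    label_vector(y))
  ev <- cross_validate(d, hyperparams(top_k = 2, knn_k = 2), n_folds = 5,
                       n_repeats = 1, seed = 1)
  expect_equal(ev$aggregate$mean[ev$aggregate$metric == "ACC"], 1)
})

test_that("cross-validation is deterministic and aggregates match its folds", {
  sim <- generate_dataset(synthetic_spec(n_subjects = 60, n_features = 20,
                                         support_size = 5, block_size = 5,
                                         seed = 65))
  ev1 <- cross_validate(sim$dataset, hyperparams(top_k = 5, max_iter = 200),
                        n_folds = 5, n_repeats = 2, seed = 7)
  ev2 <- cross_validate(sim$dataset, hyperparams(top_k = 5, max_iter = 200),
                        n_folds = 5, n_repeats = 2, seed = 7)
  expect_identical(ev1$folds, ev2$folds)
  expect_identical(ev1$W_per_fold, ev2$W_per_fold)

  for (mn in c("ACC", "AUC", "SEN", "SPE", "GMean", "F1")) {
    expect_equal(ev1$aggregate$mean[ev1$aggregate$metric == mn],
                 mean(ev1$folds[[mn]]), label = mn)
    expect_equal(ev1$aggregate$sd[ev1$aggregate$metric == mn],
                 sd(ev1$folds[[mn]]), label = mn)
  }
  expect_true(all(ev1$folds$TP + ev1$folds$TN + ev1$folds$FP + ev1$folds$FN ==
                    ev1$folds$n_test))
})

test_that("grid search enumerates the grid and breaks ties as documented", {
  sim <- generate_dataset(synthetic_spec(n_subjects = 50, n_features = 10,
                                         support_size = 3, block_size = 5,
                                         seed = 66))
  # singleton grids return that point
  gs <- grid_search(sim$dataset, alpha = 0.25, beta = 0.25, gamma = 0.5,
                    tau = 0.3, hp_base = hyperparams(top_k = 3, knn_k = 3),
                    n_folds = 5, n_repeats = 1, seed = 2)
  expect_identical(nrow(gs$results), 1L)
  expect_equal(gs$best$alpha, 0.25)

  gs2 <- grid_search(sim$dataset, alpha = c(0.5, 0.25), tau = c(0.2, 0.5),
                     hp_base = hyperparams(top_k = 3, knn_k = 3),
                     n_folds = 5, n_repeats = 1, seed = 2)
  expect_identical(nrow(gs2$results), 4L)
  # ties toward larger alpha then smaller tau
  tied <- gs2$results
  tied$acc_mean <- 0.5
  ord <- order(-tied$acc_mean, -tied$alpha, -tied$beta, -tied$gamma, tied$tau)
  expect_equal(tied$alpha[ord[1]], 0.5)
  expect_equal(tied$tau[ord[1]], 0.2)
})
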
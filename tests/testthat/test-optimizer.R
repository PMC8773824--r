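test_that("trace_norm matches singular values and an eigen oracle", {
  expect_equal(trace_norm(diag(c(3, 1))), 4)
  expect_equal(trace_norm(matrix(0, 4, 2)), 0)
  set.seed(31)
  for (case in 1:5) {
    W <- matrix(rnorm(10), 5, 2)
    ev <- eigen(t(W) %*% W, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(trace_norm(W), sum(sqrt(pmax(ev, 0))), tolerance = 1e-10)
  }
})

test_that("svt_prox soft-thresholds singular values and is non-expansive", {
  expect_equal(svt_prox(diag(c(3, 1)), 1), diag(c(2, 0)))
  set.seed(32)
  Z <- matrix(rnorm(12), 4, 3)
  expect_equal(svt_prox(Z, 0), Z, tolerance = 1e-10)
  expect_error(svt_prox(Z, -1), "nonnegative")

  for (case in 1:10) {
    Z <- matrix(rnorm(12), 4, 3)
    t <- runif(1, 0, 2)
    P <- svt_prox(Z, t)
    expect_equal(svd(P)$d, pmax(svd(Z)$d - t, 0), tolerance = 1e-10)
    # non-expansiveness
    Z2 <- matrix(rnorm(12), 4, 3)
    expect_lte(sqrt(sum((svt_prox(Z, t) - svt_prox(Z2, t))^2)),
               sqrt(sum((Z - Z2)^2)) + 1e-12)
  }
})

test_that("loss equals the sum of its four components and trivial limits", {
  d <- make_test_dataset(n = 20, p = 6, seed = 33)
  d <- normalize_dataset(d)$dataset
  hp <- hyperparams(alpha = 0.3, beta = 0.2, gamma = 0.4)
  b <- build_regularizers(d, hp)

  # W = 0: residual is m * N for -1/+1 labels, all penalties vanish
  l0 <- fc2fs_loss(matrix(0, 6, 2), d, b, hp)
  expect_equal(l0$total, 2 * 20)
  expect_equal(l0$correlation + l0$structure + l0$trace_norm, 0)

  set.seed(34)
  W <- matrix(rnorm(12), 6, 2)
  l <- fc2fs_loss(W, d, b, hp)
  expect_equal(l$total, l$residual + l$correlation + l$structure + l$trace_norm)
  # components recomputed independently
  y <- d$labels$values
  res <- sum(sapply(1:2, function(i) {
    sum((y - d$modalities[[i]]$values %*% W[, i])^2)
  }))
  expect_equal(l$residual, res, tolerance = 1e-10)
  expect_equal(l$correlation, 0.3 * correlation_penalty_oracle(W, b$R),
               tolerance = 1e-8)
  expect_equal(l$structure, 0.2 * laplacian_penalty_oracle(W, b$H),
               tolerance = 1e-8)
  expect_equal(l$trace_norm, 0.4 * sum(svd(W)$d), tolerance = 1e-10)

  hp0 <- hyperparams(alpha = 0, beta = 0, gamma = 0)
  expect_equal(fc2fs_loss(W, d, b, hp0)$total, res, tolerance = 1e-10)
  expect_error(fc2fs_loss(matrix(0, 5, 2), d, b, hp), "must be")
})

test_that("smooth gradient matches linear-term and finite-difference oracles", {
  d <- make_test_dataset(n = 25, p = 6, seed = 35)
  d <- normalize_dataset(d)$dataset
  hp <- hyperparams(alpha = 0.3, beta = 0.2, gamma = 0.4)
  b <- build_regularizers(d, hp)
  y <- d$labels$values

  # W = 0 with alpha = beta = 0: column i is -2 X_i' Y
  hp0 <- hyperparams(alpha = 0, beta = 0, gamma = 1)
  G0 <- smooth_gradient(matrix(0, 6, 2), d, b, hp0)
  for (i in 1:2) {
    expect_equal(G0[, i], as.numeric(-2 * crossprod(d$modalities[[i]]$values, y)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }

  # zero at the per-modality least-squares solution
  Wls <- sapply(1:2, function(i) {
    X <- d$modalities[[i]]$values
    qr.solve(crossprod(X), crossprod(X, y))
  })
  expect_lt(max(abs(smooth_gradient(Wls, d, b, hp0))), 1e-6)

  # central finite differences of the smooth part
  eta <- function(W) {
    fc2fs_loss(W, d, b, hp)$total - hp$gamma * trace_norm(W)
  }
  set.seed(36)
  W <- matrix(rnorm(12), 6, 2)
  G <- smooth_gradient(W, d, b, hp)
  h <- 1e-5
  for (idx in sample(12, 6)) {
    Wp <- W; Wm <- W
    Wp[idx] <- Wp[idx] + h
    Wm[idx] <- Wm[idx] - h
    fd <- (eta(Wp) - eta(Wm)) / (2 * h)
    expect_equal(G[idx], fd, tolerance = 1e-5 * max(1, abs(fd)))
  }
})

test_that("solver descends monotonically and the loss is convex", {
  sim <- generate_dataset(synthetic_spec(n_subjects = 60, n_features = 20,
                                         support_size = 5, block_size = 5,
                                         seed = 37))
  d <- normalize_dataset(sim$dataset)$dataset
  hp <- hyperparams(max_iter = 300)
  b <- build_regularizers(d, hp)
  fit <- fit_fc2fs(d, b, hp)
  expect_true(all(diff(fit$loss_history) <= 1e-10))
  expect_lte(fit$n_iter, hp$max_iter)

  set.seed(38)
  for (case in 1:5) {
    W1 <- matrix(rnorm(40), 20, 2)
    W2 <- matrix(rnorm(40), 20, 2)
    mid <- fc2fs_loss((W1 + W2) / 2, d, b, hp)$total
    expect_lte(mid, (fc2fs_loss(W1, d, b, hp)$total +
                       fc2fs_loss(W2, d, b, hp)$total) / 2 + 1e-8)
  }
})

test_that("a huge trace-norm weight drives W to zero", {
  d <- make_test_dataset(n = 30, p = 8, seed = 39)
  d <- normalize_dataset(d)$dataset
  fit <- fit_fc2fs(d, hp = hyperparams(gamma = 1e6, max_iter = 50))
  expect_equal(max(abs(fit$W)), 0)
})

test_that("larger gamma never increases the rank of the fitted W", {
  sim <- generate_dataset(synthetic_spec(n_subjects = 50, n_features = 20,
                                         support_size = 5, block_size = 5,
                                         seed = 40))
  d <- normalize_dataset(sim$dataset)$dataset
  ranks <- sapply(2^seq(-5, 1), function(g) {
    fit <- fit_fc2fs(d, hp = hyperparams(gamma = g, max_iter = 400))
    sum(svd(fit$W)$d > 1e-6)
  })
  expect_true(all(diff(ranks) <= 0))
})

test_that("models serialize and round-trip through JSON", {
  d <- make_test_dataset(n = 20, p = 6, seed = 41)
  d <- normalize_dataset(d)$dataset
  fit <- fit_fc2fs(d, hp = hyperparams(max_iter = 60))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)
  back <- load_model(path)
  expect_equal(back$W, fit$W)
  expect_equal(back$loss_history, fit$loss_history)
  expect_identical(back$n_iter, fit$n_iter)
  expect_identical(back$converged, fit$converged)
  expect_equal(back$hyperparams$alpha, fit$hyperparams$alpha)
})
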
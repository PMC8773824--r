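# Independent oracle implementations used to check the package's fast paths.
# These deliberately use naive pairwise formulas / brute-force enumeration
# and must stay independent of the package code they verify.

pearson_oracle <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

spearman_oracle <- function(x, y) {
  pearson_oracle(rank(x), rank(y))
}

# Kendall tau-b by explicit pair counting
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j])
      dy <- sign(y[i] - y[j])
      if (dx == 0) tie_x <- tie_x + 1
      if (dy == 0) tie_y <- tie_y + 1
      if (dx * dy > 0) conc <- conc + 1
      if (dx * dy < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tie_x) * (n0 - tie_y))
}

corr_matrix_oracle <- function(X, fun) {
  p <- ncol(X)
  C <- diag(1, p)
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      C[a, b] <- C[b, a] <- fun(X[, a], X[, b])
    }
  }
  C
}

# all-pairs cosine similarity masked by the union k-NN rule
cosine_adjacency_oracle <- function(X, k, clip = TRUE) {
  p <- ncol(X)
  C <- matrix(0, p, p)
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      C[a, b] <- sum(X[, a] * X[, b]) /
        (sqrt(sum(X[, a]^2)) * sqrt(sum(X[, b]^2)))
    }
  }
  keep <- matrix(FALSE, p, p)
  for (a in seq_len(p)) {
    sims <- C[a, ]
    sims[a] <- -Inf
    nb <- order(sims, decreasing = TRUE)[seq_len(k)]
    keep[a, nb] <- TRUE
  }
  keep <- keep | t(keep)
  H <- ifelse(keep, C, 0)
  if (clip) H <- pmax(H, 0)
  diag(H) <- 0
  H
}

# half the adjacency-weighted sum of squared row differences
laplacian_penalty_oracle <- function(W, H) {
  p <- nrow(W)
  acc <- 0
  for (j in seq_len(p)) {
    for (k in seq_len(p)) {
      acc <- acc + H[j, k] * sum((W[j, ] - W[k, ])^2)
    }
  }
  acc / 2
}

# explicit double-sum form of tr(W' R W)
correlation_penalty_oracle <- function(W, R) {
  WWt <- W %*% t(W)
  acc <- 0
  for (a in seq_len(nrow(R))) {
    for (b in seq_len(ncol(R))) {
      acc <- acc + R[a, b] * WWt[b, a]
    }
  }
  acc
}

# AUC by enumeration over all (negative, positive) pairs, ties credited 0.5
auc_oracle <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == -1]
  acc <- 0
  for (sp in pos) {
    for (sn in neg) {
      acc <- acc + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
    }
  }
  acc / (length(pos) * length(neg))
}

svt_objective <- function(W, Z, t) {
  0.5 * sum((W - Z)^2) + t * sum(svd(W)$d)
}

# small random but valid multi-modal dataset for plumbing tests
make_test_dataset <- function(n = 24, p = 8, m = 2, seed = 1) {
  set.seed(seed)
  mods <- lapply(seq_len(m), function(i) {
    feature_matrix(matrix(rnorm(n * p), n, p),
                   sprintf("S%03d", seq_len(n)),
                   sprintf("ROI%03d", seq_len(p)),
                   sprintf("mod%d", i))
  })
  y <- rep_len(c(-1L, 1L), n)
  multimodal_dataset(mods, label_vector(y))
}

# symmetric nonnegative adjacency with zero diagonal
random_adjacency <- function(p, density = 0.4) {
  A <- matrix(stats::runif(p * p), p, p) *
    (matrix(stats::runif(p * p), p, p) < density)
  H <- (A + t(A)) / 2
  diag(H) <- 0
  H
}
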
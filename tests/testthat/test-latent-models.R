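test_that("a perfect predictor column gives R2Y = 1 and exact fitted values", {
  y <- balanced_labels(12)
  X <- cbind(V1 = y)
  m <- fit_plsda(X, y, 1)
  expect_equal(m$r2y, 1, tolerance = 1e-12)
  expect_equal(m$fitted, y, tolerance = 1e-12)
  expect_equal(drop(X %*% m$coefficients) + m$y_mean, y, tolerance = 1e-12)
})

test_that("with no usable signal R2Y collapses to zero", {
  set.seed(4)
  y <- balanced_labels(10)
  X <- null_matrix(10, 3, 4)
  X <- X - outer(y, drop(crossprod(X, y))) / sum(y^2)  # columns orthogonal to y
  X <- X + 1e-8 * null_matrix(10, 3, 5)
  m <- fit_plsda(X, y, 1)
  expect_lt(m$r2y, 0.01)
})

test_that("the first NIPALS component has the closed form w = X'y", {
  for (s in 1:10) {
    X <- null_matrix(10, 4, s)
    y <- balanced_labels(10)
    m <- fit_plsda(X, y, 1)
    w_direct <- drop(crossprod(X, y - mean(y)))
    w_direct <- w_direct / sqrt(sum(w_direct^2))
    cosine <- abs(sum(m$weights[, 1] * w_direct))
    expect_equal(cosine, 1, tolerance = 1e-12)
    # one-component coefficients point along the same direction
    cos_b <- abs(sum(m$coefficients * w_direct) /
                   sqrt(sum(m$coefficients^2)))
    expect_equal(cos_b, 1, tolerance = 1e-12)
  }
})

test_that("one-component PLS prediction equals brute-force rank-1 regression", {
  # oracle: least squares of y on the single derived feature t = X X'y
  for (s in 1:20) {
    n <- sample(5:8, 1)
    p <- sample(2:5, 1)
    X <- null_matrix(n, p, s + 100)
    y <- rep(c(1, -1), length.out = n)
    y0 <- y - mean(y)
    t_bf <- drop(X %*% crossprod(X, y0))
    fit_bf <- mean(y) + t_bf * sum(t_bf * y0) / sum(t_bf^2)
    m <- fit_plsda(X, y, 1)
    expect_equal(predict(m, X), fit_bf, tolerance = 1e-10)
  }
})

test_that("first-component scores agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(11)
  X <- null_matrix(30, 8, 11)
  y <- balanced_labels(30)
  Xs <- autoscale(X)$values
  ours <- fit_plsda(Xs, y, 2)
  ref <- mixOmics::pls(Xs, y, ncomp = 2, scale = FALSE, mode = "regression")
  for (a in 1:2) {
    cosine <- abs(cor(ours$scores[, a], ref$variates$X[, a]))
    expect_gt(cosine, 1 - 1e-8)
  }
})

test_that("VIP follows its formula and algebraic identities", {
  y <- balanced_labels(20)
  # all columns identical to y: symmetric weights, every VIP = 1
  X <- cbind(V1 = y, V2 = y, V3 = y)
  m <- fit_plsda(X + 1e-6 * null_matrix(20, 3, 1), y, 1)
  expect_equal(unname(m$vip), rep(1, 3), tolerance = 1e-3)

  # weights concentrated on one of two variables: VIP = (sqrt(2), 0)
  set.seed(2)
  noise <- rnorm(20)
  noise <- noise - y * sum(noise * y) / sum(y * y)
  X <- cbind(V1 = y, V2 = noise * 1e-8)
  m <- fit_plsda(X, y, 1)
  expect_equal(unname(m$vip[1]), sqrt(2), tolerance = 1e-6)
  expect_lt(unname(m$vip[2]), 1e-6)

  # mean squared VIP is exactly 1 for any model
  for (s in 1:5) {
    X <- null_matrix(16, 7, s)
    y2 <- balanced_labels(16)
    m1 <- fit_plsda(X, y2, 3)
    m2 <- fit_opls(X, y2, 1, 2)
    expect_equal(mean(m1$vip^2), 1, tolerance = 1e-8)
    expect_equal(mean(m2$vip^2), 1, tolerance = 1e-8)
  }
})

test_that("OPLS orthogonal scores are uncorrelated with the labels", {
  for (s in 1:8) {
    X <- null_matrix(20, 10, s)
    y <- balanced_labels(20)
    m <- fit_opls(X, y, 1, 3)
    for (i in seq_len(ncol(m$orthogonal_scores))) {
      to <- m$orthogonal_scores[, i]
      expect_lt(abs(sum(to * y)), 1e-8 * sqrt(sum(to^2)) * sqrt(sum(y^2)))
    }
  }
})

test_that("OPLS with zero orthogonal components reduces to PLS-DA", {
  X <- null_matrix(14, 6, 3)
  y <- balanced_labels(14)
  a <- fit_opls(X, y, 2, 0)
  b <- fit_plsda(X, y, 2)
  expect_equal(abs(a$scores), abs(b$scores), tolerance = 1e-12)
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-12)
  expect_equal(a$r2y, b$r2y, tolerance = 1e-12)
})

test_that("OPLS recovers planted orthogonal structure", {
  set.seed(21)
  n <- 40
  p <- 10
  y <- balanced_labels(n)
  c_vec <- rnorm(p)
  p_o <- rnorm(p)
  t_o <- rnorm(n)
  t_o <- t_o - y * sum(t_o * y) / sum(y * y)  # orthogonal to labels
  X <- outer(y, c_vec) + outer(t_o, p_o) + 1e-4 * matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("V", 1:p)
  m <- fit_opls(X, y, 1, 1)
  cosine <- abs(cor(m$orthogonal_scores[, 1], t_o))
  expect_gt(cosine, 0.99)
})

test_that("orthogonal filtering removes variance and helps training fit", {
  X <- null_matrix(24, 12, 7)
  y <- balanced_labels(24)
  m <- fit_opls(X, y, 1, 2)
  # reconstruct the filtered matrix and compare Frobenius norms
  Xf <- X
  for (i in 1:2) {
    to <- Xf %*% m$orthogonal_weights[, i, drop = FALSE]
    Xf <- Xf - tcrossprod(to, m$orthogonal_loadings[, i, drop = FALSE])
  }
  expect_lt(sum(Xf^2), sum(X^2))

  r2 <- vapply(0:3, function(k) fit_opls(X, y, 1, k)$r2y, numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("degenerate inputs raise the documented errors and warnings", {
  X <- null_matrix(10, 3, 1)
  expect_error(fit_plsda(X, rep(1, 10), 1), "zero-variance")
  expect_error(fit_plsda(X[1:3, ], balanced_labels(10)[1:3], 1),
               "at least 4")
  # more components than the rank supports
  Xr <- cbind(V1 = balanced_labels(10) + 0.1 * rnorm(10))
  expect_warning(m <- fit_plsda(cbind(Xr, V2 = Xr[, 1]),
                                balanced_labels(10), 3), "extracted")
  expect_lt(m$n_predictive, 3)
  # no orthogonal variation left
  y <- balanced_labels(12)
  Xo <- outer(y, c(1, 2, 3))
  colnames(Xo) <- paste0("V", 1:3)
  expect_warning(mo <- fit_opls(Xo, y, 1, 2), "exhausted")
  expect_equal(mo$n_orthogonal, 0)
})

test_that("Q2 equals a hand-rolled leave-one-out PRESS/SS loop", {
  set.seed(31)
  sig <- signal_matrix(n = 12, p = 3, noise = 1.5, seed = 31)
  X <- sig$X
  y <- sig$y
  # hand-rolled LOO: refit scaling and the 1-component model per split
  press <- 0
  for (i in 1:12) {
    Xtr <- X[-i, , drop = FALSE]
    ctr <- colMeans(Xtr)
    sds <- apply(Xtr, 2, sd)
    Xs <- sweep(sweep(Xtr, 2, ctr), 2, sds, "/")
    Xte <- sweep(sweep(X[i, , drop = FALSE], 2, ctr), 2, sds, "/")
    y0 <- y[-i] - mean(y[-i])
    w <- drop(crossprod(Xs, y0))
    w <- w / sqrt(sum(w^2))
    t <- drop(Xs %*% w)
    pv <- drop(crossprod(Xs, t)) / sum(t^2)
    q <- sum(y0 * t) / sum(t^2)
    b <- w * q / sum(pv * w)
    press <- press + (y[i] - (drop(Xte %*% b) + mean(y[-i])))^2
  }
  q2_manual <- 1 - press / sum((y - mean(y))^2)
  q2_pkg <- q2_crossval(X, y, model_spec("plsda", n_components = 1),
                        k_folds = 12, seed = 1)
  expect_equal(q2_pkg, q2_manual, tolerance = 1e-10)
})

test_that("Q2 separates strong signal from pure noise", {
  sig <- signal_matrix(n = 40, p = 4, noise = 0.05, seed = 2)
  q2 <- q2_crossval(sig$X, sig$y, model_spec("plsda", n_components = 1),
                    7, seed = 1)
  expect_gt(q2, 0.9)

  # measured non-positive rate on null data is ~0.9; asserted with a
  # 3-sigma Monte-Carlo margin over 80 draws
  neg <- vapply(1:80, function(s) {
    X <- null_matrix(40, 10, s + 500)
    q2_crossval(X, balanced_labels(40),
                model_spec("plsda", n_components = 1), 7, seed = s) <= 0
  }, logical(1))
  expect_gte(mean(neg), 0.8)
})
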
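test_that("mean centering and Pareto scaling behave column-wise", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 10, 10), c = c(0, 4, 8))
  pp <- preprocess(X)
  # column a has sd 1, so Pareto scaling leaves the centered values alone
  expect_equal(unname(pp$X[, "a"]), c(-1, 0, 1))
  # constant column: centered to zero, flagged, not divided
  expect_equal(unname(pp$X[, "b"]), c(0, 0, 0))
  expect_true(pp$params$zero_sd[["b"]])
  expect_equal(unname(pp$X[, "c"]), (c(0, 4, 8) - 4) / sqrt(4))

  # applying fitted params to new data uses the training means and scales
  Xnew <- cbind(a = c(4, 5), b = c(0, 0), c = c(4, 4))
  Xn <- apply_preprocess(pp$params, Xnew)
  expect_equal(unname(Xn[, "a"]), c(2, 3))
  expect_equal(unname(Xn[, "c"]), c(0, 0))

  expect_error(preprocess(cbind(c(1, NA))), "input error")
})

test_that("PCA agrees with an eigendecomposition of the covariance", {
  set.seed(5)
  X <- matrix(rnorm(24), 6, 4)
  Xc <- scale(X, scale = FALSE)
  pca <- fit_pca(Xc, 4)
  eig <- eigen(cov(Xc))
  expect_equal(pca$explained_variance, eig$values[1:4], tolerance = 1e-8)
  for (a in 1:4)   # loadings match up to sign
    expect_equal(abs(sum(pca$loadings[, a] * eig$vectors[, a])), 1,
                 tolerance = 1e-8)
  expect_equal(crossprod(pca$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
})

test_that("a rank-1 matrix loads entirely on one component", {
  X <- outer(c(1, 2, 3, 4), c(1, -1, 2))
  Xc <- scale(X, scale = FALSE)
  pca <- fit_pca(Xc, 1)
  expect_equal(pca$explained_variance_ratio[1], 1, tolerance = 1e-12)
  expect_error(fit_pca(Xc, 3), "rank")
})

test_that("PLS-DA separates a trivially informative predictor", {
  y <- rep(c(0, 1), each = 10)
  X <- cbind(v = y)
  pp <- preprocess(X)
  fit <- fit_plsda(pp$X, y, 1)
  expect_equal(mean((fit$fitted >= 0.5) == y), 1)
  expect_error(fit_plsda(pp$X, rep(1, 20), 1), "input error")
})

test_that("NIPALS predictions match an independent SIMPLS oracle", {
  set.seed(11)
  X <- matrix(rnorm(50), 10, 5)
  y <- rep(c(0, 1), 5)
  Xc <- scale(X, scale = FALSE)
  for (a in 1:3) {
    fit <- fit_plsda(Xc, y, a)
    expect_equal(fit$fitted, simpls_predict(Xc, y, a), tolerance = 1e-6)
  }
})

test_that("PLS scores are orthogonal and row permutation is equivariant", {
  set.seed(13)
  X <- matrix(rnorm(200), 20, 10)
  y <- rep(c(0, 1), 10)
  fit <- fit_plsda(X, y, 4)
  G <- crossprod(fit$T)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)

  perm <- sample(20)
  fit2 <- fit_plsda(X[perm, ], y[perm], 4)
  expect_equal(fit2$T, fit$T[perm, ], tolerance = 1e-9)
  expect_equal(fit2$fitted, fit$fitted[perm], tolerance = 1e-9)
})

test_that("full-component PLS reproduces least-squares predictions", {
  set.seed(17)
  X <- matrix(rnorm(80), 20, 4)
  y <- rep(c(0, 1), 10)
  Xc <- scale(X, scale = FALSE)
  fit <- fit_plsda(Xc, y, 4)
  ols <- unname(stats::fitted(lm(y ~ Xc)))
  expect_equal(fit$fitted, ols, tolerance = 1e-6)
})

test_that("VIP satisfies its algebraic identities and finds the signal", {
  y <- rep(c(0, 1), each = 15)
  X1 <- cbind(v = y + rnorm(30, sd = 0.1))
  f1 <- fit_plsda(preprocess(X1)$X, y, 1)
  expect_equal(vip(f1), c(v = 1), tolerance = 1e-12)

  set.seed(19)
  X <- cbind(signal = y + rnorm(30, sd = 0.2),
             matrix(rnorm(30 * 9), 30, 9,
                    dimnames = list(NULL, paste0("n", 1:9))))
  fit <- fit_plsda(preprocess(X)$X, y, 2)
  v <- vip(fit)
  expect_equal(mean(v^2), 1, tolerance = 1e-10)     # holds for any model
  expect_gt(v[["signal"]], 1)
  expect_equal(names(which.max(v)), "signal")
})

test_that("venetian-blind CV is deterministic and nails separable data", {
  y <- rep(c(0, 1), each = 30)
  set.seed(23)
  X <- cbind(y + rnorm(60, sd = 0.05), matrix(rnorm(120), 60, 2))
  cv1 <- venetian_cv(X, y, folds = 10, repeats = 3, n_components = 2,
                     seed = 42)
  cv2 <- venetian_cv(X, y, folds = 10, repeats = 3, n_components = 2,
                     seed = 42)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_equal(cv1$accuracy, 1.0)
  expect_lt(cv1$rmsecv, 0.5)
  expect_gt(cv1$q2, 0.9)
  expect_equal(cv1$auroc, 1.0)
  # the PRESS-based statistic never exceeds the training R2
  pp <- preprocess(X)
  fit <- fit_plsda(pp$X, y, 2)
  r2 <- 1 - sum((y - fit$fitted)^2) / sum((y - mean(y))^2)
  expect_lte(cv1$q2_press, r2 + 1e-9)
})

test_that("CV predictive statistics stay near zero without signal", {
  q2s <- vapply(1:20, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(200 * 20), 200, 20)
    y <- rep(c(0, 1), each = 100)
    suppressWarnings(venetian_cv(X, y, folds = 10, repeats = 2,
                                 n_components = 2, seed = s))$q2
  }, numeric(1))
  expect_lte(mean(q2s), 0.1)
})

test_that("the permutation p attains its 1/(n+1) floor on separable data", {
  y <- rep(c(0, 1), each = 30)
  set.seed(31)
  X <- cbind(y + rnorm(60, sd = 0.05), matrix(rnorm(120), 60, 2))
  pr <- permutation_test(X, y, n_permutations = 50, folds = 10, repeats = 2,
                         n_components = 2, seed = 7)
  expect_length(pr$permuted, 50)
  expect_equal(pr$p, 1 / 51)
  expect_error(permutation_test(X, y, n_permutations = 0), "input error")
})

test_that("permutation p-values are unremarkable on pure noise", {
  set.seed(37)
  ps <- vapply(1:8, function(s) {
    X <- matrix(rnorm(40 * 5), 40, 5)
    y <- rep(c(0, 1), each = 20)
    suppressWarnings(permutation_test(X, y, n_permutations = 19, folds = 5,
                                      repeats = 1, n_components = 1,
                                      seed = s))$p
  }, numeric(1))
  expect_gt(mean(ps), 0.15)   # not systematically significant
  expect_gt(max(ps), 0.3)
})

test_that("AUROC is the Mann-Whitney statistic with tie handling", {
  expect_equal(cv_roc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auroc, 1)
  expect_equal(cv_roc(rep(0.5, 10), rep(c(0, 1), 5))$auroc, 0.5)
  set.seed(41)
  s <- rnorm(100); y <- rep(c(0, 1), 50)
  expect_equal(cv_roc(s, y)$auroc, 1 - cv_roc(-s, y)$auroc,
               tolerance = 1e-12)
  # independent oracle
  expect_equal(cv_roc(s, y)$auroc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-9)
  # null distribution: 0.5 within 3 SEs
  set.seed(43)
  s2 <- runif(500); y2 <- rbinom(500, 1, 0.5)
  n1 <- sum(y2); n0 <- 500 - n1
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(cv_roc(s2, y2)$auroc - 0.5), 3 * se)
  expect_error(cv_roc(s2, rep(1, 500)), "input error")
})
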
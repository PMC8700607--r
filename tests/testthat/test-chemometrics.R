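test_that("PCA matches a singular value decomposition oracle", {
  x <- withr::with_seed(10, matrix(stats::rnorm(24), 6, 4))
  x <- scale(x)[, ]  # pre-scaled, as the pipeline guarantees
  m <- pca_fit(x)
  sv <- svd(x)
  for (k in seq_len(ncol(m$scores))) {
    # singular directions are sign-ambiguous; compare up to sign
    s <- sign(sum(m$loadings[, k] * sv$v[, k]))
    expect_equal(m$loadings[, k], s * sv$v[, k], tolerance = 1e-10)
    expect_equal(m$scores[, k], s * sv$u[, k] * sv$d[k], tolerance = 1e-10)
  }
  expect_equal(m$explained_var, sv$d^2 / sum(sv$d^2), tolerance = 1e-12)
  # full reconstruction
  expect_equal(m$scores %*% t(m$loadings), x, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca_fit(x, 5), "exceeds")
})

test_that("PCA puts all variance on PC1 for collinear points", {
  pts <- cbind(1:5, 2 * (1:5))
  m <- pca_fit(scale(pts, scale = FALSE))
  expect_equal(m$explained_var[1], 1, tolerance = 1e-12)
})

test_that("one latent variable suffices when y follows a single x direction", {
  # orthogonal design columns: the weight vector collapses onto the active
  # direction and one component reproduces y exactly
  x <- stats::poly(1:12, degree = 4)[, ]
  y <- 3 * x[, 2]
  fit <- pls_fit(x, y, n_lv = 1)
  expect_equal(r_squared(y, as.numeric(fit$fitted)), 1, tolerance = 1e-9)
  # with a single predictor the claim holds for any data
  x1 <- withr::with_seed(2, matrix(stats::rnorm(10), 10, 1))
  fit1 <- pls_fit(x1, 3 * x1[, 1], n_lv = 1)
  expect_equal(r_squared(3 * x1[, 1], as.numeric(fit1$fitted)), 1,
               tolerance = 1e-9)
})

test_that("full-rank PLS reproduces the least-squares oracle", {
  x <- withr::with_seed(3, matrix(stats::rnorm(50), 10, 5))
  y <- withr::with_seed(4, stats::rnorm(10))
  fit <- pls_fit(x, y, n_lv = 5)
  ols <- stats::lm.fit(cbind(1, scale(x)), y)
  expect_equal(as.numeric(fit$fitted), as.numeric(cbind(1, scale(x)) %*%
                                                    ols$coefficients),
               tolerance = 1e-6)
})

test_that("PLS coefficients are invariant to sample order", {
  x <- withr::with_seed(5, matrix(stats::rnorm(60), 12, 5))
  y <- withr::with_seed(6, stats::rnorm(12))
  fit <- pls_fit(x, y, n_lv = 3)
  perm <- withr::with_seed(7, sample(12))
  fit_p <- pls_fit(x[perm, ], y[perm], n_lv = 3)
  expect_equal(fit$coefficients, fit_p$coefficients, tolerance = 1e-8)
})

test_that("NIPALS scores are orthogonal and weights sign-normalized", {
  x <- withr::with_seed(8, matrix(stats::rnorm(80), 10, 8))
  y <- withr::with_seed(9, matrix(stats::rnorm(20), 10, 2))
  fit <- pls_fit(x, y, n_lv = 4)
  g <- crossprod(fit$x_scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  for (a in seq_len(fit$n_lv)) {
    w <- fit$x_weights[, a]
    expect_gt(w[which.max(abs(w))], 0)
  }
  expect_error(pls_fit(x, rep(2, 10), n_lv = 2), "zero variance")
})

test_that("first-component NIPALS matches a hand-rolled oracle", {
  x <- withr::with_seed(11, matrix(stats::rnorm(50), 10, 5))
  y <- withr::with_seed(12, stats::rnorm(10))
  fit <- pls_fit(x, y, n_lv = 1, scale_x = FALSE)
  # brute-force single-component NIPALS on centered data
  xc <- scale(x, scale = FALSE)
  yc <- y - mean(y)
  w <- crossprod(xc, yc) / sum(yc^2)
  w <- w / sqrt(sum(w^2))
  w <- w * sign(w[which.max(abs(w))])
  tt <- xc %*% w
  q <- sum(yc * tt) / sum(tt^2)
  expect_equal(as.numeric(fit$x_weights), as.numeric(w), tolerance = 1e-9)
  expect_equal(as.numeric(fit$fitted), as.numeric(tt * q + mean(y)),
               tolerance = 1e-9)
})

test_that("prediction applies stored scaling and coefficients", {
  x <- withr::with_seed(13, matrix(stats::rnorm(60), 12, 5))
  y <- withr::with_seed(14, stats::rnorm(12))
  fit <- pls_fit(x, y, n_lv = 3)
  expect_equal(pls_predict(fit, x), fit$fitted, tolerance = 1e-10)
  # a row at the training column means autoscales to zero -> predicts mean(y)
  expect_equal(as.numeric(pls_predict(fit, matrix(colMeans(x), 1))),
               mean(y), tolerance = 1e-10)
  # manual dot product for one new row
  new <- withr::with_seed(15, stats::rnorm(5))
  xs <- (new - fit$scaling$center) / fit$scaling$scale
  expect_equal(as.numeric(pls_predict(fit, matrix(new, 1))),
               sum(xs * fit$coefficients) + fit$y_mean,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(pls_predict(fit, matrix(0, 1, 4)), "column count")
})

test_that("predictions agree with an independent PLS implementation", {
  x <- withr::with_seed(50, matrix(stats::rnorm(80), 10, 8,
                                   dimnames = list(NULL, paste0("v", 1:8))))
  y <- withr::with_seed(51, stats::rnorm(10))
  fit <- pls_fit(x, y, n_lv = 3)
  mo <- mixOmics::pls(x, y, ncomp = 3, mode = "regression", scale = TRUE)
  po <- predict(mo, x)
  for (a in 1:3) {
    expect_equal(as.numeric(pls_predict(fit, x, n_lv = a)),
                 as.numeric(po$predict[, 1, a]), tolerance = 1e-10)
  }
})

test_that("venetian blinds interleave and partition the samples", {
  s <- venetian_blind_splits(6, 3)
  expect_identical(lapply(s, `[[`, "test"),
                   list(c(1L, 4L), c(2L, 5L), c(3L, 6L)))
  loo <- venetian_blind_splits(5, 5)
  expect_identical(lapply(loo, `[[`, "test"), as.list(1:5))
  for (n in c(7, 12)) {
    for (k in c(2, 3, 5)) {
      s <- venetian_blind_splits(n, k)
      tests <- unlist(lapply(s, `[[`, "test"))
      expect_identical(sort(tests), seq_len(n))  # disjoint and exhaustive
      for (f in s) expect_identical(sort(c(f$train, f$test)), seq_len(n))
    }
  }
  expect_error(venetian_blind_splits(3, 4), "n_splits")
  expect_error(venetian_blind_splits(3, 1), "n_splits")
})

test_that("cross-validation error vanishes on noiseless single-factor data", {
  tvec <- seq(-2, 2, length.out = 12)
  x <- outer(tvec, c(1, -0.5, 2, 0.3))
  y <- 5 * tvec
  cv <- cross_validate_pls(x, y, max_lv = 2, n_splits = 4)
  expect_lt(cv$rmsecv_by_lv[1], 1e-8)
})

test_that("shuffled responses cross-validate no better than the y spread", {
  x <- withr::with_seed(16, matrix(stats::rnorm(200), 20, 10))
  y <- withr::with_seed(17, sample(rep(seq(0, 100, by = 20), length.out = 20)))
  cv <- cross_validate_pls(x, y, max_lv = 5, n_splits = 5)
  expect_true(all(cv$rmsecv_by_lv >= 0.8 * stats::sd(y)))
})

test_that("held-out folds never leak into scaling or fitting", {
  x <- withr::with_seed(18, matrix(stats::rnorm(90), 9, 10))
  y <- withr::with_seed(19, stats::rnorm(9))
  cv <- cross_validate_pls(x, y, max_lv = 2, n_splits = 3)
  # oracle: rebuild each fold with train-only scaling and compare predictions
  for (fold in venetian_blind_splits(9, 3)) {
    fit <- pls_fit(x[fold$train, ], y[fold$train], n_lv = 2)
    for (a in 1:2) {
      expect_equal(cv$predictions[fold$test, 1, a],
                   as.numeric(pls_predict(fit, x[fold$test, ], n_lv = a)),
                   tolerance = 1e-10)
    }
  }
  # corrupting a test row changes only that row's prediction in its fold
  x2 <- x
  x2[1, ] <- x2[1, ] * 1e6
  cv2 <- cross_validate_pls(x2, y, max_lv = 2, n_splits = 3)
  # row 1 sits in fold 1's test set; folds 2 and 3 train on it, so the
  # predictions of fold 1's remaining test rows (4, 7) must stay identical
  expect_equal(cv2$predictions[c(4, 7), 1, ], cv$predictions[c(4, 7), 1, ],
               tolerance = 1e-10)
})

test_that("latent-variable selection finds the first important minimum", {
  expect_identical(select_lv(c(5.0, 3.0, 2.9, 3.2)), 3L)
  expect_identical(select_lv(c(2.0, 2.0, 2.0)), 1L)
  expect_identical(select_lv(c(9, 6, 4, 2.5, 1.5)), 5L)  # keeps improving
  expect_identical(select_lv(c(5, 1.0, 1.01, 1.009)), 2L)
  expect_identical(select_lv(3), 1L)
  cv <- structure(list(rmsecv_by_lv = c(4, 2, 2.03, 2.2)),
                  class = "cv_result")
  expect_identical(select_lv(cv), 2L)
})
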
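# PCA reduction and ROMP sparse regression.

test_that("PCA keeps min(m-1, rank) components ordered by variance", {
  set.seed(1)
  # full-rank tall data: k = m - 1
  F <- matrix(rnorm(60 * 200), 60)
  p <- pca_fit(F)
  expect_equal(p$k, 59L)
  expect_true(all(diff(p$variance) <= 1e-12))
  # orthonormal components
  expect_equal(crossprod(p$components), diag(p$k), tolerance = 1e-8)
  # wide full-rank data: k = n
  p2 <- pca_fit(matrix(rnorm(50 * 10), 50))
  expect_equal(p2$k, 10L)
  # two identical rows: centered rank 0
  expect_warning(p3 <- pca_fit(matrix(c(1, 2, 1, 2), 2, byrow = TRUE)),
                 "constant")
  expect_equal(p3$k, 0L)
})

test_that("PCA reconstruction and transform satisfy their contracts", {
  set.seed(2)
  F <- matrix(rnorm(10 * 50), 10)
  p <- pca_fit(F)
  expect_equal(p$k, 9L)
  Z <- pca_transform(p, F)
  expect_equal(dim(Z), c(10L, 9L))
  Xc <- sweep(F, 2, colMeans(F))
  # reconstruction from all components equals the centered matrix
  expect_equal(Z %*% t(p$components), Xc, tolerance = 1e-8)
  # per-column score variance equals the explained variance
  expect_equal(apply(Z, 2, stats::var), p$variance, tolerance = 1e-8)
  # the training mean maps to the origin
  expect_equal(drop(pca_transform(p, matrix(colMeans(F), 1))),
               rep(0, 9), tolerance = 1e-8)
  # isometry on the row space: pairwise distances preserved at k = rank
  expect_equal(as.matrix(dist(Z)), as.matrix(dist(Xc)), tolerance = 1e-8)
  expect_error(pca_transform(p, F[, 1:10]), "width mismatch")
})

test_that("ROMP recovers exact sparse signals on orthonormal designs", {
  ok <- 0
  for (s in 1:40) {
    set.seed(s)
    X <- qr.Q(qr(matrix(rnorm(64 * 64), 64)))
    supp <- sample(64, 4)
    w_true <- numeric(64)
    w_true[supp] <- runif(4, 1, 2) * sample(c(-1, 1), 4, replace = TRUE)
    y <- drop(X %*% w_true)
    fit <- romp_fit(X, y, fit_config(K = 4))
    if (setequal(fit$support, supp) &&
        max(abs(fit$w - w_true)) <= 1e-10) ok <- ok + 1
  }
  expect_gte(ok, 38)
})

test_that("ROMP edge cases: zero response, support caps, invalid K", {
  set.seed(3)
  X <- matrix(rnorm(30 * 10), 30)
  z <- romp_fit(X, rep(0, 30), fit_config(K = 2))
  expect_equal(z$w, rep(0, 10))
  expect_equal(z$b, 0)
  expect_length(z$support, 0)
  expect_error(romp_fit(X, rnorm(30), fit_config(K = 11)),
               "exceeds the number of predictors")
  # dense response: support never exceeds 2K
  for (s in 1:10) {
    set.seed(s)
    y <- rnorm(30)
    fit <- romp_fit(X, y, fit_config(K = 3, tol = 1e-12))
    expect_lte(length(fit$support), 6L)
  }
})

test_that("ROMP residual norms are non-increasing across iterations", {
  for (s in 1:50) {
    set.seed(s + 100)
    m <- sample(20:60, 1); k <- sample(10:40, 1)
    X <- matrix(rnorm(m * k), m)
    y <- rnorm(m)
    fit <- romp_fit(X, y, fit_config(K = min(5, k)))
    expect_true(all(diff(fit$residual_path) <= 1e-10))
  }
})

test_that("voxelwise fitting is independent per voxel and handles degenerate columns", {
  set.seed(4)
  X <- matrix(rnorm(40 * 12), 40)
  w1 <- numeric(12); w1[c(2, 7)] <- c(1.5, -2)
  y1 <- drop(X %*% w1) + 0.3
  Y <- cbind(a = y1, b = rnorm(40), c = y1, d = rep(1, 40))
  expect_warning(mods <- fit_voxelwise(X, Y, fit_config(K = 4)),
                 "zero response variance")
  expect_length(mods$models, 4)
  # duplicate columns give identical models
  expect_equal(mods$models[[1]]$w, mods$models[[3]]$w)
  # independence: refitting a single column reproduces the joint fit
  solo <- romp_fit(X, Y[, 2], fit_config(K = 4))
  expect_equal(mods$models[[2]]$w, solo$w)
  # constant voxel: zero weights, intercept = mean
  expect_equal(mods$models[[4]]$w, rep(0, 12))
  expect_equal(mods$models[[4]]$b, 1)
  # noiseless sparse voxel is recovered to tolerance
  expect_lte(mods$models[[1]]$residual_norm, 1e-6 * sqrt(sum(y1^2)))
  td <- tidy(mods)
  expect_equal(nrow(td), 4)
  expect_equal(td$n_nonzero[4], 0L)
})

test_that("prediction applies F w + b per voxel and checks widths", {
  set.seed(5)
  X <- matrix(rnorm(20 * 6), 20)
  Y <- cbind(drop(X %*% c(2, 0, 0, 0, 0, 0)) + 1, rnorm(20))
  mods <- fit_voxelwise(X, Y, fit_config(K = 2))
  Xt <- matrix(rnorm(10 * 6), 10)
  pred <- predict(mods, Xt)
  expect_equal(dim(pred), c(10L, 2L))
  # row-wise dot-product oracle
  for (i in 1:10)
    expect_equal(unname(pred[i, 1]),
                 sum(Xt[i, ] * mods$models[[1]]$w) + mods$models[[1]]$b,
                 tolerance = 1e-10)
  # single-feature arithmetic: w = 2, b = 1 maps (0, 1, 2) to (1, 3, 5)
  m1 <- list(models = list(structure(list(w = 2, b = 1, support = 1L),
                                     class = "sparse_linear_model")),
             voxel_ids = "v", n_features = 1L)
  class(m1) <- "voxel_models"
  expect_equal(drop(predict(m1, matrix(c(0, 1, 2)))), c(1, 3, 5))
  expect_error(predict(mods, Xt[, 1:3]), "width mismatch")
})
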
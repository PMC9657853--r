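# NIPALS PLS1, joint PCA, coefficient extraction, prediction, component count

test_that("p = 1 PLS1 equals simple least squares", {
  x <- matrix(c(1, 2, 3, 4), ncol = 1)
  y <- c(2, 4, 5, 9)
  fit <- fit_plsr(x, y, 1)
  co <- extract_regression(fit)
  # closed form: slope = Sxy/Sxx = 11/5, intercept = 5 - 2.2 * 2.5
  expect_equal(co$beta, 2.2, tolerance = 1e-12)
  expect_equal(co$intercept, -0.5, tolerance = 1e-12)
})

test_that("noiseless linear responses are recovered exactly", {
  set.seed(21)
  X <- matrix(rnorm(40), 20, 2)
  y <- 2 * X[, 1] - 3 * X[, 2] + 1
  fit <- fit_plsr(X, y, 2)
  expect_equal(r_squared(y, fit$fitted), 1, tolerance = 1e-12)
  expect_lt(max(abs(fit$Y_resid)), 1e-10)
  co <- extract_regression(fit)
  expect_equal(co$beta, c(2, -3), tolerance = 1e-8)
  expect_equal(co$intercept, 1, tolerance = 1e-8)
})

test_that("full-rank PLS reproduces OLS predictions (20 random instances)", {
  for (i in 1:20) {
    set.seed(100 + i)
    n <- sample(10:40, 1); p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    fit <- fit_plsr(X, y, p)
    ols <- oracle_ols_fit(X, y)
    pred <- predict(extract_regression(fit), X)
    expect_equal(pred, ols, tolerance = 1e-8)
    expect_equal(fit$fitted, ols, tolerance = 1e-8)
  }
})

test_that("scores are orthogonal and the decomposition identities hold at every h", {
  set.seed(33)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(30, sd = 0.3)
  for (h in c(1, 3, 6)) {
    fit <- fit_plsr(X, y, h)
    G <- crossprod(fit$T)
    offdiag <- G - diag(diag(G), nrow = nrow(G))
    expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
    Xc <- sweep(X, 2, fit$X_mean)
    expect_equal(fit$T %*% t(fit$P) + fit$X_resid, Xc, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(drop(fit$T %*% fit$b) + fit$Y_resid, y - fit$Y_mean,
                 tolerance = 1e-9)
  }
})

test_that("degenerate fits raise classed errors", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_plsr(X, rep(1, 10), 1), class = "sl_degenerate")
  expect_error(fit_plsr(matrix(1, 10, 2), rnorm(10), 1),
               class = "sl_degenerate")
  expect_error(fit_plsr(X, rnorm(10), 5), class = "sl_parameter_error")
})

test_that("predict applies the affine form and enforces band contracts", {
  co <- regression_coefficients(c(0, 0), 5, c(500, 600))
  X <- matrix(rnorm(8), 4, 2)
  expect_equal(predict(co, X), rep(5, 4))
  # hand-computed 2x2 dot products
  co2 <- regression_coefficients(c(2, -1), 0.5, c(500, 600))
  X2 <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(predict(co2, X2), c(2 * 1 - 1 * 2 + 0.5, 2 * 3 - 1 * 4 + 0.5))
  err <- expect_error(predict(co2, X2, band_nm = c(500, 601)),
                      class = "sl_contract_error")
  expect_match(conditionMessage(err), "601")
  # superposition: prediction is affine in X
  A <- matrix(rnorm(8), 4, 2); B <- matrix(rnorm(8), 4, 2)
  lhs <- predict(co2, A + B)
  rhs <- predict(co2, A) + predict(co2, B) - co2$intercept
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("extracted coefficients reproduce the internal fitted values", {
  set.seed(8)
  X <- matrix(rnorm(25 * 5), 25, 5)
  y <- drop(X %*% c(1, -2, 0.5, 0, 3)) + rnorm(25, sd = 0.1)
  for (h in c(2, 5)) {
    fit <- fit_plsr(X, y, h)
    expect_equal(predict(extract_regression(fit), X), fit$fitted,
                 tolerance = 1e-8)
  }
})

test_that("joint PCA reconstructs, orders variance, and weighs duplicates equally", {
  set.seed(13)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- drop(X %*% c(1, 2, -1, 0.5)) + rnorm(30, sd = 0.2)
  full <- fit_joint_pca(X, y, 5)
  expect_lt(max(abs(full$Z_resid)), 1e-10)
  expect_true(all(diff(full$eigenvalues[1:5]) <= 1e-10))
  expect_equal(crossprod(full$P_z), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # two identical predictor columns: the leading direction weighs them equally
  X2 <- cbind(X[, 1], X[, 1])
  jm <- fit_joint_pca(X2, y, 1)
  w <- jm$P_z[2:3, 1]
  expect_equal(w[1], w[2], tolerance = 1e-10)
})

test_that("joint-PCA regression recovers a noiseless linear map", {
  set.seed(17)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- drop(X %*% c(2, -1, 0.5)) + 4
  jm <- fit_joint_pca(X, y, 3)
  co <- extract_regression(jm)
  expect_equal(co$source, "YX-PCA")
  expect_equal(predict(co, X), y, tolerance = 1e-8)
  # h covering the full space makes the response column self-reproducing
  expect_error(extract_regression(fit_joint_pca(X, y, 4)),
               class = "sl_numeric_error")
})

test_that("select_components picks the smallest sufficient count", {
  set.seed(29)
  n <- 40
  t1 <- rnorm(n); t2 <- rnorm(n)
  X <- cbind(t1, t1 + 0.01 * t2, t2, t2 - 0.5 * t1, rnorm(n, sd = 1e-3))
  y <- 3 * t1 - 2 * t2
  vp <- select_components(X, y, 4, variance_threshold_pct = 99.9)
  expect_identical(vp$chosen_h, 2L)
  expect_true(all(diff(vp$y_cum) >= -1e-10))
  expect_true(all(vp$y_cum <= 100 + 1e-8))
  vp0 <- select_components(X, y, 4, variance_threshold_pct = 0)
  expect_identical(vp0$chosen_h, 1L)
})

test_that("parameter recovery at 1% noise: coefficient correlation >= 0.99", {
  set.seed(64)
  n <- 64; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(3, -2, 1.5, 0.8, -1.2, 2.5)
  signal <- drop(X %*% beta)
  y <- signal + rnorm(n, sd = 0.01 * sd(signal))
  co <- extract_regression(fit_plsr(X, y, p))
  expect_gte(cor(co$beta, beta), 0.99)
})

test_that("model JSON serialization round-trips coefficients and metadata", {
  co <- regression_coefficients(c(1.5, -2.25), 0.125, c(500.5, 600.25))
  path <- file.path(withr::local_tempdir(), "m.json")
  write_model_json(co, path, meta = list(method = "FDR", h = 2L))
  back <- read_model_json(path)
  expect_equal(back$coeffs$beta, co$beta)
  expect_equal(back$coeffs$intercept, co$intercept)
  expect_equal(back$coeffs$band_nm, co$band_nm)
  expect_identical(back$method, "FDR")
})
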
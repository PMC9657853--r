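# VIP scores and the three waveband selectors

# build a PLS fit whose single weight vector is exactly proportional to w_target
fit_with_weights <- function(w_target, n = 24, seed = 2) {
  set.seed(seed)
  p <- length(w_target)
  M <- matrix(rnorm(n * p), n, p)
  # centre first, then orthonormalize: the Q columns stay mean-zero, so the
  # PLS weight is exactly proportional to w_target
  Q <- qr.Q(qr(sweep(M, 2, colMeans(M))))
  y <- drop(Q %*% w_target)
  fit_plsr(Q, y, 1)
}

test_that("VIP matches the hand-computed two-band case", {
  fit <- fit_with_weights(c(0.8, 0.6))
  vip <- compute_vip(fit)
  # h = 1, w = (0.8, 0.6): VIP = sqrt(2) * (0.8, 0.6)
  expect_equal(vip$scores, sqrt(2) * c(0.8, 0.6), tolerance = 1e-6)
  # direct summation oracle for the same model
  p <- fit$p
  ss <- fit$b^2 * colSums(fit$T^2)
  oracle <- sapply(seq_len(p), function(j) {
    num <- 0
    for (i in seq_len(fit$h))
      num <- num + ss[i] * (fit$W[j, i] / sqrt(sum(fit$W[, i]^2)))^2
    sqrt(p * num / sum(ss))
  })
  expect_equal(vip$scores, oracle, tolerance = 1e-12)
})

test_that("equal weights give unit VIP everywhere; h = 1 closed form holds", {
  fit <- fit_with_weights(rep(0.5, 4))
  expect_equal(compute_vip(fit)$scores, rep(1, 4), tolerance = 1e-8)
  set.seed(77)
  w <- rnorm(7)
  fit2 <- fit_with_weights(w, n = 30, seed = 78)
  vip2 <- compute_vip(fit2)
  expect_equal(vip2$scores,
               sqrt(7) * abs(fit2$W[, 1]) / sqrt(sum(fit2$W[, 1]^2)),
               tolerance = 1e-10)
})

test_that("the mean squared VIP score is 1 for arbitrary fitted models", {
  for (i in 1:12) {
    set.seed(300 + i)
    n <- sample(10:60, 1); p <- sample(4:30, 1)
    h <- sample.int(min(n - 1, p, 6), 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% rnorm(p)) + rnorm(n)
    vip <- compute_vip(fit_plsr(X, y, h))
    expect_equal(mean(vip$scores^2), 1, tolerance = 1e-10)
  }
})

test_that("select_by_vip applies a strict threshold, peak reduction, and caps", {
  mk_vip <- function(scores, wl = seq(400, by = 10, length.out = length(scores)))
    structure(list(scores = scores, band_nm = wl, h_used = 1L,
                   p = length(scores)), class = "vip_scores")
  flat <- mk_vip(rep(1, 10))
  sel <- select_by_vip(flat, threshold = 1, max_bands = 5)
  expect_identical(nrow(sel), 0L)
  expect_true(attr(sel, "empty"))

  spike <- mk_vip(c(0.2, 0.2, 2, 0.2, 0.2))
  sel2 <- select_by_vip(spike, max_bands = 3)
  expect_identical(sel2$band_index, 3L)

  # two equal peaks above threshold, cap 1: tie goes to the lower wavelength
  two <- mk_vip(c(0.1, 1.5, 0.1, 1.5, 0.1))
  sel3 <- select_by_vip(two, max_bands = 1)
  expect_identical(sel3$band_index, 2L)
})

test_that("select_by_coefficients ranks |beta| peaks with documented ties", {
  co <- regression_coefficients(c(0, 1, 0, 0, -3, 0), 0,
                                seq(400, by = 10, length.out = 6))
  sel <- select_by_coefficients(co, 1)
  expect_identical(sel$band_index, 5L)
  sel2 <- select_by_coefficients(co, 2)
  expect_identical(sel2$band_index, c(2L, 5L)) # sorted by wavelength

  # alternating +/- c: every band ties; the first k bands win
  alt <- regression_coefficients(rep(c(0.4, -0.4), 5), 0,
                                 seq(400, by = 10, length.out = 10))
  sel3 <- select_by_coefficients(alt, 3)
  expect_identical(sel3$band_index, 1:3)

  expect_warning(sel4 <- select_by_coefficients(co, 5))
  expect_true(attr(sel4, "truncated"))
  expect_identical(nrow(sel4), 2L) # only the two genuine |beta| peaks exist
})

test_that("select_by_fdr snaps representatives to the nearest grid band", {
  wl <- seq(390.57, 1008.6, length.out = 462)
  reg <- structure(data.frame(
    start_nm = 700, end_nm = 730, start_index = 1L, end_index = 10L,
    representative_nm = 713.51, peak_magnitude = 0.01),
    class = c("waveband_regions", "data.frame"))
  sel <- select_by_fdr(reg, wl)
  expect_identical(nrow(sel), 1L)
  expect_identical(sel$band_index, which.min(abs(wl - 713.51)))

  empty <- structure(data.frame(
    start_nm = numeric(0), end_nm = numeric(0), start_index = integer(0),
    end_index = integer(0), representative_nm = numeric(0),
    peak_magnitude = numeric(0)), class = c("waveband_regions", "data.frame"))
  sel0 <- select_by_fdr(empty, wl)
  expect_identical(nrow(sel0), 0L)
  expect_true(attr(sel0, "empty"))
})

test_that("COEF and VIP selections are invariant to affine rescaling of y", {
  set.seed(404)
  n <- 48; p <- 20
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% c(rep(0, 8), 4, rep(0, 5), -3, rep(0, 5))) + rnorm(n, sd = 0.05)
  wl <- seq(400, by = 10, length.out = p)
  f1 <- fit_plsr(X, y, 3, band_nm = wl)
  f2 <- fit_plsr(X, 2.5 * y - 40, 3, band_nm = wl)
  s1 <- select_by_coefficients(extract_regression(f1), 2)
  s2 <- select_by_coefficients(extract_regression(f2), 2)
  expect_identical(s1$band_index, s2$band_index)
  v1 <- select_by_vip(compute_vip(f1), max_bands = 2)
  v2 <- select_by_vip(compute_vip(f2), max_bands = 2)
  expect_identical(v1$band_index, v2$band_index)
  expect_equal(compute_vip(f1)$scores, compute_vip(f2)$scores,
               tolerance = 1e-9)
})

test_that("selection CSV serialization is 0-based and lossless", {
  co <- regression_coefficients(c(0, 2, 0, -1, 0), 0,
                                seq(500, by = 5, length.out = 5))
  sel <- select_by_coefficients(co, 2)
  path <- file.path(withr::local_tempdir(), "sel.csv")
  write_selection_csv(sel, path)
  back <- utils::read.csv(path)
  expect_identical(back$band_idx0, sel$band_index - 1L)
  expect_identical(back$method, rep("COEF", 2L))
})
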
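# shared fixtures: tiny grids, cubes, and float32 snapping for ENVI
# round-trip checks

grid12 <- seq(400, 900, length.out = 12)

toy_spectrum <- function(values, wl = seq(400, 400 + length(values) - 1)) {
  mean_spectrum(values, wl)
}

# snap doubles to their float32 representation (what an ENVI file stores)
snap32 <- function(x) {
  readBin(writeBin(as.vector(as.numeric(x)), raw(), size = 4L),
          "numeric", n = length(x), size = 4L)
}

random_cube <- function(nr = 4, nc = 4, nb = 12, seed = 1,
                        wl = seq(400, 900, length.out = nb)) {
  set.seed(seed)
  spectral_cube(array(snap32(runif(nr * nc * nb, 0, 1)), c(nr, nc, nb)), wl)
}

# a nutrient vector sitting at the configured means
mean_nutrients <- function(cfg) cfg$nutrient_means

# canonical noiseless fixtures for region detection: the generator baseline
# pushed through the standard smoothing/NDS/FDR path
baseline_fdr <- function(system, window = 13) {
  cfg <- synthetic_config(system, noise_sd = 0)
  sp <- mean_spectrum(spectroleaf:::baseline_reflectance(cfg),
                      cfg$wavelengths_nm)
  compute_fdr(compute_nds(smooth_moving_average(sp, window)))
}

# independent brute-force oracles (direct summation, no vectorized reuse)
oracle_rmse <- function(y, p) {
  s <- 0
  for (k in seq_along(y)) s <- s + (y[k] - p[k])^2
  sqrt(s / length(y))
}

oracle_pearson <- function(x, y) {
  xb <- sum(x) / length(x); yb <- sum(y) / length(y)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_along(x)) {
    num <- num + (x[i] - xb) * (y[i] - yb)
    dx <- dx + (x[i] - xb)^2
    dy <- dy + (y[i] - yb)^2
  }
  num / sqrt(dx * dy)
}

oracle_ols_fit <- function(X, y) {
  Xc <- cbind(1, X)
  drop(Xc %*% solve(crossprod(Xc), crossprod(Xc, y)))
}
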
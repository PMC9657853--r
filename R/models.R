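# Latent-variable regression models: NIPALS PLS1 and joint response-predictor
# PCA, regression-coefficient extraction, prediction, and component-count
# selection by explained response variance.

check_predictors <- function(X, band_nm = NULL, min_n = 2L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X)))
    abort_sl("predictor matrix must be finite with no missing values",
             "sl_contract_error")
  if (nrow(X) < min_n || ncol(X) < 1L)
    abort_sl(sprintf("predictor matrix needs n >= %d samples and p >= 1 bands",
                     min_n), "sl_precondition")
  if (is.null(band_nm)) {
    band_nm <- suppressWarnings(as.numeric(colnames(X)))
    if (length(band_nm) == 0L || anyNA(band_nm))
      band_nm <- rep(NA_real_, ncol(X))
  }
  if (!anyNA(band_nm) && is.unsorted(band_nm, strictly = TRUE))
    abort_sl("predictor columns must be ordered by increasing wavelength",
             "sl_contract_error")
  list(X = X, band_nm = as.numeric(band_nm))
}

check_response <- function(y, n) {
  y <- as.numeric(y)
  if (length(y) != n)
    abort_sl(sprintf("response has %d values but X has %d rows",
                     length(y), n), "sl_contract_error")
  if (anyNA(y) || any(!is.finite(y)))
    abort_sl("response must be finite with no missing values",
             "sl_contract_error")
  y
}

#' Fit a univariate-response PLS regression (NIPALS PLS1)
#'
#' Decomposes the mean-centred predictor matrix as `X = T P' + E` and the
#' centred response as `y = T b + f`, extracting components that maximise
#' covariance between X-scores and the response. For a single response the
#' NIPALS weight update is closed-form, so each component is computed in one
#' pass: weight `w_i = X'y / ||X'y||`, score `t_i = X w_i`, X-loading
#' `p_i = X't_i / t_i't_i`, inner coefficient `b_i = y't_i / t_i't_i`,
#' followed by deflation of X and y.
#'
#' @param X n x p matrix of mean reflectance values (columns ordered by
#'   wavelength; wavelengths may be given as numeric column names or via
#'   `band_nm`).
#' @param y numeric response vector of length n.
#' @param h number of latent components, `1 <= h <= min(n - 1, p)`.
#' @param band_nm optional numeric vector of the p wavelengths.
#' @return an object of class `"pls_model"` with score matrices `T` (X-scores)
#'   and `U` (response working residual per component, the univariate-response
#'   Y-scores), loadings `P`, Y-loadings `Q` (= inner coefficients), weights
#'   `W`, inner coefficients `b`, residuals `X_resid`/`Y_resid`, centring
#'   offsets, fitted values, and bookkeeping fields.
#' @export
fit_plsr <- function(X, y, h, band_nm = NULL) {
  cx <- check_predictors(X, band_nm)
  X <- cx$X
  n <- nrow(X); p <- ncol(X)
  y <- check_response(y, n)
  h_max <- min(n - 1L, p)
  if (!is_count(h) || h > h_max)
    abort_sl(sprintf("h must be an integer in [1, %d]; got %s",
                     h_max, toString(h)), "sl_parameter_error")
  if (stats::var(y) == 0)
    abort_sl("response has zero variance", "sl_degenerate")
  col_var <- apply(X, 2L, stats::var)
  if (all(col_var == 0))
    abort_sl("all predictor columns are constant", "sl_degenerate")

  X_mean <- colMeans(X); Y_mean <- mean(y)
  Xd <- sweep(X, 2L, X_mean)
  yd <- y - Y_mean
  Tm <- matrix(0, n, h); Um <- matrix(0, n, h)
  Pm <- matrix(0, p, h); Wm <- matrix(0, p, h)
  b <- numeric(h)
  h_used <- 0L
  for (i in seq_len(h)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps * p) break # response variance exhausted
    w <- w / nw
    t_i <- drop(Xd %*% w)
    tt <- sum(t_i^2)
    if (tt < .Machine$double.eps) break
    p_i <- drop(crossprod(Xd, t_i)) / tt
    b_i <- sum(yd * t_i) / tt
    Tm[, i] <- t_i
    Um[, i] <- yd # univariate Y-score: the working response residual
    Pm[, i] <- p_i
    Wm[, i] <- w
    b[i] <- b_i
    Xd <- Xd - tcrossprod(t_i, p_i)
    yd <- yd - b_i * t_i
    h_used <- i
  }
  if (h_used == 0L)
    abort_sl("response is numerically unrelated to the predictors",
             "sl_degenerate")
  if (h_used < h) {
    Tm <- Tm[, seq_len(h_used), drop = FALSE]
    Um <- Um[, seq_len(h_used), drop = FALSE]
    Pm <- Pm[, seq_len(h_used), drop = FALSE]
    Wm <- Wm[, seq_len(h_used), drop = FALSE]
    b <- b[seq_len(h_used)]
  }
  fitted <- drop(Tm %*% b) + Y_mean
  structure(list(
    T = Tm, U = Um, P = Pm, Q = matrix(b, 1L, h_used), W = Wm, b = b,
    X_resid = Xd, Y_resid = yd, X_mean = X_mean, Y_mean = Y_mean,
    h = h_used, h_requested = as.integer(h), n = n, p = p,
    band_nm = cx$band_nm, fitted = fitted, y = y), class = "pls_model")
}

#' Fit a joint response-predictor PCA model
#'
#' Stacks the response as the first column of `Z = [y X]`, autoscales each
#' column (the response and the reflectance columns have incommensurate
#' units), and extracts the top `h` principal directions of the scaled matrix
#' by singular value decomposition: `Z_s = T_z P_z' + E`.
#'
#' @param X n x p predictor matrix.
#' @param y numeric response vector of length n.
#' @param h number of components, `1 <= h <= min(n - 1, p + 1)`.
#' @param band_nm optional numeric vector of the p wavelengths.
#' @return an object of class `"joint_pca_model"` with orthonormal loadings
#'   `P_z` ((1+p) x h), scores `T_z`, residual `Z_resid`, per-column centring
#'   and scaling, and per-component explained variance.
#' @export
fit_joint_pca <- function(X, y, h, band_nm = NULL) {
  cx <- check_predictors(X, band_nm)
  X <- cx$X
  n <- nrow(X); p <- ncol(X)
  y <- check_response(y, n)
  h_max <- min(n - 1L, p + 1L)
  if (!is_count(h) || h > h_max)
    abort_sl(sprintf("h must be an integer in [1, %d]; got %s",
                     h_max, toString(h)), "sl_parameter_error")
  if (stats::var(y) == 0)
    abort_sl("response has zero variance", "sl_degenerate")
  Z <- cbind(y, X)
  Z_mean <- colMeans(Z)
  Z_sd <- apply(Z, 2L, stats::sd)
  # constant predictor columns carry no information; give them unit scale so
  # the scaled column is exactly zero rather than NaN
  Z_sd[Z_sd == 0] <- 1
  Zs <- sweep(sweep(Z, 2L, Z_mean), 2L, Z_sd, "/")
  sv <- svd(Zs, nu = 0, nv = h_max)
  P_z <- sv$v[, seq_len(h), drop = FALSE]
  T_z <- Zs %*% P_z
  ev <- sv$d^2 / (n - 1L)
  structure(list(
    P_z = P_z, T_z = T_z, Z_resid = Zs - tcrossprod(T_z, P_z),
    Z_mean = Z_mean, Z_sd = Z_sd, h = as.integer(h), n = n, p = p,
    eigenvalues = ev, explained_pct = 100 * ev / sum(ev),
    band_nm = cx$band_nm, y = y), class = "joint_pca_model")
}

#' Extract multivariate regression coefficients from a fitted model
#'
#' Reduces a fitted latent-variable model to the linear form
#' `y_hat = sum_i beta_i x_i + C` in raw (uncentred, unscaled) units.
#'
#' For PLS1 the reduction is the standard `beta = W (P'W)^{-1} b`. For the
#' joint PCA model, write the loadings as `P_z = [a; B]` with `a` the response
#' row; requiring the reconstruction of the response column to be
#' self-consistent for a new sample gives `beta_s = B a / (1 - a'a)` in scaled
#' units, which is then mapped back to raw units.
#'
#' @param model a `"pls_model"` or `"joint_pca_model"`.
#' @return an object of class `"regression_coefficients"`: fields `beta`
#'   (length p), `intercept`, `band_nm`, `source` (`"PLSR"` or `"YX-PCA"`).
#' @export
extract_regression <- function(model) UseMethod("extract_regression")

#' @export
extract_regression.pls_model <- function(model) {
  PtW <- crossprod(model$P, model$W)
  R <- tryCatch(model$W %*% solve(PtW),
                error = function(e) abort_sl(sprintf(
                  "P'W is numerically singular (h = %d): %s",
                  model$h, conditionMessage(e)), "sl_numeric_error"))
  beta <- drop(R %*% model$b)
  intercept <- model$Y_mean - sum(model$X_mean * beta)
  regression_coefficients(beta, intercept, model$band_nm, "PLSR")
}

#' @export
extract_regression.joint_pca_model <- function(model) {
  a <- model$P_z[1L, ]
  B <- model$P_z[-1L, , drop = FALSE]
  denom <- 1 - sum(a^2)
  if (abs(denom) < 1e-10)
    abort_sl(paste0(
      "joint PCA components reproduce the response column exactly ",
      "(response loading norm ~ 1); reduce h to extract a regression"),
      "sl_numeric_error")
  beta_s <- drop(B %*% a) / denom
  sd_y <- model$Z_sd[1L]; sd_x <- model$Z_sd[-1L]
  mu_y <- model$Z_mean[1L]; mu_x <- model$Z_mean[-1L]
  beta <- beta_s * sd_y / sd_x
  intercept <- mu_y - sum(mu_x * beta)
  regression_coefficients(beta, intercept, model$band_nm, "YX-PCA")
}

#' Construct a regression-coefficient object
#'
#' @param beta numeric coefficient vector (response units per reflectance
#'   unit).
#' @param intercept constant term, response units.
#' @param band_nm wavelengths the coefficients attach to (NA when unknown).
#' @param source `"PLSR"` or `"YX-PCA"`.
#' @return an object of class `"regression_coefficients"`.
#' @export
regression_coefficients <- function(beta, intercept,
                                    band_nm = rep(NA_real_, length(beta)),
                                    source = c("PLSR", "YX-PCA")) {
  source <- match.arg(source)
  beta <- as.numeric(beta)
  if (anyNA(beta) || any(!is.finite(beta)) || !is_number(intercept))
    abort_sl("coefficients and intercept must be finite", "sl_numeric_error")
  if (length(band_nm) != length(beta))
    abort_sl("band_nm length must match beta", "sl_contract_error")
  structure(list(beta = beta, intercept = intercept,
                 band_nm = as.numeric(band_nm), source = source),
            class = "regression_coefficients")
}

#' Predict responses from extracted regression coefficients
#'
#' Computes `y_hat = X beta + C`. When both the coefficients and `X` carry
#' wavelengths, they must agree band by band.
#'
#' @param object a `"regression_coefficients"` object.
#' @param X n x p matrix of reflectance values at the coefficient wavebands.
#' @param band_nm optional wavelengths of the columns of `X`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.regression_coefficients <- function(object, X, band_nm = NULL, ...) {
  cx <- check_predictors(X, band_nm, min_n = 1L)
  X <- cx$X
  if (ncol(X) != length(object$beta))
    abort_sl(sprintf("X has %d bands but the model has %d coefficients",
                     ncol(X), length(object$beta)), "sl_contract_error")
  if (!anyNA(object$band_nm) && !anyNA(cx$band_nm)) {
    off <- which(abs(object$band_nm - cx$band_nm) > 1e-6)
    if (length(off))
      abort_sl(sprintf(
        "waveband mismatch between X and coefficients at: %s",
        paste(sprintf("%.2f nm (model %.2f nm)", cx$band_nm[off],
                      object$band_nm[off]), collapse = ", ")),
        "sl_contract_error")
  }
  drop(X %*% object$beta) + object$intercept
}

#' Choose the number of PLS components by explained response variance
#'
#' Fits PLS1 with up to `h_max` components (NIPALS components are nested, so
#' a single fit yields every sub-model) and records the cumulative percentage
#' of centred-response variance explained at each component count, plus the
#' analogous predictor-variance curve. The chosen count is the smallest `h`
#' whose cumulative response variance reaches `variance_threshold_pct`, or
#' `h_max` when none does.
#'
#' @param X n x p predictor matrix.
#' @param y response vector.
#' @param h_max largest component count to examine.
#' @param variance_threshold_pct target cumulative percentage. Default 95.
#' @param band_nm optional wavelengths.
#' @return an object of class `"variance_profile"`: per-component and
#'   cumulative explained-variance percentages for X and Y, and `chosen_h`.
#' @export
select_components <- function(X, y, h_max, variance_threshold_pct = 95,
                              band_nm = NULL) {
  if (!is_number(variance_threshold_pct) || variance_threshold_pct < 0 ||
      variance_threshold_pct > 100)
    abort_sl("variance_threshold_pct must lie in [0, 100]",
             "sl_parameter_error")
  fit <- fit_plsr(X, y, h_max, band_nm = band_nm)
  yc <- fit$y - fit$Y_mean
  ss_y <- sum(yc^2)
  Xc <- sweep(check_predictors(X)$X, 2L, fit$X_mean)
  ss_x <- sum(Xc^2)
  h_fit <- fit$h
  y_cum <- numeric(h_fit); x_pct <- numeric(h_fit)
  for (k in seq_len(h_fit)) {
    fitted_k <- drop(fit$T[, seq_len(k), drop = FALSE] %*% fit$b[seq_len(k)])
    y_cum[k] <- 100 * (1 - sum((yc - fitted_k)^2) / ss_y)
    x_pct[k] <- 100 * sum(tcrossprod(fit$T[, k], fit$P[, k])^2) / ss_x
  }
  x_cum <- cumsum(x_pct)
  y_pct <- diff(c(0, y_cum))
  reached <- which(y_cum >= variance_threshold_pct)
  chosen_h <- if (length(reached)) reached[1L] else h_fit
  structure(list(
    y_pct = y_pct, y_cum = y_cum, x_pct = x_pct, x_cum = x_cum,
    chosen_h = as.integer(chosen_h), h_max = as.integer(h_max),
    h_fitted = h_fit, threshold_pct = variance_threshold_pct),
    class = "variance_profile")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> n = %d, p = %d, h = %d; in-sample R2 = %.4f\n",
              x$n, x$p, x$h, r_squared(x$y, x$fitted)))
  invisible(x)
}

#' @export
print.joint_pca_model <- function(x, ...) {
  cat(sprintf(
    "<joint_pca_model> n = %d, p = %d, h = %d; %.1f%% of joint variance\n",
    x$n, x$p, x$h, sum(x$explained_pct[seq_len(x$h)])))
  invisible(x)
}

#' @export
print.regression_coefficients <- function(x, ...) {
  cat(sprintf("<regression_coefficients> source %s, %d bands, intercept %.4g\n",
              x$source, length(x$beta), x$intercept))
  invisible(x)
}

#' @export
print.variance_profile <- function(x, ...) {
  cat(sprintf(
    "<variance_profile> chosen h = %d (>= %.1f%% of response variance at h = %d of %d)\n",
    x$chosen_h, x$threshold_pct, x$chosen_h, x$h_fitted))
  invisible(x)
}

#' Serialize a regression model to JSON
#'
#' Stores coefficients, intercept, band list and provenance metadata so a
#' model can be re-applied without refitting.
#'
#' @param coeffs a `"regression_coefficients"` object.
#' @param path output JSON path.
#' @param meta named list of provenance fields (method, h, config hash, ...).
#' @return invisibly, `path`.
#' @export
write_model_json <- function(coeffs, path, meta = list()) {
  payload <- c(list(
    source = coeffs$source,
    beta = coeffs$beta,
    intercept = coeffs$intercept,
    band_nm = coeffs$band_nm), meta)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a regression model written by [write_model_json()]
#' @param path JSON path.
#' @return a list with a `"regression_coefficients"` object under `$coeffs`
#'   and all remaining metadata fields.
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  coeffs <- regression_coefficients(payload$beta, payload$intercept,
                                    payload$band_nm, payload$source)
  meta <- payload[setdiff(names(payload),
                          c("beta", "intercept", "band_nm", "source"))]
  c(list(coeffs = coeffs), meta)
}
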
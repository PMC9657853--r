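# Model evaluation: RMSE, coefficient of determination, band-windowed Pearson
# cross-correlation, and assembly of method-comparison reports.

#' Root mean square error
#'
#' `RMSE = sqrt( sum_k (y_k - yhat_k)^2 / n )`.
#'
#' @param measured numeric vector of laboratory-measured values.
#' @param predicted numeric vector of model predictions, same length.
#' @return a single non-negative number in response units.
#' @export
rmse <- function(measured, predicted) {
  measured <- as.numeric(measured); predicted <- as.numeric(predicted)
  if (length(measured) != length(predicted))
    abort_sl(sprintf("length mismatch: %d measured vs %d predicted",
                     length(measured), length(predicted)), "sl_contract_error")
  if (length(measured) < 1L)
    abort_sl("rmse needs at least one observation", "sl_precondition")
  sqrt(mean((measured - predicted)^2))
}

#' Coefficient of determination
#'
#' `R2 = 1 - sum (y - yhat)^2 / sum (y - ybar)^2`; defined through residual
#' and total sums of squares so that a fit worse than the mean yields a
#' negative value.
#'
#' @param measured numeric vector with non-zero variance, length >= 2.
#' @param predicted numeric vector of predictions, same length.
#' @return a single number `<= 1`.
#' @export
r_squared <- function(measured, predicted) {
  measured <- as.numeric(measured); predicted <- as.numeric(predicted)
  if (length(measured) != length(predicted))
    abort_sl(sprintf("length mismatch: %d measured vs %d predicted",
                     length(measured), length(predicted)), "sl_contract_error")
  if (length(measured) < 2L)
    abort_sl("r_squared needs at least two observations", "sl_precondition")
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0)
    abort_sl("measured values have zero variance; R2 undefined",
             "sl_degenerate")
  1 - sum((measured - predicted)^2) / ss_tot
}

#' Band-windowed Pearson cross-correlation of two spectra
#'
#' Zero-lag Pearson product-moment correlation of two spectra restricted to
#' the bands whose wavelength lies inside `window_nm` (inclusive at both
#' ends). The default window is the blue-green range over which solution and
#' leaf reflectance co-vary with the applied nitrogen concentration.
#'
#' @param x a [mean_spectrum()] (conventionally the nutrient solution).
#' @param y a [mean_spectrum()] on the same grid (conventionally the leaf).
#' @param window_nm numeric `(low, high)` wavelength window. Default
#'   `c(390.57, 554.48)`.
#' @return an object of class `"correlation_result"`: `r_corr`,
#'   `band_window_nm`, `n_bands`, and the two labels.
#' @export
cross_correlation <- function(x, y, window_nm = c(390.57, 554.48)) {
  stopifnot(inherits(x, "mean_spectrum"), inherits(y, "mean_spectrum"))
  if (length(x$values) != length(y$values) ||
      any(abs(x$wavelengths_nm - y$wavelengths_nm) > 1e-9))
    abort_sl("the two spectra must share one wavelength grid",
             "sl_contract_error")
  if (length(window_nm) != 2L || !all(is.finite(window_nm)) ||
      window_nm[1L] >= window_nm[2L])
    abort_sl("window_nm must be an increasing (low, high) pair",
             "sl_parameter_error")
  idx <- which(x$wavelengths_nm >= window_nm[1L] &
               x$wavelengths_nm <= window_nm[2L])
  if (length(idx) < 3L)
    abort_sl(sprintf("only %d bands fall in [%.2f, %.2f] nm; need >= 3",
                     length(idx), window_nm[1L], window_nm[2L]),
             "sl_precondition")
  structure(list(
    r_corr = stats::cor(x$values[idx], y$values[idx]),
    band_window_nm = as.numeric(window_nm),
    n_bands = length(idx),
    solution_label = x$label, leaf_label = y$label),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.4f over %d bands in [%.2f, %.2f] nm\n",
              x$r_corr, x$n_bands, x$band_window_nm[1L], x$band_window_nm[2L]))
  invisible(x)
}

#' Assemble a method-comparison evaluation report
#'
#' Collects per-model accuracy rows into one table and flags, within every
#' (cultivar, system, response) cell, the selection method with the highest
#' R-squared (lowest RMSE on ties).
#'
#' @param rows a `data.frame` (or list of row lists) with columns `cultivar`,
#'   `system`, `response`, `method`, `R2`, `RMSE`, `n`, `h`.
#' @return the report as a `data.frame` of class `"evaluation_report"` with an
#'   added logical `best` column, ordered by cultivar, system, response,
#'   method.
#' @export
build_report <- function(rows) {
  if (!is.data.frame(rows))
    rows <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  needed <- c("cultivar", "system", "response", "method", "R2", "RMSE", "n", "h")
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols))
    abort_sl(sprintf("report rows lack columns: %s",
                     paste(missing_cols, collapse = ", ")), "sl_format_error")
  if (any(rows$RMSE < 0, na.rm = TRUE) || any(rows$R2 > 1 + 1e-12, na.rm = TRUE))
    abort_sl("invalid accuracy values (RMSE < 0 or R2 > 1)", "sl_format_error")
  key <- interaction(rows$cultivar, rows$system, rows$response, drop = TRUE)
  if (anyDuplicated(interaction(key, rows$method, drop = TRUE)))
    abort_sl("duplicate (cultivar, system, response, method) rows",
             "sl_format_error")
  best <- logical(nrow(rows))
  for (g in split(seq_len(nrow(rows)), key)) {
    o <- g[order(-rows$R2[g], rows$RMSE[g])]
    best[o[1L]] <- TRUE
  }
  rows$best <- best
  rows <- rows[order(rows$cultivar, rows$system, rows$response, rows$method), ,
               drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, class = c("evaluation_report", "data.frame"))
}

#' Write an evaluation report to CSV
#' @param report an `"evaluation_report"`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(format_df_for_csv(as.data.frame(report)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an evaluation report written by [write_report_csv()]
#' @param path CSV path.
#' @return an `"evaluation_report"` data frame.
#' @export
read_report_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$best <- as.logical(df$best)
  structure(df, class = c("evaluation_report", "data.frame"))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d rows, %d responses, methods: %s\n",
              nrow(x), length(unique(x$response)),
              paste(sort(unique(x$method)), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
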
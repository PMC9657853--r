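# Waveband selection: derivative-region representatives, regression-
# coefficient peaks, and PLS VIP scores, all reduced to a common
# waveband_selection table.

#' Variable importance in projection (VIP) scores
#'
#' Computes the standard Wold PLS-VIP for every predictor of a fitted PLS1
#' model:
#' `VIP_j = sqrt( p * sum_i SS_i (w_ji / ||w_i||)^2 / sum_i SS_i )`
#' with `SS_i = b_i^2 t_i' t_i`, the response sum of squares captured by
#' component i. By construction the mean of the squared scores is exactly 1
#' (`sum_j VIP_j^2 = p`), so scores above 1 flag above-average importance.
#'
#' @param model a fitted `"pls_model"`.
#' @return an object of class `"vip_scores"`: `scores` (length p,
#'   non-negative), `band_nm`, `h_used`.
#' @export
compute_vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ss <- model$b^2 * colSums(model$T^2)
  if (sum(ss) <= 0)
    abort_sl("every component captures zero response variance; VIP undefined",
             "sl_degenerate")
  w_norm2 <- colSums(model$W^2)
  Wn2 <- sweep(model$W^2, 2L, w_norm2, "/")
  scores <- sqrt(model$p * drop(Wn2 %*% ss) / sum(ss))
  structure(list(scores = scores, band_nm = model$band_nm,
                 h_used = model$h, p = model$p),
            class = "vip_scores")
}

#' @export
print.vip_scores <- function(x, ...) {
  cat(sprintf("<vip_scores> %d bands, h = %d, %d scores > 1\n",
              x$p, x$h_used, sum(x$scores > 1)))
  invisible(x)
}

waveband_selection <- function(method, band_index, band_nm, score,
                               empty = FALSE, truncated = FALSE) {
  o <- order(band_nm, band_index)
  sel <- data.frame(method = rep(method, length(band_index)),
                    band_index = as.integer(band_index[o]),
                    band_nm = as.numeric(band_nm[o]),
                    score = as.numeric(score[o]))
  sel <- sel[!duplicated(sel$band_index), , drop = FALSE]
  rownames(sel) <- NULL
  structure(sel, class = c("waveband_selection", "data.frame"),
            empty = empty, truncated = truncated)
}

#' Select wavebands whose VIP score exceeds a threshold
#'
#' Candidate bands are those with `VIP > threshold` (strict, so a flat curve
#' at exactly 1 selects nothing); the candidates are reduced to local maxima
#' of the VIP curve so each importance peak contributes one band, and, when
#' more than `max_bands` remain, the top `max_bands` by score are kept with
#' ties broken toward the lower wavelength.
#'
#' @param vip a `"vip_scores"` object.
#' @param threshold selection threshold, default 1 (the mean-square level).
#' @param max_bands maximum number of bands returned.
#' @return a `"waveband_selection"` data frame (`method = "VIP"`), sorted by
#'   wavelength, with 1-based `band_index`. An empty selection is returned
#'   (not an error) with attribute `empty = TRUE` when no band qualifies.
#' @export
select_by_vip <- function(vip, threshold = 1.0, max_bands = 6L) {
  stopifnot(inherits(vip, "vip_scores"))
  if (!is_number(threshold) || !is_count(max_bands))
    abort_sl("threshold must be a number and max_bands a positive integer",
             "sl_parameter_error")
  s <- vip$scores
  cand <- intersect(which(s > threshold), local_maxima(s))
  if (length(cand) == 0L)
    return(waveband_selection("VIP", integer(0), numeric(0), numeric(0),
                              empty = TRUE))
  if (length(cand) > max_bands) {
    o <- order(-s[cand], vip$band_nm[cand], cand)
    cand <- cand[o][seq_len(max_bands)]
  }
  waveband_selection("VIP", cand, vip$band_nm[cand], s[cand])
}

#' Select wavebands at the peaks of the regression-coefficient curve
#'
#' Ranks the local maxima of `|beta|` over the full spectrum and returns the
#' top `k`, sorted by wavelength, with ties broken toward the lower
#' wavelength. When fewer than `k` local maxima exist, all of them are
#' returned and the result carries attribute `truncated = TRUE`.
#'
#' @param coeffs full-spectrum `"regression_coefficients"`.
#' @param k number of bands to select.
#' @return a `"waveband_selection"` data frame (`method = "COEF"`).
#' @export
select_by_coefficients <- function(coeffs, k = 6L) {
  stopifnot(inherits(coeffs, "regression_coefficients"))
  if (!is_count(k))
    abort_sl("k must be a positive integer", "sl_parameter_error")
  s <- abs(coeffs$beta)
  peaks <- local_maxima(s)
  truncated <- length(peaks) < k
  if (truncated)
    warning(sprintf("only %d |beta| local maxima available (k = %d)",
                    length(peaks), k), call. = FALSE)
  band_nm <- coeffs$band_nm
  if (anyNA(band_nm)) band_nm <- seq_along(s)
  o <- order(-s[peaks], band_nm[peaks], peaks)
  keep <- peaks[o][seq_len(min(k, length(peaks)))]
  waveband_selection("COEF", keep, coeffs$band_nm[keep], s[keep],
                     truncated = truncated)
}

#' Select one waveband per detected dynamic region
#'
#' Snaps each region's representative wavelength (its `|FDR|` peak) to the
#' nearest band of the grid.
#'
#' @param regions a `"waveband_regions"` data frame from
#'   [detect_dynamic_regions()].
#' @param wavelengths_nm the wavelength grid to snap onto.
#' @return a `"waveband_selection"` data frame (`method = "FDR"`), one band
#'   per region; empty (flagged, not an error) when no regions were supplied.
#' @export
select_by_fdr <- function(regions, wavelengths_nm) {
  stopifnot(inherits(regions, "waveband_regions"))
  wl <- unclass(wavelength_grid(wavelengths_nm))
  if (nrow(regions) == 0L)
    return(waveband_selection("FDR", integer(0), numeric(0), numeric(0),
                              empty = TRUE))
  idx <- vapply(regions$representative_nm, function(t) nearest_band(wl, t), 1L)
  waveband_selection("FDR", idx, wl[idx], regions$peak_magnitude)
}

#' Write waveband selections to CSV
#'
#' Serialized band indices are 0-based (instrument convention).
#'
#' @param selections a `"waveband_selection"` data frame or a list of them
#'   (rows are concatenated). Extra columns (e.g. grouping labels) pass
#'   through.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_selection_csv <- function(selections, path) {
  if (inherits(selections, "waveband_selection")) selections <- list(selections)
  rows <- do.call(rbind, lapply(selections, as.data.frame))
  rows$band_idx0 <- rows$band_index - 1L
  rows$band_index <- NULL
  front <- c("method", "band_idx0", "band_nm", "score")
  rows <- rows[c(front, setdiff(names(rows), front))]
  utils::write.csv(format_df_for_csv(rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
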
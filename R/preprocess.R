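# Spectral preprocessing: moving-average smoothing, normalized-difference
# spectra (NDS), first-order derivative of reflectance (FDR), and detection
# of dynamic waveband regions from the FDR curve.

#' Smooth a spectrum with a centred moving average
#'
#' Applies the standard k-point moving average used to denoise push-broom
#' reflectance data before derivative analysis. At the spectrum edges the
#' window shrinks symmetrically-truncated rather than padding, so no data is
#' invented at the blue or NIR extremes and constants pass through unchanged.
#'
#' @param spectrum a [mean_spectrum()].
#' @param window odd window width in bands, `>= 3` and `<= n_bands`.
#'   Default 13.
#' @return a smoothed [mean_spectrum()] of the same length.
#' @export
smooth_moving_average <- function(spectrum, window = 13L) {
  stopifnot(inherits(spectrum, "mean_spectrum"))
  n <- length(spectrum$values)
  if (!is_count(window, min = 3L) || window %% 2L == 0L || window > n)
    abort_sl(sprintf(
      "window must be an odd integer in [3, %d]; got %s", n, toString(window)),
      "sl_parameter_error")
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, spectrum$values))
  idx <- seq_len(n)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  mean_spectrum(out, spectrum$wavelengths_nm, spectrum$label)
}

#' Normalized-difference spectrum (NDS)
#'
#' Per-spectrum min-max normalization: `(v - min v) / (max v - min v)`. The
#' result lies in `[0, 1]`, preserves the positions of all extrema, and is
#' invariant to positive affine transforms of the input, which makes the
#' downstream derivative thresholds comparable across samples.
#'
#' @param spectrum a [mean_spectrum()] with non-zero range.
#' @return a [mean_spectrum()] of NDS values in `[0, 1]`.
#' @export
compute_nds <- function(spectrum) {
  stopifnot(inherits(spectrum, "mean_spectrum"))
  rng <- range(spectrum$values)
  if (rng[2L] <= rng[1L])
    abort_sl("flat spectrum: NDS undefined when max(values) == min(values)",
             "sl_degenerate")
  mean_spectrum((spectrum$values - rng[1L]) / (rng[2L] - rng[1L]),
                spectrum$wavelengths_nm, spectrum$label)
}

#' First-order derivative of reflectance (FDR)
#'
#' Central finite differences on the actual wavelength grid (one-sided at the
#' two ends), in units of 1/nm. Working on the grid rather than on band
#' indices keeps derivative magnitudes comparable across instruments with
#' non-uniform band spacing.
#'
#' @param spectrum a [mean_spectrum()] (typically NDS or smoothed
#'   reflectance) with at least 3 bands.
#' @return a [derivative_spectrum()] of the same length.
#' @export
compute_fdr <- function(spectrum) {
  stopifnot(inherits(spectrum, "mean_spectrum"))
  v <- spectrum$values
  wl <- spectrum$wavelengths_nm
  n <- length(v)
  if (n < 3L)
    abort_sl("FDR needs at least 3 bands", "sl_precondition")
  d <- numeric(n)
  d[1L] <- (v[2L] - v[1L]) / (wl[2L] - wl[1L])
  d[n] <- (v[n] - v[n - 1L]) / (wl[n] - wl[n - 1L])
  mid <- 2:(n - 1L)
  d[mid] <- (v[mid + 1L] - v[mid - 1L]) / (wl[mid + 1L] - wl[mid - 1L])
  derivative_spectrum(d, wl, spectrum$label)
}

#' Detect dynamic waveband regions from an FDR curve
#'
#' Flags contiguous runs of bands whose absolute derivative exceeds an
#' adaptive threshold `tau = mean(|FDR|) + threshold_factor * sd(|FDR|)`,
#' computed over bands at or below `search_max_nm` (the flat far-NIR tail is
#' excluded so it does not dilute the statistics). Runs shorter than
#' `min_width_bands` are dropped, then surviving runs separated by at most
#' `merge_gap_bands` bands are merged. Each region's representative waveband
#' is the wavelength of its largest `|FDR|` value.
#'
#' @param fdr a [derivative_spectrum()].
#' @param threshold_factor multiplier on the SD term of the threshold.
#'   Default 1.
#' @param min_width_bands minimum run width in bands. Default 5.
#' @param merge_gap_bands maximum gap (bands) between runs that are merged.
#'   Default 3.
#' @param search_max_nm upper wavelength bound of the search. Default 850.
#' @return a `data.frame` of class `"waveband_regions"` with columns
#'   `start_nm`, `end_nm`, `start_index`, `end_index` (1-based, inclusive),
#'   `representative_nm`, `peak_magnitude`, sorted by `start_nm`. Zero rows
#'   is a valid result.
#' @export
detect_dynamic_regions <- function(fdr, threshold_factor = 1.0,
                                   min_width_bands = 5L,
                                   merge_gap_bands = 3L,
                                   search_max_nm = 850) {
  stopifnot(inherits(fdr, "derivative_spectrum"))
  if (!is_number(threshold_factor) || threshold_factor <= 0 ||
      !is_count(min_width_bands) || !is_count(merge_gap_bands, min = 0L) ||
      !is_number(search_max_nm) || search_max_nm <= 0)
    abort_sl("region-detection parameters must be positive", "sl_parameter_error")

  a <- abs(fdr$values)
  wl <- fdr$wavelengths_nm
  in_window <- wl <= search_max_nm
  if (!any(in_window))
    abort_sl("search_max_nm excludes every band", "sl_parameter_error")
  aw <- a[in_window]
  tau <- mean(aw) + threshold_factor * stats::sd(aw)
  if (!is.finite(tau)) tau <- mean(aw)
  # a band is dynamic when it clears tau and carries real signal: an all-zero
  # derivative yields tau = 0 and must produce no regions
  hot <- in_window & a >= tau & a > 0

  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_width_bands
  starts <- starts[keep]; ends <- ends[keep]

  empty <- data.frame(start_nm = numeric(0), end_nm = numeric(0),
                      start_index = integer(0), end_index = integer(0),
                      representative_nm = numeric(0),
                      peak_magnitude = numeric(0))
  if (length(starts) == 0L)
    return(structure(empty, class = c("waveband_regions", "data.frame"),
                     tau = tau))

  # merge runs separated by small gaps
  ms <- starts[1L]; me <- ends[1L]
  out_s <- integer(0); out_e <- integer(0)
  if (length(starts) > 1L) {
    for (i in 2:length(starts)) {
      if (starts[i] - me - 1L <= merge_gap_bands) {
        me <- ends[i]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- starts[i]; me <- ends[i]
      }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)

  rep_idx <- mapply(function(s, e) s - 1L + which.max(a[s:e]), out_s, out_e)
  regions <- data.frame(
    start_nm = wl[out_s], end_nm = wl[out_e],
    start_index = out_s, end_index = out_e,
    representative_nm = wl[rep_idx],
    peak_magnitude = a[rep_idx])
  regions <- regions[order(regions$start_nm), , drop = FALSE]
  rownames(regions) <- NULL
  structure(regions, class = c("waveband_regions", "data.frame"), tau = tau)
}

#' Write detected regions to CSV
#'
#' Band indices are serialized 0-based (instrument convention); in-memory
#' objects are 1-based.
#'
#' @param regions a `"waveband_regions"` data frame.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_regions_csv <- function(regions, path) {
  out <- data.frame(
    start_nm = regions$start_nm, end_nm = regions$end_nm,
    start_idx0 = regions$start_index - 1L,
    end_idx0 = regions$end_index - 1L,
    representative_nm = regions$representative_nm,
    peak_magnitude = regions$peak_magnitude)
  utils::write.csv(format_df_for_csv(out), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read regions written by [write_regions_csv()]
#' @param path CSV path.
#' @return a `"waveband_regions"` data frame (1-based indices).
#' @export
read_regions_csv <- function(path) {
  df <- utils::read.csv(path)
  regions <- data.frame(
    start_nm = df$start_nm, end_nm = df$end_nm,
    start_index = df$start_idx0 + 1L, end_index = df$end_idx0 + 1L,
    representative_nm = df$representative_nm,
    peak_magnitude = df$peak_magnitude)
  structure(regions, class = c("waveband_regions", "data.frame"))
}
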
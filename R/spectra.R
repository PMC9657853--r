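# S3 containers for spectra and hyperspectral cubes.

#' Validate a wavelength grid
#'
#' A wavelength grid is a strictly increasing numeric vector of band-center
#' wavelengths in nanometres. Instruments of the push-broom VNIR family
#' covered here report band centres between 380 and 1100 nm.
#'
#' @param wavelengths_nm numeric vector of band centres (nm).
#' @return the validated numeric vector, invisibly classed as
#'   `"wavelength_grid"`.
#' @export
wavelength_grid <- function(wavelengths_nm) {
  w <- as.numeric(wavelengths_nm)
  if (length(w) < 1L || anyNA(w) || any(!is.finite(w)))
    abort_sl("wavelength grid must be finite and non-empty", "sl_format_error")
  if (any(diff(w) <= 0))
    abort_sl("wavelength grid must be strictly increasing", "sl_format_error")
  if (w[1L] < 380 || w[length(w)] > 1100)
    abort_sl(sprintf(
      "wavelength grid [%.2f, %.2f] nm outside the supported 380-1100 nm range",
      w[1L], w[length(w)]), "sl_format_error")
  structure(w, class = "wavelength_grid")
}

#' Construct a mean reflectance spectrum
#'
#' @param values numeric vector of reflectance, one value per band.
#' @param wavelengths_nm wavelength grid (nm), same length as `values`.
#' @param label optional sample identifier (e.g. cultivar / treatment).
#' @return an object of class `"mean_spectrum"` with fields `values`,
#'   `wavelengths_nm` and `label`.
#' @export
mean_spectrum <- function(values, wavelengths_nm, label = NA_character_) {
  grid <- unclass(wavelength_grid(wavelengths_nm))
  values <- as.numeric(values)
  if (length(values) != length(grid))
    abort_sl("spectrum length does not match its wavelength grid",
             "sl_contract_error")
  if (anyNA(values) || any(!is.finite(values)))
    abort_sl("spectrum values must all be finite", "sl_format_error")
  structure(list(values = values, wavelengths_nm = grid,
                 label = as.character(label)),
            class = "mean_spectrum")
}

#' Construct a first-derivative spectrum
#'
#' Holds d(reflectance)/d(wavelength) in 1/nm on the same grid as its source
#' spectrum.
#'
#' @param values numeric derivative values (1/nm).
#' @param wavelengths_nm wavelength grid (nm).
#' @param source_label identifier of the spectrum the derivative came from.
#' @return an object of class `"derivative_spectrum"`.
#' @export
derivative_spectrum <- function(values, wavelengths_nm,
                                source_label = NA_character_) {
  grid <- unclass(wavelength_grid(wavelengths_nm))
  values <- as.numeric(values)
  if (length(values) != length(grid))
    abort_sl("derivative length does not match its wavelength grid",
             "sl_contract_error")
  if (anyNA(values) || any(!is.finite(values)))
    abort_sl("derivative values must all be finite", "sl_format_error")
  structure(list(values = values, wavelengths_nm = grid,
                 source_label = as.character(source_label)),
            class = "derivative_spectrum")
}

#' Construct a hyperspectral reflectance cube
#'
#' @param reflectance 3-D array `[rows x cols x bands]` of dimensionless
#'   reflectance (expected within `[0, ~1.2]`).
#' @param wavelengths_nm wavelength grid (nm), length equal to the band
#'   dimension.
#' @param roi_mask logical matrix `[rows x cols]` flagging region-of-interest
#'   pixels. Defaults to all-`TRUE`.
#' @return an object of class `"spectral_cube"`.
#' @export
spectral_cube <- function(reflectance, wavelengths_nm, roi_mask = NULL) {
  if (!is.array(reflectance) || length(dim(reflectance)) != 3L)
    abort_sl("reflectance must be a rows x cols x bands 3-D array",
             "sl_contract_error")
  grid <- unclass(wavelength_grid(wavelengths_nm))
  d <- dim(reflectance)
  if (d[3L] != length(grid))
    abort_sl(sprintf("cube has %d bands but grid has %d wavelengths",
                     d[3L], length(grid)), "sl_contract_error")
  if (is.null(roi_mask)) {
    roi_mask <- matrix(TRUE, d[1L], d[2L])
  } else {
    roi_mask <- as.matrix(roi_mask)
    storage.mode(roi_mask) <- "logical"
    if (!identical(dim(roi_mask), d[1:2]))
      abort_sl("roi_mask shape does not match the cube's spatial dimensions",
               "sl_contract_error")
  }
  structure(list(reflectance = reflectance, wavelengths_nm = grid,
                 roi_mask = roi_mask),
            class = "spectral_cube")
}

#' @export
print.mean_spectrum <- function(x, ...) {
  cat(sprintf("<mean_spectrum> %d bands, %.2f-%.2f nm%s\n",
              length(x$values), x$wavelengths_nm[1L],
              x$wavelengths_nm[length(x$wavelengths_nm)],
              if (is.na(x$label)) "" else paste0(", label: ", x$label)))
  invisible(x)
}

#' @export
print.derivative_spectrum <- function(x, ...) {
  cat(sprintf("<derivative_spectrum> %d bands, peak |FDR| %.4g 1/nm\n",
              length(x$values), max(abs(x$values))))
  invisible(x)
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf(
    "<spectral_cube> %d x %d pixels, %d bands (%.2f-%.2f nm), %d ROI pixels\n",
    d[1L], d[2L], d[3L], x$wavelengths_nm[1L],
    x$wavelengths_nm[length(x$wavelengths_nm)], sum(x$roi_mask)))
  invisible(x)
}
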
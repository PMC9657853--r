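# ENVI cube I/O, ROI spectrum extraction, and sample-table I/O.
#
# Supported ENVI dialect: ASCII "key = value" header + raw binary image,
# data type 4 (32-bit little/big-endian float), BIL or BIP interleave,
# wavelength list in nanometres. This matches the output conventions of
# push-broom VNIR cameras without taking on open-ended format scope.

envi_binary_path <- function(header_path, must_exist = FALSE) {
  base <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  candidates <- unique(c(base, paste0(base, c(".img", ".dat", ".raw", ".bil", ".bip"))))
  if (!must_exist) return(paste0(base, ".img"))
  hit <- candidates[file.exists(candidates) & candidates != header_path]
  if (length(hit) == 0L)
    abort_sl(sprintf("no binary image found next to ENVI header '%s'",
                     header_path), "sl_io_error")
  hit[[1L]]
}

parse_envi_header <- function(header_path) {
  txt <- readLines(header_path, warn = FALSE)
  if (length(txt) == 0L || !grepl("^\\s*ENVI\\s*$", txt[1L]))
    abort_sl(sprintf("'%s' is not an ENVI header (missing ENVI magic line)",
                     header_path), "sl_format_error")
  body <- paste(txt[-1L], collapse = "\n")
  keys <- list()
  # tokenizer: scan for 'name = value' where value is either a {...} block
  # (possibly spanning lines) or the remainder of the line
  pattern <- "(?m)^\\s*([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pattern, body, perl = TRUE)[[1L]]
  if (m[1L] != -1L) {
    starts <- m
    lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      entry <- substr(body, starts[i], starts[i] + lens[i] - 1L)
      key <- tolower(trimws(sub("=.*$", "", entry)))
      val <- trimws(sub("^[^=]*=", "", entry))
      keys[[key]] <- val
    }
  }
  keys
}

header_num <- function(keys, name, header_path) {
  if (is.null(keys[[name]]))
    abort_sl(sprintf("ENVI header '%s' lacks required field '%s'",
                     header_path, name), "sl_format_error")
  as.numeric(keys[[name]])
}

#' Read an ENVI hyperspectral cube
#'
#' Reads an ENVI header (`.hdr`) plus its companion raw binary image into a
#' [spectral_cube()]. The wavelength list in the header is taken verbatim as
#' the band grid; reflectance values are returned unscaled. The ROI mask is
#' initialised to all-`TRUE` (masks are not part of the ENVI format; see
#' [nir_threshold_mask()]).
#'
#' Only data type 4 (32-bit float) with BIL or BIP interleave is supported;
#' other data types raise a format error.
#'
#' @param header_path path to the `.hdr` file. The binary image is looked up
#'   next to it (same basename, optionally with `.img`/`.dat`/`.raw`
#'   extension).
#' @return a [spectral_cube()].
#' @export
read_envi_cube <- function(header_path) {
  if (!file.exists(header_path))
    abort_sl(sprintf("ENVI header '%s' does not exist", header_path),
             "sl_io_error")
  keys <- parse_envi_header(header_path)
  bands <- header_num(keys, "bands", header_path)
  lines_n <- header_num(keys, "lines", header_path)
  samples <- header_num(keys, "samples", header_path)
  dtype <- header_num(keys, "data type", header_path)
  if (dtype != 4)
    abort_sl(sprintf(
      "unsupported ENVI data type %d in '%s' (only 4 = 32-bit float)",
      dtype, header_path), "sl_format_error")
  interleave <- tolower(keys[["interleave"]] %||% "")
  if (!interleave %in% c("bil", "bip"))
    abort_sl(sprintf("unsupported interleave '%s' (only bil, bip)",
                     interleave), "sl_format_error")
  if (is.null(keys[["wavelength"]]))
    abort_sl(sprintf("ENVI header '%s' lacks a wavelength list", header_path),
             "sl_format_error")
  wl_txt <- gsub("[{}]", "", keys[["wavelength"]])
  wl <- as.numeric(trimws(strsplit(wl_txt, ",")[[1L]]))
  if (length(wl) != bands)
    abort_sl(sprintf("header declares %d bands but lists %d wavelengths",
                     bands, length(wl)), "sl_format_error")
  endian <- if ((keys[["byte order"]] %||% "0") == "1") "big" else "little"

  bin_path <- envi_binary_path(header_path, must_exist = TRUE)
  n_values <- bands * lines_n * samples
  expected_bytes <- 4 * n_values
  actual_bytes <- file.info(bin_path)$size
  if (actual_bytes != expected_bytes)
    abort_sl(sprintf(
      "binary '%s' holds %d bytes but header implies %d (= %d lines x %d samples x %d bands x 4)",
      bin_path, actual_bytes, expected_bytes, lines_n, samples, bands),
      "sl_io_error")

  con <- file(bin_path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, "numeric", n = n_values, size = 4L, endian = endian)
  if (interleave == "bil") {
    # stored as [samples, bands, lines] fastest-to-slowest
    arr <- array(raw_vals, dim = c(samples, bands, lines_n))
    refl <- aperm(arr, c(3L, 1L, 2L)) # -> rows(lines) x cols(samples) x bands
  } else {
    # bip: stored as [bands, samples, lines]
    arr <- array(raw_vals, dim = c(bands, samples, lines_n))
    refl <- aperm(arr, c(3L, 2L, 1L))
  }
  spectral_cube(refl, wl)
}

#' Write an ENVI hyperspectral cube
#'
#' Emits a standard ENVI ASCII header and raw 32-bit float binary so that
#' [read_envi_cube()] round-trips the reflectance array exactly (at float32
#' precision). The ROI mask is not serialized (it is not part of the format).
#'
#' @param cube a [spectral_cube()].
#' @param header_path output path for the header; must end in `.hdr`. The
#'   binary image is written next to it with extension `.img`.
#' @param interleave `"bil"` (default) or `"bip"`.
#' @return invisibly, the path of the binary image written.
#' @export
write_envi_cube <- function(cube, header_path, interleave = c("bil", "bip")) {
  stopifnot(inherits(cube, "spectral_cube"))
  interleave <- match.arg(interleave)
  if (!grepl("\\.hdr$", header_path, ignore.case = TRUE))
    abort_sl("header_path must end in '.hdr'", "sl_parameter_error")
  dir_ok <- dir.exists(dirname(header_path))
  if (!dir_ok)
    abort_sl(sprintf("output directory '%s' does not exist",
                     dirname(header_path)), "sl_io_error")
  d <- dim(cube$reflectance)
  wl <- format(cube$wavelengths_nm, digits = 12, trim = TRUE,
               scientific = FALSE)
  hdr <- c(
    "ENVI",
    "description = { spectroleaf reflectance cube }",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = { %s }", paste(wl, collapse = ", "))
  )
  bin_path <- envi_binary_path(header_path)
  ok <- tryCatch({
    writeLines(hdr, header_path)
    con <- file(bin_path, "wb")
    on.exit(close(con), add = TRUE)
    vals <- if (interleave == "bil") {
      aperm(cube$reflectance, c(2L, 3L, 1L)) # [samples, bands, lines]
    } else {
      aperm(cube$reflectance, c(3L, 2L, 1L)) # [bands, samples, lines]
    }
    writeBin(as.vector(vals), con, size = 4L, endian = "little")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort_sl(sprintf("failed to write ENVI pair at '%s': %s", header_path,
                     conditionMessage(ok)), "sl_io_error")
  invisible(bin_path)
}

#' Mean spectrum over the region of interest
#'
#' Averages the reflectance of all masked pixels band by band, producing the
#' single per-sample spectrum that downstream smoothing and modeling operate
#' on.
#'
#' @param cube a [spectral_cube()] whose `roi_mask` has at least one `TRUE`
#'   pixel.
#' @param label optional sample label carried into the result.
#' @return a [mean_spectrum()].
#' @export
roi_mean_spectrum <- function(cube, label = NA_character_) {
  stopifnot(inherits(cube, "spectral_cube"))
  n_roi <- sum(cube$roi_mask)
  if (n_roi < 1L)
    abort_sl("ROI mask has no TRUE pixels", "sl_precondition")
  d <- dim(cube$reflectance)
  flat <- matrix(cube$reflectance, nrow = d[1L] * d[2L], ncol = d[3L])
  vals <- colMeans(flat[as.vector(cube$roi_mask), , drop = FALSE])
  mean_spectrum(vals, cube$wavelengths_nm, label)
}

#' Build an ROI mask by thresholding near-infrared reflectance
#'
#' Vegetation is bright in the NIR plateau while background in a dark imaging
#' chamber is not, so thresholding the band nearest `nir_nm` separates leaf
#' from background reproducibly.
#'
#' @param cube a [spectral_cube()].
#' @param threshold reflectance cut-off; pixels strictly above it are kept.
#'   Default 0.3.
#' @param nir_nm wavelength whose nearest band is thresholded. Default 800 nm.
#' @return logical matrix of the cube's spatial shape.
#' @export
nir_threshold_mask <- function(cube, threshold = 0.3, nir_nm = 800) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (!is_number(threshold))
    abort_sl("threshold must be a single finite number", "sl_parameter_error")
  band <- nearest_band(cube$wavelengths_nm, nir_nm)
  cube$reflectance[, , band] > threshold
}

# canonical sample-table columns, in serialization order
SAMPLE_TABLE_COLUMNS <- c(
  "sample_id", "cultivar", "system", "applied_N_ppm", "NO3_ppm", "K_ppm",
  "Ca_ppm", "SPAD", "pH", "brix_pct", "fresh_weight_g", "dry_weight_g")

#' Read a sample table of laboratory-measured responses
#'
#' The CSV must carry exactly the canonical columns: `sample_id`, `cultivar`,
#' `system` (`tub` or `NFT`), `applied_N_ppm`, `NO3_ppm`, `K_ppm`, `Ca_ppm`,
#' `SPAD`, `pH`, `brix_pct`, `fresh_weight_g`, `dry_weight_g`. Validation
#' enforces the designs supported here: tub treatments in {0, 50, ..., 350}
#' ppm N, NFT treatments in {50, 100, 200, 400} ppm N, non-negative
#' concentrations and pH within (0, 14). Missing laboratory values (e.g. dry
#' weight of plants grown in tap water) are `NA`.
#'
#' @param path CSV file path.
#' @return a `data.frame` with the canonical columns.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path))
    abort_sl(sprintf("sample table '%s' does not exist", path), "sl_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_table(df)
}

validate_sample_table <- function(df) {
  missing_cols <- setdiff(SAMPLE_TABLE_COLUMNS, names(df))
  if (length(missing_cols))
    abort_sl(sprintf("sample table lacks columns: %s",
                     paste(missing_cols, collapse = ", ")), "sl_format_error")
  df <- df[SAMPLE_TABLE_COLUMNS]
  if (!all(df$system %in% c("tub", "NFT")))
    abort_sl("system must be 'tub' or 'NFT'", "sl_format_error")
  tub_ok <- df$system != "tub" | df$applied_N_ppm %in% seq(0, 350, by = 50)
  nft_ok <- df$system != "NFT" | df$applied_N_ppm %in% c(50, 100, 200, 400)
  if (!all(tub_ok) || !all(nft_ok))
    abort_sl("applied_N_ppm outside the supported treatment designs",
             "sl_format_error")
  conc <- c("NO3_ppm", "K_ppm", "Ca_ppm")
  if (any(unlist(df[conc]) < 0, na.rm = TRUE))
    abort_sl("concentrations must be non-negative", "sl_format_error")
  if (any(df$pH <= 0 | df$pH >= 14, na.rm = TRUE))
    abort_sl("pH must lie in (0, 14)", "sl_format_error")
  df
}

#' Write a sample table
#'
#' @param df a sample table `data.frame` (canonical columns).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_sample_table <- function(df, path) {
  df <- validate_sample_table(df)
  utils::write.csv(format_df_for_csv(df), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

# serialize numeric columns with >= 9 significant digits
format_df_for_csv <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), NA,
                        format(df[[j]], digits = 12, trim = TRUE,
                               scientific = FALSE))
  }
  df
}
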
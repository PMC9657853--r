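# End-to-end orchestration: simulate/ingest -> preprocess -> select -> fit ->
# evaluate -> report, with every stage callable in isolation on a run
# directory so staged and monolithic executions produce identical artifacts.

#' Assemble a pipeline run configuration
#'
#' @param input_dir directory holding `spectra.csv`, `sample_table.csv` and
#'   optionally `solution_spectra.csv` for pre-existing data; `NULL` to
#'   simulate synthetic data instead.
#' @param synthetic named list of [synthetic_config()] arguments used when
#'   `input_dir` is `NULL`.
#' @param seed integer seed (forwarded to the synthetic generator).
#' @param smooth_window moving-average width (odd, default 13).
#' @param fdr_on `"nds"` (default) to differentiate the normalized spectrum,
#'   `"smoothed"` to differentiate smoothed reflectance directly.
#' @param region named list of [detect_dynamic_regions()] parameters.
#' @param selection named list: `k` (bands per selection; default = number of
#'   detected regions) and `vip_threshold` (default 1).
#' @param model named list: `h` (components; default 6 for tub, 3 for NFT)
#'   and `coef_source` (`"PLSR"` or `"YX-PCA"` for the coefficient-peak
#'   selector).
#' @param evaluation named list: `window_nm` for the leaf-solution
#'   correlation (default `c(390.57, 554.48)`).
#' @param per_cultivar fit one model per cultivar (default) or pooled.
#' @param write_cubes also render and write ENVI cubes when simulating.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return an object of class `"run_config"`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            synthetic = list(),
                            seed = 1L,
                            smooth_window = 13L,
                            fdr_on = c("nds", "smoothed"),
                            region = list(),
                            selection = list(),
                            model = list(),
                            evaluation = list(),
                            per_cultivar = TRUE,
                            write_cubes = FALSE,
                            log_level = "info") {
  fdr_on <- match.arg(fdr_on)
  region <- utils::modifyList(
    list(threshold_factor = 1.0, min_width_bands = 5L, merge_gap_bands = 3L,
         search_max_nm = 850), region)
  selection <- utils::modifyList(list(k = NULL, vip_threshold = 1.0), selection)
  model <- utils::modifyList(list(h = NULL, coef_source = "PLSR"), model)
  evaluation <- utils::modifyList(list(window_nm = c(390.57, 554.48)),
                                  evaluation)
  if (!is.null(selection$k) && !is_count(selection$k))
    abort_sl("selection k must be a positive integer", "sl_parameter_error")
  if (!model$coef_source %in% c("PLSR", "YX-PCA"))
    abort_sl("model coef_source must be 'PLSR' or 'YX-PCA'",
             "sl_parameter_error")
  structure(list(
    input_dir = input_dir, synthetic = synthetic, seed = as.integer(seed),
    smooth_window = smooth_window, fdr_on = fdr_on, region = region,
    selection = selection, model = model, evaluation = evaluation,
    per_cultivar = isTRUE(per_cultivar), write_cubes = isTRUE(write_cubes),
    log_level = log_level), class = "run_config")
}

sl_log <- function(cfg, level, fmt, ...) {
  levels <- c(quiet = 0L, info = 1L, debug = 2L)
  want <- levels[[match.arg(cfg$log_level, names(levels))]]
  if (levels[[level]] <= want && want > 0L)
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}

# ---- run-directory serialization helpers -----------------------------------

write_matrix_csv <- function(m, path, id_col = "sample_id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.csv(format_df_for_csv(df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

read_matrix_csv <- function(path, id_col = "sample_id") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

spectra_wavelengths <- function(m) as.numeric(colnames(m))

#' Simulate a study into a run directory
#'
#' Writes `spectra.csv`, `sample_table.csv`, `solution_spectra.csv`,
#' `ground_truth.json` and, optionally, per-sample ENVI cubes under `cubes/`.
#'
#' @param config a [pipeline_config()].
#' @param dir run directory (created if needed).
#' @return invisibly, the generated `"hsi_study"`.
#' @export
stage_simulate <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  syn_args <- utils::modifyList(config$synthetic, list(seed = config$seed))
  cfg <- do.call(synthetic_config, syn_args)
  study <- generate_study(cfg)
  write_matrix_csv(study$spectra, file.path(dir, "spectra.csv"))
  write_sample_table(study$samples, file.path(dir, "sample_table.csv"))
  write_matrix_csv(study$solution_spectra, file.path(dir, "solution_spectra.csv"),
                   id_col = "treatment")
  gt <- study$ground_truth
  jsonlite::write_json(list(
    informative_idx0 = gt$informative_index - 1L,
    informative_nm = gt$informative_nm,
    beta = gt$beta, intercept = gt$intercept,
    system = cfg$system, seed = cfg$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  if (config$write_cubes) {
    cube_dir <- file.path(dir, "cubes")
    dir.create(cube_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(study$spectra))) {
      sp <- mean_spectrum(study$spectra[i, ], study$wavelengths_nm,
                          rownames(study$spectra)[i])
      set.seed(sample_seed(cfg$seed + 900001L, i, 1L, 1L))
      cube <- generate_cube(sp, cfg$cube_shape, cfg$pixel_noise_sd)
      write_envi_cube(cube, file.path(
        cube_dir, paste0(rownames(study$spectra)[i], ".hdr")))
    }
  }
  sl_log(config, "info", "simulated %d samples (%s system) into %s",
         nrow(study$samples), cfg$system, dir)
  invisible(study)
}

#' Load a run directory's raw inputs
#'
#' @param dir run directory holding `spectra.csv` and `sample_table.csv`
#'   (written by [stage_simulate()] or supplied externally).
#' @return a list with `spectra`, `samples`, `solution_spectra` (or `NULL`),
#'   and `wavelengths_nm`.
#' @export
load_study_dir <- function(dir) {
  sp_path <- file.path(dir, "spectra.csv")
  tb_path <- file.path(dir, "sample_table.csv")
  if (!file.exists(sp_path) || !file.exists(tb_path))
    abort_sl(sprintf("run directory '%s' lacks spectra.csv / sample_table.csv",
                     dir), "sl_io_error")
  spectra <- read_matrix_csv(sp_path)
  samples <- read_sample_table(tb_path)
  sol_path <- file.path(dir, "solution_spectra.csv")
  sol <- if (file.exists(sol_path)) read_matrix_csv(sol_path, "treatment")
  list(spectra = spectra, samples = samples, solution_spectra = sol,
       wavelengths_nm = spectra_wavelengths(spectra))
}

#' Preprocess a run directory
#'
#' Smooths every leaf spectrum, computes the grand-mean NDS and its FDR, and
#' detects dynamic waveband regions. Writes `smoothed.csv`, `fdr.csv` and
#' `regions.csv`.
#'
#' @param config a [pipeline_config()].
#' @param dir run directory.
#' @return invisibly, the detected `"waveband_regions"`.
#' @export
stage_preprocess <- function(config, dir) {
  data <- load_study_dir(dir)
  wl <- data$wavelengths_nm
  smoothed <- t(apply(data$spectra, 1L, function(v)
    smooth_moving_average(mean_spectrum(v, wl), config$smooth_window)$values))
  dimnames(smoothed) <- dimnames(data$spectra)
  write_matrix_csv(smoothed, file.path(dir, "smoothed.csv"))

  grand <- mean_spectrum(colMeans(smoothed), wl, "grand_mean")
  fdr_input <- if (config$fdr_on == "nds") compute_nds(grand) else grand
  fdr <- compute_fdr(fdr_input)
  fdr_m <- matrix(fdr$values, 1L, dimnames = list("grand_mean", colnames(smoothed)))
  write_matrix_csv(fdr_m, file.path(dir, "fdr.csv"))

  regions <- do.call(detect_dynamic_regions, c(list(fdr), config$region))
  write_regions_csv(regions, file.path(dir, "regions.csv"))
  sl_log(config, "info", "detected %d dynamic regions", nrow(regions))
  invisible(regions)
}

model_groups <- function(samples, per_cultivar) {
  if (per_cultivar) split(seq_len(nrow(samples)), samples$cultivar)
  else list(all = seq_len(nrow(samples)))
}

default_h <- function(config, samples) {
  config$model$h %||% if (all(samples$system == "NFT")) 3L else 6L
}

#' Select wavebands in a run directory
#'
#' Produces, per model group (cultivar by default) and response, the three
#' selections: `FDR` (region representatives, shared across groups), `COEF`
#' (peaks of the full-spectrum regression-coefficient curve) and `VIP`
#' (above-1 local maxima of the VIP curve). Writes `selections.csv`.
#'
#' The full-spectrum models behind `COEF` and `VIP` are fitted on the raw
#' (unsmoothed) spectra: the moving-average filter blurs narrow neighbouring
#' features together and displaces coefficient peaks, which matters for band
#' selection but not for the subsequent model fits on the selected bands.
#'
#' @param config a [pipeline_config()].
#' @param dir run directory (after [stage_preprocess()]).
#' @return invisibly, a `data.frame` of all selection rows.
#' @export
stage_select <- function(config, dir) {
  data <- load_study_dir(dir)
  raw <- data$spectra
  regions <- read_regions_csv(file.path(dir, "regions.csv"))
  wl <- data$wavelengths_nm
  k <- config$selection$k %||% max(nrow(regions), 1L)
  h <- default_h(config, data$samples)
  fdr_sel <- select_by_fdr(regions, wl)

  groups <- model_groups(data$samples, config$per_cultivar)
  out <- list()
  for (g in names(groups)) {
    rows_g <- groups[[g]]
    for (resp in RESPONSE_NAMES) {
      y <- data$samples[[resp]][rows_g]
      ok <- !is.na(y)
      if (sum(!ok) > 0L)
        sl_log(config, "debug", "%s/%s: dropped %d rows with missing response",
               g, resp, sum(!ok))
      X <- raw[rows_g[ok], , drop = FALSE]
      yv <- y[ok]
      h_full <- min(h, nrow(X) - 1L, ncol(X))
      fit <- fit_plsr(X, yv, h_full, band_nm = wl)
      coeffs <- if (config$model$coef_source == "PLSR") {
        extract_regression(fit)
      } else {
        extract_regression(fit_joint_pca(X, yv, h_full, band_nm = wl))
      }
      sels <- list(fdr_sel,
                   select_by_coefficients(coeffs, k),
                   select_by_vip(compute_vip(fit),
                                 config$selection$vip_threshold, k))
      for (s in sels) {
        if (nrow(s) == 0L) {
          sl_log(config, "info", "%s/%s: a selection came back empty", g, resp)
          next
        }
        s$group <- g
        s$response <- resp
        out[[length(out) + 1L]] <- s
      }
    }
  }
  write_selection_csv(out, file.path(dir, "selections.csv"))
  invisible(do.call(rbind, lapply(out, as.data.frame)))
}

#' Fit per-selection regression models in a run directory
#'
#' For every (group, response, method) selection, fits PLS1 on the ROI-mean
#' reflectance at the selected bands and reduces it to regression
#' coefficients. Writes all models to `models.json`. (The moving-average
#' filter is applied in the derivative/region and correlation paths only; the
#' models see the unfiltered per-sample mean spectra.)
#'
#' @param config a [pipeline_config()].
#' @param dir run directory (after [stage_select()]).
#' @return invisibly, the list of model entries.
#' @export
stage_fit <- function(config, dir) {
  data <- load_study_dir(dir)
  raw <- data$spectra
  wl <- data$wavelengths_nm
  sel <- utils::read.csv(file.path(dir, "selections.csv"),
                         stringsAsFactors = FALSE)
  h <- default_h(config, data$samples)
  groups <- model_groups(data$samples, config$per_cultivar)
  entries <- list()
  for (key in split(sel, interaction(sel$group, sel$response, sel$method,
                                     drop = TRUE))) {
    g <- key$group[1L]; resp <- key$response[1L]; meth <- key$method[1L]
    rows_g <- groups[[g]]
    y <- data$samples[[resp]][rows_g]
    ok <- !is.na(y)
    bands <- sort(key$band_idx0) + 1L
    X <- raw[rows_g[ok], bands, drop = FALSE]
    h_fit <- min(h, ncol(X), sum(ok) - 1L)
    fit <- fit_plsr(X, y[ok], h_fit, band_nm = wl[bands])
    coeffs <- extract_regression(fit)
    entries[[length(entries) + 1L]] <- list(
      group = g, response = resp, method = meth, h = h_fit, n = sum(ok),
      band_idx0 = bands - 1L, band_nm = wl[bands],
      beta = coeffs$beta, intercept = coeffs$intercept,
      source = coeffs$source)
  }
  ord <- order(vapply(entries, function(e)
    paste(e$group, e$response, e$method), ""))
  entries <- entries[ord]
  jsonlite::write_json(entries, file.path(dir, "models.json"),
                       auto_unbox = TRUE, digits = NA)
  sl_log(config, "info", "fitted %d models", length(entries))
  invisible(entries)
}

#' Evaluate fitted models and leaf-solution correlations
#'
#' Recomputes in-sample predictions for every fitted model, assembles the
#' R-squared/RMSE comparison report, and computes the band-windowed Pearson
#' correlation between per-cell mean leaf spectra and the matching solution
#' spectra. Writes `report.csv` and (when solution spectra exist)
#' `correlation.csv`.
#'
#' @param config a [pipeline_config()].
#' @param dir run directory (after [stage_fit()]).
#' @return invisibly, the `"evaluation_report"`.
#' @export
stage_evaluate <- function(config, dir) {
  data <- load_study_dir(dir)
  raw <- data$spectra
  smoothed <- read_matrix_csv(file.path(dir, "smoothed.csv"))
  wl <- data$wavelengths_nm
  entries <- jsonlite::read_json(file.path(dir, "models.json"),
                                 simplifyVector = TRUE, simplifyDataFrame = FALSE)
  groups <- model_groups(data$samples, config$per_cultivar)
  rows <- lapply(entries, function(e) {
    rows_g <- groups[[e$group]]
    y <- data$samples[[e$response]][rows_g]
    ok <- !is.na(y)
    X <- raw[rows_g[ok], unlist(e$band_idx0) + 1L, drop = FALSE]
    coeffs <- regression_coefficients(unlist(e$beta), e$intercept,
                                      unlist(e$band_nm), e$source)
    pred <- predict(coeffs, X, band_nm = unlist(e$band_nm))
    list(cultivar = e$group,
         system = data$samples$system[rows_g][1L],
         response = e$response, method = e$method,
         R2 = r_squared(y[ok], pred), RMSE = rmse(y[ok], pred),
         n = e$n, h = e$h)
  })
  report <- build_report(rows)
  write_report_csv(report, file.path(dir, "report.csv"))

  if (!is.null(data$solution_spectra)) {
    treats <- as.numeric(sub("_ppm$", "", rownames(data$solution_spectra)))
    cultivars <- sort(unique(data$samples$cultivar))
    corr <- matrix(NA_real_, length(treats), length(cultivars),
                   dimnames = list(rownames(data$solution_spectra), cultivars))
    for (ti in seq_along(treats)) {
      sol <- smooth_moving_average(
        mean_spectrum(data$solution_spectra[ti, ], wl), config$smooth_window)
      for (cu in seq_along(cultivars)) {
        cell <- data$samples$cultivar == cultivars[cu] &
          data$samples$applied_N_ppm == treats[ti]
        if (!any(cell)) next
        leaf <- mean_spectrum(colMeans(smoothed[cell, , drop = FALSE]), wl)
        corr[ti, cu] <- cross_correlation(
          sol, leaf, config$evaluation$window_nm)$r_corr
      }
    }
    write_matrix_csv(corr, file.path(dir, "correlation.csv"),
                     id_col = "treatment")
  } else {
    sl_log(config, "info", "no solution spectra; correlation stage skipped")
  }
  invisible(report)
}

#' Summarise a completed run and write its manifest
#'
#' @param config a [pipeline_config()].
#' @param dir run directory (after [stage_evaluate()]).
#' @return the `"evaluation_report"` read back from disk.
#' @export
stage_report <- function(config, dir) {
  report <- read_report_csv(file.path(dir, "report.csv"))
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package = "spectroleaf",
    version = as.character(utils::packageVersion("spectroleaf")),
    seed = config$seed,
    config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
    config_md5 = unname(tools::md5sum(tmp)))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  sl_log(config, "info", "run complete: %d report rows", nrow(report))
  report
}

#' Run the full pipeline
#'
#' Executes simulate (or ingest), preprocess, select, fit, evaluate and
#' report in sequence on one run directory. Stage failures abort with a
#' stage-tagged diagnostic and leave a `FAILED` marker file (partial outputs
#' are retained).
#'
#' @param config a [pipeline_config()] (or a YAML file path understood by
#'   [read_run_config()]).
#' @param dir output run directory.
#' @return the final `"evaluation_report"`.
#' @export
run_pipeline <- function(config, dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list(
    simulate = function() {
      if (is.null(config$input_dir)) stage_simulate(config, dir)
      else {
        for (f in c("spectra.csv", "sample_table.csv", "solution_spectra.csv",
                    "ground_truth.json")) {
          src <- file.path(config$input_dir, f)
          if (file.exists(src)) file.copy(src, file.path(dir, f),
                                          overwrite = TRUE)
        }
        load_study_dir(dir)
      }
    },
    preprocess = function() stage_preprocess(config, dir),
    select = function() stage_select(config, dir),
    fit = function() stage_fit(config, dir),
    evaluate = function() stage_evaluate(config, dir),
    report = function() stage_report(config, dir))
  out <- NULL
  for (nm in names(stages)) {
    out <- tryCatch(stages[[nm]](), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", nm, conditionMessage(e)),
                 file.path(dir, "FAILED"))
      abort_sl(sprintf("[stage %s] %s", nm, conditionMessage(e)),
               class(e)[1L])
    })
  }
  out
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return a `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    abort_sl(sprintf("config file '%s' does not exist", path), "sl_io_error")
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    abort_sl(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
             "sl_format_error")
  do.call(pipeline_config, raw)
}
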
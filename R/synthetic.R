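# Synthetic lettuce-like hyperspectral data with known ground truth.
#
# The generator states a simple structural world:
#
#   * A per-sample latent factor vector w (one factor per spectral feature).
#     Factor 1 is the nitrogen-status factor, driven deterministically by the
#     applied treatment; the remaining factors are independent physiological
#     noise, plus fixed cultivar offsets.
#   * The nutrient panel is affine in the factors: z = mu0 + s * (V w), with
#     V the response-by-factor loading matrix. Treatment trends therefore
#     propagate consistently into every response (NO3 and SPAD rise with N,
#     K and Ca stay roughly level, and so on).
#   * The leaf spectrum is a fixed chlorophyll-like baseline (blue shoulder,
#     green peak via a rise-fall transition pair, red edge, NIR plateau
#     steps) plus one Gaussian sensitivity bump per
#     feature whose amplitude is linear in the standardized nutrients:
#     a = effect_matrix %*% z_std, with z_std = V w by construction.
#   * Multiplicative-style measurement noise: sd = noise_sd * local signal.
#
# Because spectra and nutrients are both affine in w, every response has an
# exact linear representation on the reflectance at the feature-center bands;
# the generator returns that true coefficient vector per response as ground
# truth for parameter-recovery tests.

RESPONSE_NAMES <- c("applied_N_ppm", "NO3_ppm", "K_ppm", "Ca_ppm", "SPAD",
                    "pH", "brix_pct", "fresh_weight_g", "dry_weight_g")

CULTIVARS <- c("Black Seeded Simpson", "Parris Island", "Rex RZ", "Tacitus")

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# response-by-factor loadings (standardized units); factors:
# 1 nitrogen status, 2 mineral uptake, 3 structural/calcium, 4 growth/water,
# 5 soluble sugar, 6 acidity
default_factor_loadings <- function() {
  V <- rbind(
    applied_N_ppm  = c(1.00, 0.00, 0.00, 0.00, 0.00, 0.00),
    NO3_ppm        = c(0.90, 0.35, 0.35, 0.30, 0.30, 0.30),
    K_ppm          = c(0.00, 0.80, 0.00, 0.25, 0.00, 0.00),
    Ca_ppm         = c(0.00, 0.35, 0.90, 0.00, 0.00, 0.00),
    SPAD           = c(0.85, 0.00, 0.00, 0.40, 0.00, 0.00),
    pH             = c(-0.25, 0.00, 0.30, 0.00, 0.00, 0.90),
    brix_pct       = c(-0.30, 0.00, 0.00, -0.25, 0.85, 0.00),
    fresh_weight_g = c(0.50, 0.00, 0.00, 0.75, 0.00, 0.00),
    dry_weight_g   = c(0.35, 0.00, 0.00, 0.50, 0.20, 0.00))
  colnames(V) <- c("nitrogen", "mineral", "structural", "growth", "sugar",
                   "acidity")
  V
}

# feature -> driving factor assignment (by name), mirroring the physiology
# each waveband is sensitive to
default_feature_factor <- c("structural", "mineral", "sugar", "nitrogen",
                            "growth", "acidity")

default_nutrient_means <- function(system, treatments) {
  base <- list(
    tub = c(NA, 4800, 4700, 260, 33, 6.0, 8.0, 85, 4.0),
    nft = c(NA, 5500, 4600, 230, 35, 5.9, 8.0, 128, 8.5))[[system]]
  base[1L] <- mean(treatments)
  stats::setNames(base, RESPONSE_NAMES)
}

default_nutrient_scales <- function(system, treatments) {
  base <- list(
    tub = c(NA, 1500, 700, 60, 8, 0.25, 2.2, 28, 1.2),
    nft = c(NA, 1600, 900, 45, 8, 0.20, 3.0, 40, 2.5))[[system]]
  base[1L] <- pop_sd(treatments)
  stats::setNames(base, RESPONSE_NAMES)
}

#' Configuration of the synthetic study generator
#'
#' Bundles every stated parameter of the synthetic world: instrument grid,
#' experimental design (cultivars x treatments x replicates for tub or NFT
#' systems), spectral feature geometry, the nutrient-to-amplitude effect
#' matrix, noise level and RNG seed. Defaults emulate a 462-band VNIR grid
#' over 390.57-1008.6 nm, the tub design (8 N treatments of 0-350 ppm, 4
#' cultivars, 4 replicates) or the NFT design (50/100/200/400 ppm), and six
#' (tub) or four (NFT) dynamic spectral features.
#'
#' @param system `"tub"` or `"nft"`.
#' @param n_bands number of bands (default 462).
#' @param wl_start_nm,wl_end_nm grid end points (defaults 390.57, 1008.6).
#' @param cultivars cultivar labels (default the four study cultivars).
#' @param treatments_ppm applied-N levels; defaults by system.
#' @param replicates plants per cultivar x treatment cell (default 4).
#' @param noise_sd relative spectral noise (sd = noise_sd x local signal).
#'   Default 0.01.
#' @param feature_centers_nm transition centres; default
#'   410, 523, 568, 714, 812, 829 nm (tub) or the first four (NFT).
#' @param feature_width_nm per-feature width (logistic scale of the baseline
#'   transition and sd of the Gaussian sensitivity bump), nm.
#' @param feature_baseline_amp per-feature baseline transition amplitude
#'   (reflectance units; negative = downward step).
#' @param feature_gain per-feature sensitivity gain (reflectance per unit
#'   latent factor).
#' @param effect_matrix optional `n_features x 9` map from standardized
#'   nutrients to feature amplitudes; the default realises unit-gain coupling
#'   of each feature to its assigned latent factor.
#' @param factor_loadings `9 x n_features` response-by-factor matrix `V`.
#' @param factor_sd per-factor noise SD (factor 1, treatment-driven, has no
#'   noise).
#' @param cultivar_shift `length(cultivars) x n_features` fixed factor
#'   offsets per cultivar.
#' @param pixel_noise_sd absolute per-pixel noise used when rendering cubes.
#' @param cube_shape spatial shape `(rows, cols)` of rendered cubes.
#' @param seed integer RNG seed for the whole study.
#' @return an object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(system = c("tub", "nft"),
                             n_bands = 462L,
                             wl_start_nm = 390.57,
                             wl_end_nm = 1008.6,
                             cultivars = CULTIVARS,
                             treatments_ppm = NULL,
                             replicates = 4L,
                             noise_sd = 0.01,
                             feature_centers_nm = NULL,
                             feature_width_nm = NULL,
                             feature_baseline_amp = NULL,
                             feature_gain = NULL,
                             effect_matrix = NULL,
                             factor_loadings = NULL,
                             factor_sd = NULL,
                             cultivar_shift = NULL,
                             pixel_noise_sd = 0.01,
                             cube_shape = c(16L, 16L),
                             seed = 1L) {
  system <- match.arg(system)
  if (is.null(treatments_ppm))
    treatments_ppm <- if (system == "tub") seq(0, 350, by = 50) else
      c(50, 100, 200, 400)
  if (!is_count(n_bands, min = 8L))
    abort_sl("n_bands must be an integer >= 8", "sl_parameter_error")
  if (!is_number(wl_start_nm) || !is_number(wl_end_nm) ||
      wl_start_nm >= wl_end_nm)
    abort_sl("wl_start_nm must be < wl_end_nm", "sl_parameter_error")
  if (!is_number(noise_sd) || noise_sd < 0)
    abort_sl("noise_sd must be >= 0", "sl_parameter_error")
  if (!is_count(replicates))
    abort_sl("replicates must be a positive integer", "sl_parameter_error")

  n_tub_features <- 6L
  if (is.null(feature_centers_nm))
    feature_centers_nm <- c(410, 523, 568, 714, 812, 829)[
      seq_len(if (system == "tub") 6L else 4L)]
  n_f <- length(feature_centers_nm)
  if (any(feature_centers_nm <= wl_start_nm) ||
      any(feature_centers_nm >= wl_end_nm))
    abort_sl("feature centres must lie inside the wavelength grid",
             "sl_parameter_error")
  pick <- function(x, defaults) {
    if (!is.null(x)) {
      if (length(x) != n_f)
        abort_sl("per-feature parameter length must match feature count",
                 "sl_parameter_error")
      x
    } else if (n_f <= length(defaults)) defaults[seq_len(n_f)] else
      rep(defaults, length.out = n_f)
  }
  feature_width_nm <- pick(feature_width_nm, c(4, 5, 5, 6, 4, 4))
  feature_baseline_amp <- pick(feature_baseline_amp,
                               c(0.07, 0.09, -0.08, 0.12, 0.095, -0.095))
  feature_gain <- pick(feature_gain, c(0.02, 0.022, 0.024, 0.04, 0.03, 0.03))

  V_full <- factor_loadings %||% default_factor_loadings()
  if (!is.matrix(V_full) || nrow(V_full) != length(RESPONSE_NAMES))
    abort_sl("factor_loadings must be a 9-response by n-factor matrix",
             "sl_parameter_error")
  V <- V_full[, seq_len(min(n_f, ncol(V_full))), drop = FALSE]
  if (ncol(V) < n_f)
    abort_sl("factor_loadings has fewer factors than spectral features",
             "sl_parameter_error")

  if (is.null(effect_matrix)) {
    # couple each feature to its assigned latent factor with gain g, then
    # express that coupling as a map from standardized nutrients:
    # a = M w and z_std = V w  =>  effect = M V^+  (so effect %*% z_std = M w)
    fac_names <- colnames(default_factor_loadings())
    assign_idx <- match(default_feature_factor, fac_names)[seq_len(n_f)]
    assign_idx[is.na(assign_idx)] <- seq_len(n_f)[is.na(assign_idx)]
    assign_idx <- pmin(assign_idx, n_f)
    M <- matrix(0, n_f, n_f)
    M[cbind(seq_len(n_f), assign_idx)] <- feature_gain
    V_pinv <- solve(crossprod(V), t(V))
    effect_matrix <- M %*% V_pinv
  }
  if (!is.matrix(effect_matrix) || nrow(effect_matrix) != n_f ||
      ncol(effect_matrix) != length(RESPONSE_NAMES))
    abort_sl("effect_matrix must be n_features x 9", "sl_parameter_error")

  factor_sd <- factor_sd %||% c(0, rep(1, n_f - 1L))
  if (length(factor_sd) != n_f || any(factor_sd < 0))
    abort_sl("factor_sd must be non-negative, one per factor",
             "sl_parameter_error")

  if (is.null(cultivar_shift)) {
    shift6 <- rbind(c(0, -0.5, 0, -0.6, 0, 0),
                    c(0, 0.2, 0, 0.9, 0, 0),
                    c(0, 0.8, 0, -0.2, 0, 0),
                    c(0, -0.4, 0, 0.3, 0, 0))
    cultivar_shift <- shift6[rep_len(seq_len(4L), length(cultivars)),
                             seq_len(n_f), drop = FALSE]
  }
  if (!is.matrix(cultivar_shift) || nrow(cultivar_shift) != length(cultivars) ||
      ncol(cultivar_shift) != n_f)
    abort_sl("cultivar_shift must be n_cultivars x n_features",
             "sl_parameter_error")

  cfg <- list(
    system = system,
    wavelengths_nm = seq(wl_start_nm, wl_end_nm, length.out = n_bands),
    n_bands = as.integer(n_bands),
    cultivars = cultivars,
    treatments_ppm = as.numeric(treatments_ppm),
    replicates = as.integer(replicates),
    noise_sd = noise_sd,
    feature_centers_nm = as.numeric(feature_centers_nm),
    feature_width_nm = as.numeric(feature_width_nm),
    feature_baseline_amp = as.numeric(feature_baseline_amp),
    feature_gain = as.numeric(feature_gain),
    effect_matrix = effect_matrix,
    factor_loadings = V,
    factor_sd = as.numeric(factor_sd),
    cultivar_shift = cultivar_shift,
    base_level = 0.06,
    water_level = 0.03,
    solution_taper = c(center_nm = 580, width_nm = 15),
    nutrient_means = default_nutrient_means(system, treatments_ppm),
    nutrient_scales = default_nutrient_scales(system, treatments_ppm),
    pixel_noise_sd = pixel_noise_sd,
    cube_shape = as.integer(cube_shape),
    seed = as.integer(seed))
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %s system: %d cultivars x %d treatments x %d reps, %d bands, noise_sd %.3g\n",
    x$system, length(x$cultivars), length(x$treatments_ppm), x$replicates,
    x$n_bands, x$noise_sd))
  invisible(x)
}

logistic <- function(u) 1 / (1 + exp(-u))

# deterministic baseline reflectance over the grid
baseline_reflectance <- function(cfg, wavelengths = cfg$wavelengths_nm) {
  r <- rep(cfg$base_level, length(wavelengths))
  for (f in seq_along(cfg$feature_centers_nm)) {
    r <- r + cfg$feature_baseline_amp[f] *
      logistic((wavelengths - cfg$feature_centers_nm[f]) /
               cfg$feature_width_nm[f])
  }
  r
}

# Gaussian sensitivity basis, bands x features
sensitivity_basis <- function(cfg, wavelengths = cfg$wavelengths_nm) {
  vapply(seq_along(cfg$feature_centers_nm), function(f) {
    exp(-0.5 * ((wavelengths - cfg$feature_centers_nm[f]) /
                cfg$feature_width_nm[f])^2)
  }, numeric(length(wavelengths)))
}

standardize_nutrients <- function(nutrients, cfg) {
  if (is.null(names(nutrients)) ||
      !all(RESPONSE_NAMES %in% names(nutrients)))
    abort_sl(sprintf("nutrient vector must carry the named responses: %s",
                     paste(RESPONSE_NAMES, collapse = ", ")),
             "sl_contract_error")
  (as.numeric(nutrients[RESPONSE_NAMES]) - cfg$nutrient_means) /
    cfg$nutrient_scales
}

#' Generate one leaf mean spectrum from a nutrient vector
#'
#' Baseline reflectance plus nutrient-driven Gaussian feature bumps plus
#' relative Gaussian noise, clipped to `[0, 1.2]`. Draws from the current RNG
#' stream; callers wanting reproducibility set the seed beforehand.
#'
#' @param nutrients named numeric vector carrying all nine canonical
#'   responses (`applied_N_ppm`, `NO3_ppm`, `K_ppm`, `Ca_ppm`, `SPAD`, `pH`,
#'   `brix_pct`, `fresh_weight_g`, `dry_weight_g`).
#' @param cfg a [synthetic_config()].
#' @param label sample label carried into the spectrum.
#' @return a [mean_spectrum()].
#' @export
generate_leaf_spectrum <- function(nutrients, cfg, label = NA_character_) {
  stopifnot(inherits(cfg, "synthetic_config"))
  z_std <- standardize_nutrients(nutrients, cfg)
  a <- drop(cfg$effect_matrix %*% z_std)
  clean <- baseline_reflectance(cfg) + drop(sensitivity_basis(cfg) %*% a)
  vals <- clean
  if (cfg$noise_sd > 0)
    vals <- vals + stats::rnorm(length(clean), 0, cfg$noise_sd * abs(clean))
  mean_spectrum(pmin(pmax(vals, 0), 1.2), cfg$wavelengths_nm, label)
}

#' Generate a nutrient-solution spectrum
#'
#' A flat water-like baseline everywhere, plus the leaf baseline's blue-green
#' component scaled monotonically with the applied N concentration and
#' tapered off beyond the green range, with the same relative noise model.
#' This reproduces the empirical co-variation of solution and leaf
#' reflectance in the blue-green window.
#'
#' @param applied_N_ppm non-negative N concentration.
#' @param cfg a [synthetic_config()].
#' @param label sample label.
#' @return a [mean_spectrum()].
#' @export
generate_solution_spectrum <- function(applied_N_ppm, cfg,
                                       label = NA_character_) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is_number(applied_N_ppm) || applied_N_ppm < 0)
    abort_sl("applied_N_ppm must be a single non-negative number",
             "sl_contract_error")
  wl <- cfg$wavelengths_nm
  bluegreen <- rep(0, length(wl))
  for (f in which(cfg$feature_centers_nm <= 560 & cfg$feature_baseline_amp > 0)) {
    bluegreen <- bluegreen + cfg$feature_baseline_amp[f] *
      logistic((wl - cfg$feature_centers_nm[f]) / cfg$feature_width_nm[f])
  }
  taper <- logistic((cfg$solution_taper[["center_nm"]] - wl) /
                    cfg$solution_taper[["width_nm"]])
  g <- applied_N_ppm / max(cfg$treatments_ppm)
  clean <- cfg$water_level + g * bluegreen * taper
  vals <- clean
  if (cfg$noise_sd > 0)
    vals <- vals + stats::rnorm(length(clean), 0, cfg$noise_sd * abs(clean))
  mean_spectrum(pmin(pmax(vals, 0), 1.2), cfg$wavelengths_nm, label)
}

#' Render a spectrum into a spatial hyperspectral cube
#'
#' Leaf pixels (a centred ellipse covering about 40% of the frame) carry the
#' supplied spectrum plus independent per-pixel Gaussian noise; background
#' pixels carry a dark baseline (reflectance 0.02). The true leaf mask is
#' stored as the cube's ROI mask.
#'
#' @param spectrum a [mean_spectrum()].
#' @param spatial_shape integer `(rows, cols)`.
#' @param pixel_noise_sd absolute per-pixel noise SD. Default 0.
#' @return a [spectral_cube()].
#' @export
generate_cube <- function(spectrum, spatial_shape = c(16L, 16L),
                          pixel_noise_sd = 0) {
  stopifnot(inherits(spectrum, "mean_spectrum"))
  if (length(spatial_shape) != 2L || any(spatial_shape < 1))
    abort_sl("spatial_shape must be two positive integers",
             "sl_contract_error")
  if (!is_number(pixel_noise_sd) || pixel_noise_sd < 0)
    abort_sl("pixel_noise_sd must be >= 0", "sl_parameter_error")
  nr <- as.integer(spatial_shape[1L]); nc <- as.integer(spatial_shape[2L])
  nb <- length(spectrum$values)
  # centred ellipse with ~40% area coverage: pi * 0.357^2 * 4 ~ 0.40
  rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
  ra <- 0.357 * nr; ca <- 0.357 * nc
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask <- ((rows - rc) / ra)^2 + ((cols - cc) / ca)^2 <= 1
  refl <- array(0.02, dim = c(nr, nc, nb))
  leaf <- which(mask)
  for (b in seq_len(nb)) {
    plane <- refl[, , b]
    plane[leaf] <- spectrum$values[b]
    refl[, , b] <- plane
  }
  if (pixel_noise_sd > 0)
    refl <- refl + array(stats::rnorm(length(refl), 0, pixel_noise_sd),
                         dim = dim(refl))
  spectral_cube(pmin(pmax(refl, 0), 1.2), spectrum$wavelengths_nm, mask)
}

# deterministic per-sample seed, independent of replicate count ordering
sample_seed <- function(seed, ci, ti, rep) {
  (abs(seed) + ((ci * 131L + ti) * 127L + rep) * 7919L) %% 2147483647L
}

#' Generate a complete synthetic study
#'
#' Draws, for every cultivar x treatment x replicate cell, a latent factor
#' vector (treatment trend + cultivar offset + noise), maps it to the
#' nutrient panel and to a leaf spectrum, and generates one solution spectrum
#' per treatment. Dry weight is reported missing (`NA`) for tub plants grown
#' in tap water (0 ppm), emulating field practice, though the underlying
#' value still drives the spectrum.
#'
#' All randomness derives hierarchically from `cfg$seed`, so a study is fully
#' reproducible and adding replicates does not perturb existing samples.
#'
#' @param cfg a [synthetic_config()].
#' @return an object of class `"hsi_study"`: `samples` (the sample table),
#'   `spectra` (n_samples x n_bands matrix of leaf mean spectra),
#'   `solution_spectra` (treatments x n_bands matrix), `wavelengths_nm`,
#'   `ground_truth` (true per-response coefficients over the informative
#'   bands, their 1-based indices, and the latent factor draws), and the
#'   originating `config`.
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  wl <- cfg$wavelengths_nm
  n_f <- length(cfg$feature_centers_nm)
  treats <- cfg$treatments_ppm
  theta1 <- (treats - mean(treats)) / pop_sd(treats)
  V <- cfg$factor_loadings
  mu0 <- cfg$nutrient_means
  sc <- cfg$nutrient_scales

  n <- length(cfg$cultivars) * length(treats) * cfg$replicates
  spectra <- matrix(NA_real_, n, cfg$n_bands,
                    dimnames = list(NULL, format(wl, digits = 10)))
  W <- matrix(NA_real_, n, n_f)
  tab <- vector("list", n)
  ids <- character(n)
  k <- 0L
  for (ci in seq_along(cfg$cultivars)) {
    for (ti in seq_along(treats)) {
      for (r in seq_len(cfg$replicates)) {
        k <- k + 1L
        set.seed(sample_seed(cfg$seed, ci, ti, r))
        # rejection-sample the factor draw so the nutrient panel stays
        # physical (non-negative amounts, pH in range); both the table row
        # and the spectrum use the accepted draw, so the exact linear law
        # between them is untouched
        for (attempt in 1:100) {
          eta <- stats::rnorm(n_f, 0, cfg$factor_sd)
          w <- c(theta1[ti], rep(0, n_f - 1L)) + cfg$cultivar_shift[ci, ] + eta
          z <- mu0 + sc * drop(V %*% w)
          amounts <- z[c("NO3_ppm", "K_ppm", "Ca_ppm", "brix_pct",
                         "fresh_weight_g", "dry_weight_g")]
          if (all(amounts >= 0) && z[["pH"]] > 0 && z[["pH"]] < 14) break
        }
        z["applied_N_ppm"] <- treats[ti] # exact by construction
        ids[k] <- sprintf("%s_%s_%03d_r%d",
                          cfg$system, gsub("[^A-Za-z]", "", cfg$cultivars[ci]),
                          treats[ti], r)
        sp <- generate_leaf_spectrum(z, cfg, label = ids[k])
        spectra[k, ] <- sp$values
        W[k, ] <- w
        row <- as.list(z)
        if (cfg$system == "tub" && treats[ti] == 0)
          row$dry_weight_g <- NA_real_
        tab[[k]] <- c(list(sample_id = ids[k],
                           cultivar = cfg$cultivars[ci],
                           system = if (cfg$system == "tub") "tub" else "NFT"),
                      row)
      }
    }
  }
  rownames(spectra) <- ids
  samples <- do.call(rbind, lapply(tab, function(r)
    as.data.frame(r, check.names = FALSE)))
  names(samples) <- SAMPLE_TABLE_COLUMNS

  sol <- matrix(NA_real_, length(treats), cfg$n_bands,
                dimnames = list(sprintf("%d_ppm", treats),
                                colnames(spectra)))
  for (ti in seq_along(treats)) {
    set.seed((cfg$seed + 500009L + ti * 7919L) %% 2147483647L)
    sol[ti, ] <- generate_solution_spectrum(
      treats[ti], cfg, label = sprintf("solution_%d_ppm", treats[ti]))$values
  }

  structure(list(
    samples = samples,
    spectra = spectra,
    solution_spectra = sol,
    wavelengths_nm = wl,
    ground_truth = study_ground_truth(cfg),
    factors = W,
    config = cfg), class = "hsi_study")
}

#' Expected nutrient panel per treatment
#'
#' The generator's closed-form mean structure: for each treatment, the
#' expected nutrient vector averaged over cultivars and factor noise,
#' `E[z | t] = mu0 + s * V (theta(t) + mean cultivar shift)`. Useful for
#' checking the encoded treatment trends (e.g. leaf NO3 rising with applied
#' N) without sampling noise.
#'
#' @param cfg a [synthetic_config()].
#' @return a `data.frame` with `treatment_ppm` and one column per response.
#' @export
expected_nutrient_means <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  treats <- cfg$treatments_ppm
  theta1 <- (treats - mean(treats)) / pop_sd(treats)
  shift <- colMeans(cfg$cultivar_shift)
  n_f <- length(cfg$feature_centers_nm)
  out <- t(vapply(seq_along(treats), function(ti) {
    w <- c(theta1[ti], rep(0, n_f - 1L)) + shift
    cfg$nutrient_means + cfg$nutrient_scales * drop(cfg$factor_loadings %*% w)
  }, numeric(length(RESPONSE_NAMES))))
  colnames(out) <- RESPONSE_NAMES
  data.frame(treatment_ppm = treats, out, check.names = FALSE)
}

# closed-form true regression coefficients at the informative bands
study_ground_truth <- function(cfg) {
  wl <- cfg$wavelengths_nm
  n_f <- length(cfg$feature_centers_nm)
  idx <- vapply(cfg$feature_centers_nm, function(t) nearest_band(wl, t), 1L)
  S <- sensitivity_basis(cfg, wl[idx])          # n_f x n_f
  K <- S %*% (cfg$effect_matrix %*% cfg$factor_loadings)
  base_sel <- baseline_reflectance(cfg, wl[idx])
  Kinv <- tryCatch(solve(K), error = function(e) NULL)
  if (is.null(Kinv)) {
    warning("effect/loading configuration is rank-deficient; ",
            "true coefficients unavailable", call. = FALSE)
    return(list(informative_index = idx, informative_nm = wl[idx],
                beta = NULL, intercept = NULL))
  }
  B <- (cfg$nutrient_scales * cfg$factor_loadings) %*% Kinv  # 9 x n_f
  intercept <- cfg$nutrient_means - drop(B %*% base_sel)
  rownames(B) <- RESPONSE_NAMES
  list(informative_index = idx, informative_nm = wl[idx],
       beta = B, intercept = stats::setNames(intercept, RESPONSE_NAMES))
}

#' @export
print.hsi_study <- function(x, ...) {
  cat(sprintf(
    "<hsi_study> %s: %d samples (%d cultivars x %d treatments x %d reps), %d bands\n",
    x$config$system, nrow(x$samples), length(x$config$cultivars),
    length(x$config$treatments_ppm), x$config$replicates, ncol(x$spectra)))
  invisible(x)
}
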
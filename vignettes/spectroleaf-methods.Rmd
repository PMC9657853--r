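---
title: "spectroleaf: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spectroleaf: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectroleaf)
```

## Scope

`spectroleaf` estimates the nutrient status of hydroponically grown lettuce
(leaf NO₃⁻, K⁺, Ca²⁺, SPAD, pH, Brix, fresh and dry weight, and the applied
nitrogen concentration) from visible/near-infrared hyperspectral reflectance
of freshly cut leaves. The workflow is: extract a region-of-interest (ROI)
mean spectrum per sample, detect informative waveband regions from the
derivative of the spectrum, select a small set of wavebands by one of three
strategies, fit a latent-variable linear regression per response on the
selected bands, and report R², RMSE and leaf-versus-solution band-windowed
correlations.

## Preprocessing

**Smoothing.** Each ROI-mean spectrum is filtered with a 13-point centred
moving average (the conventional width for this instrument family; ~17 nm at
the 1.34 nm band spacing of a 462-band grid over 390.57–1008.6 nm). At the
spectrum edges the window truncates symmetrically rather than padding:
no data is invented at the blue or NIR extremes, constants pass through
unchanged, and the output never leaves the input's range.

**NDS.** The normalized difference spectrum is per-spectrum min–max
normalization, `(v − min v)/(max v − min v)`. The originating formulation is
not printed in the source literature; min–max normalization is used as a
documented stand-in because it is affine-invariant (instrument gain and
offset cancel), bounded in [0, 1], and preserves the shape and extrema of the
reflectance curve, which matches how published NDS curves track reflectance.

**FDR.** The first-order derivative of reflectance is computed by central
finite differences *on the wavelength grid* (one-sided at the two ends),
giving units of 1/nm so that thresholds transfer across instruments with
non-uniform band spacing. By default the derivative is taken on the NDS of
the smoothed grand-mean spectrum; a flag (`fdr_on = "smoothed"`) switches to
smoothed reflectance directly, since the source protocol is ambiguous on
this point.

**Dynamic regions.** The source protocol identified derivative-active
regions "clearly" by eye; the package needs an explicit rule, so all four
knobs are exposed:

| parameter | default | meaning |
|---|---|---|
| `threshold_factor` | 1.0 | τ = mean(\|FDR\|) + factor × SD(\|FDR\|) |
| `min_width_bands` | 5 | runs narrower than this are dropped |
| `merge_gap_bands` | 3 | runs separated by ≤ this many bands merge |
| `search_max_nm` | 850 | bands above this are excluded from the statistics and the search (the far-NIR tail is flat and would dilute τ) |

Each region's representative waveband is its \|FDR\| peak. Region counts are
data-driven, not hard-coded: on the default synthetic worlds the detector
returns six regions for the tub design and four for the NFT design, matching
the counts reported for the real systems.

## Models

**PLS1 (NIPALS).** For a univariate response the NIPALS update is
closed-form, one pass per component: weight `wᵢ = Xᵀy/‖Xᵀy‖`, score
`tᵢ = Xwᵢ`, X-loading `pᵢ = Xᵀtᵢ/tᵢᵀtᵢ`, inner coefficient
`bᵢ = yᵀtᵢ/tᵢᵀtᵢ`, then deflation of X and y. (A convergence tolerance
would only matter for multivariate responses; none is needed here, which is
why the package exposes no such knob.) X and y are mean-centred but not
scaled: the predictor columns are all reflectances and share units.
Components are nested, so component-count selection
(`select_components()`) fits once at `h_max` and reads off the cumulative
response-variance curve; the chosen `h` is the smallest reaching the
threshold (default 95%). Defaults of `h = 6` (tub) and `h = 3` (NFT) follow
the variance profiles reported for the real systems.

**Joint PCA.** The alternative route stacks `Z = [y X]`, autoscales each
column (y and X have incommensurate units, unlike the X-only case), and
takes the top-h principal directions by SVD. The reduction to regression
coefficients is a documented interpretation, since the source only cites the
construction: write the loadings `P_z = [a; B]` with `a` the response row;
requiring the reconstruction of the response column to be self-consistent
for a new sample, `ŷ_s = (ŷ_s a + x_s B) a`, gives
`β_s = B a / (1 − aᵀa)`, mapped back to raw units. When the retained
components reproduce the response column exactly (`aᵀa → 1`) the reduction
is singular and the package raises a diagnostic asking for a smaller `h`.

**Coefficients and prediction.** PLS coefficients are the standard
`β = W(PᵀW)⁻¹b` with intercept `C = ȳ − x̄ᵀβ`; prediction is
`ŷ = Xβ + C`, with band lists checked when both sides carry wavelengths.
At full rank (`h = min(n−1, p)`) PLS1 reproduces ordinary least squares,
which the tests verify against a normal-equations oracle.

## Waveband selection

Three selectors reduce curves over 462 bands to a discrete set:

1. **FDR**: one band per detected region — the grid band nearest the
   region's derivative peak.
2. **COEF**: local maxima of the full-spectrum |β| curve, top `k` by
   magnitude, ties toward the lower wavelength. `k` defaults to the number
   of detected regions (six tub / four NFT).
3. **VIP**: `VIP_j = sqrt(p Σᵢ SSᵢ (w_{ji}/‖wᵢ‖)² / Σᵢ SSᵢ)` with
   `SSᵢ = bᵢ²tᵢᵀtᵢ`. The mean squared score is exactly 1 by construction,
   so bands scoring strictly above 1 are candidates; candidates are reduced
   to local maxima of the VIP curve and capped at `k`. The printed form of
   the VIP formula in the source is typographically garbled; the standard
   Wold PLS-VIP — its evident intent — is implemented, and VIP is computed
   from the PLS decomposition only (it is undefined for plain PCA, which
   lacks an inner regression).

The local-maxima-then-top-k rule and its tie-breaking are package inventions
(the source only says important bands "were located"); they are deterministic
and fully specified so selections are reproducible.

**Where selection happens in the pipeline.** The full-spectrum models behind
COEF and VIP, and the per-selection model fits, use the *unsmoothed* ROI-mean
spectra. The 13-point filter spans ~17 nm — wider than the separation of the
two neighbouring NIR features at 812 and 829 nm — so smoothing before
selection blends adjacent narrow features into mixed bands, displaces
coefficient peaks, and can deprive a sparse VIP selection of a needed degree
of freedom. Smoothing is therefore confined to the derivative/region path
(where it suppresses band-to-band noise before differentiation) and to the
correlation analysis. This is a deliberate deviation from a
"filter-everything-first" reading of the protocol and is the package's main
documented pipeline design choice.

## Evaluation

`RMSE = sqrt(Σ(y_k − ŷ_k)²/n)`; `R² = 1 − SS_res/SS_tot` (negative for fits
worse than the mean — R² is deliberately not clamped). The leaf–solution
"cross-correlation" is the zero-lag Pearson product-moment coefficient
restricted to bands inside a wavelength window, by default
390.57–554.48 nm (inclusive endpoints, selection by wavelength so
non-uniform grids behave): the printed formula in the source has unbalanced
parentheses, and the surrounding text identifies it as the statistical
correlation coefficient. No lag search is performed. Correlations are
computed on smoothed spectra (same rationale as the derivative path: the
statistic compares curve shapes).

Reports carry one row per cultivar × system × response × method with a
`best` flag per cell (highest R², RMSE tie-break). Models are evaluated
in-sample, mirroring how the reference tables report fitted-model accuracy;
no train/test split is claimed.

## The synthetic world

No real cubes are distributed, so the generator states an explicit world:

* **Design.** Tub: 4 cultivars × 8 applied-N treatments (0–350 ppm in 50 ppm
  steps) × 4 replicates = 128 samples. NFT: 4 × {50, 100, 200, 400} ppm × 4
  = 64. Grid: 462 bands, 390.57–1008.6 nm (uniform; the real instrument's
  grid is non-uniform and unpublished).
* **Latent factors.** One factor per spectral feature: nitrogen status
  (treatment-driven, no sample noise), mineral uptake, structural/calcium,
  growth/water, soluble sugar, acidity. A sample's factor vector is
  treatment trend + fixed cultivar offset + unit-SD Gaussian noise,
  rejection-sampled until the implied nutrient panel is physical
  (non-negative amounts, pH in range).
* **Nutrients.** Affine in the factors, `z = μ₀ + s·Vw`, with means and
  scales eyeballed once from published tub/NFT nutrient tables (e.g. tub NO₃⁻
  ≈ 4800 ± 1500 ppm, SPAD ≈ 33 ± 8). The loading matrix `V` encodes the
  qualitative trends: NO₃⁻ and SPAD rise with applied N, K⁺ and Ca²⁺ stay
  level, Brix dips, biomass rises. The applied-N column *is* the treatment.
  Dry weight is reported `NA` for 0-ppm tub samples, as in real tables.
* **Spectra.** A fixed chlorophyll-like baseline — blue shoulder at 410 nm,
  green peak built from a 523 nm rise and 568 nm fall, red edge at 714 nm,
  NIR steps at 812/829 nm — plus one Gaussian sensitivity bump per feature
  whose amplitude is linear in the standardized nutrients
  (`a = E z_std`, with the default `E` coupling each feature to its assigned
  factor), plus relative Gaussian noise (SD = `noise_sd` × local signal,
  default 1%), clipped to [0, 1.2].
* **Ground truth.** Because spectra and nutrients are both affine in the
  factors, each response has an exact linear representation on the
  reflectance at the feature-centre bands; `generate_study()` returns that
  β and intercept per response in closed form (with respect to unsmoothed
  reflectance). This is what parameter-recovery tests compare against.
* **Solutions.** The nutrient solution spectrum shares the leaf baseline's
  blue–green component, scaled monotonically with applied N over a flat
  water baseline, so leaf and solution co-vary inside the blue–green window
  exactly as observed; at 0 ppm the solution is flat water and the
  correlation is uninformative (the real tables' high 0-ppm correlation is
  an acknowledged anomaly that the world does not emulate).

**Calibration, stated once.** The baseline transition amplitudes
(0.07–0.12) are near-equal so that every planted transition clears the
mean + 1·SD derivative threshold after 13-point smoothing; a realistic
dominant red edge (NIR plateau ≈ 0.5) would swamp the adaptive threshold and
collapse detection to two regions. The default world therefore has a NIR
plateau ≈ 0.3. Likewise the NIR pair uses 4 nm transition widths so their
smoothed derivative peaks stay within ±1 band of the planted centres, and
the weak entries of `V` are large enough that every factor a response loads
on is detectable by VIP at the per-cultivar sample size (n = 32). These
choices were fixed against the stated fixtures and are not tuned per run.

**What a green test does not establish.** The world is linear by
construction with six degrees of freedom; real leaf spectra have continuous
pigment/water absorption features, scattering nonlinearity, illumination
geometry effects, and no exact low-rank structure. Recovery and R² results
on synthetic studies validate the *machinery* (formulas, selectors,
bookkeeping, determinism), not field performance, and the published accuracy
tables from real cubes are explicitly not reproduction targets.

## Numerical and interface choices

* ENVI dialect: ASCII header + raw binary, data type 4 (float32), BIL/BIP,
  wavelengths in nm; anything else is rejected loudly. Round-trips are
  bit-exact at float32 precision.
* Band indices are 1-based inside R; every serialized artifact
  (regions/selections CSV, ground-truth JSON) writes 0-based indices with
  `idx0` naming, matching instrument-side conventions.
* Floats in CSV/JSON artifacts are written with ≥ 9 significant digits;
  reports are byte-reproducible for a fixed config + seed, and the run
  manifest records the package version, seed and config hash.
* Degenerate inputs (flat spectrum, zero-variance response, empty ROI,
  all-constant predictors) raise classed conditions
  (`sl_degenerate`, `sl_precondition`, ...) rather than returning NaN.
* Empty selections are flagged results, not errors; a missing
  (group, response, method) combination is a logged gap in the report.
* Randomness is hierarchical: a single study seed derives per-sample seeds,
  so adding replicates never perturbs existing samples.

## Known limitations

* In-sample evaluation only (leave-one-out is easy to add; the reference
  workflow reports fitted accuracy).
* PLS1 per response; no multi-response PLS2, kernel PLS, or regularization.
* No radiative-transfer realism in the generator (no PROSPECT-style leaf
  optics, BRDF, or illumination effects).
* The region detector's four knobs are heuristic stand-ins for expert
  judgement; on real data they may need retuning, which is why they are all
  config-exposed.
* Savitzky–Golay filtering, second derivatives and continuum removal are out
  of scope.
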
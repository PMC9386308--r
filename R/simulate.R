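#' Constituent absorption-band model
#'
#' Each constituent contributes one or more Gaussian absorption bands to the
#' apparent-absorbance spectrum, scaled linearly by its concentration
#' (Beer-Lambert-style mixing). The default places the six major brown-rice
#' flour bands at 1196, 1466, 1634, 1904, 2288 and 2322 nm with their
#' functional-group attributions: 1196 and 2322 nm C-H (oil), 1466 and
#' 2288 nm N-H/O-H (protein, with a starch O-H share at 1466), 1904 nm
#' O-H/C-O (starch), 1634 nm O-H (water). Amylose is modelled as a starch
#' sub-component sharing the 1904 nm band with its own weight plus a
#' distinct band, and dietary fiber receives cell-wall C-H/O-H bands; band
#' widths and amplitudes are free model parameters.
#'
#' @param bands named list (one element per constituent) of data.frames
#'   with columns `center_nm`, `sigma_nm`, `amplitude` (absorbance units
#'   per percent concentration).
#' @return a `component_band_model`.
#' @export
component_band_model <- function(bands = default_bands()) {
  stopifnot(is.list(bands), length(bands) >= 1)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    stopifnot(all(c("center_nm", "sigma_nm", "amplitude") %in% names(b)),
              nrow(b) >= 1)
    if (any(b$amplitude < 0)) stop("negative band amplitude for '", nm, "'")
    if (any(b$sigma_nm <= 0)) stop("non-positive band width for '", nm, "'")
  }
  structure(list(bands = bands), class = "component_band_model")
}

#' @rdname component_band_model
#' @export
default_bands <- function() {
  band <- function(center, sigma, amp) {
    data.frame(center_nm = center, sigma_nm = sigma, amplitude = amp)
  }
  # amplitudes are kept small relative to the baseline so that apparent
  # absorbance stays quasi-linear in composition after MSC (the per-sample
  # MSC slope then hardly depends on composition)
  list(
    protein_pct = band(c(1466, 2288), c(25, 14), c(0.0030, 0.0025)),
    starch_pct  = band(c(1904, 1466), c(25, 25), c(0.0020, 0.00075)),
    amylose_pct = band(c(1904, 2136), c(25, 28), c(0.00075, 0.0015)),
    tdf_pct     = band(c(1730, 1374), c(22, 22), c(0.0025, 0.0015)),
    oil_pct     = band(c(1196, 2322), c(20, 14), c(0.0035, 0.0040)),
    moisture_pct = band(1634, 25, 0.0035)
  )
}

#' Simulation configuration
#'
#' Defaults emulate the diversity of a ~500-accession brown-rice germplasm
#' scan set: trait ranges span the laboratory reference ranges of the
#' study conditions (protein 6.45-14.63, TDF 4.43-5.84, starch 65-85.45,
#' amylose 5.23-30.7, oil 3.05-7.00, all percent), moisture is a nuisance
#' variable in 9.5-11.9 percent, and nitrogen is emitted such that
#' protein = N * 5.95 exactly.
#'
#' @param n_samples number of samples (default 500).
#' @param trait_ranges named list of `c(min, max)` percent ranges.
#' @param protein_factor nitrogen-to-protein conversion factor (5.95).
#' @param central_frac fraction of samples drawn from the central scaled
#'   Beta(2,2) component; the remainder is uniform over the full range so
#'   extreme values carry real mass.
#' @param scatter_slope_sd SD of the per-sample multiplicative scatter
#'   factor (around 1).
#' @param scatter_offset_sd SD of the per-sample additive offset (AU).
#' @param noise_sd i.i.d. instrument noise SD per wavelength (AU).
#' @param baseline_offset,baseline_slope,baseline_curvature fixed baseline:
#'   `offset + slope*(lambda-400) + curvature*((lambda-1445)/1045)^2` (AU).
#' @param wavelengths_nm wavelength grid (default 400-2490 nm step 2,
#'   1046 points).
#' @return a `simulation_config`.
#' @export
simulation_config <- function(n_samples = 500,
                              trait_ranges = list(
                                protein_pct = c(6.45, 14.63),
                                tdf_pct     = c(4.43, 5.84),
                                starch_pct  = c(65.00, 85.45),
                                amylose_pct = c(5.23, 30.70),
                                oil_pct     = c(3.05, 7.00),
                                moisture_pct = c(9.5, 11.9)),
                              protein_factor = 5.95,
                              central_frac = 0.7,
                              scatter_slope_sd = 0.05,
                              scatter_offset_sd = 0.02,
                              noise_sd = 3e-4,
                              baseline_offset = 0.25,
                              baseline_slope = 1.2e-4,
                              baseline_curvature = 0.05,
                              wavelengths_nm = seq(400, 2490, by = 2)) {
  stopifnot(n_samples >= 2, central_frac >= 0, central_frac <= 1)
  for (nm in names(trait_ranges)) {
    r <- trait_ranges[[nm]]
    if (length(r) != 2 || r[2] < r[1]) {
      stop("degenerate range for trait '", nm, "'")
    }
  }
  structure(list(n_samples = n_samples, trait_ranges = trait_ranges,
                 protein_factor = protein_factor,
                 central_frac = central_frac,
                 scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 noise_sd = noise_sd,
                 baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope,
                 baseline_curvature = baseline_curvature,
                 wavelengths_nm = wavelengths_nm),
            class = "simulation_config")
}

# Mixture marginal: central_frac scaled Beta(2,2) + rest uniform, over [lo, hi].
draw_trait <- function(n, lo, hi, central_frac) {
  central <- stats::runif(n) < central_frac
  v <- numeric(n)
  v[central] <- lo + (hi - lo) * stats::rbeta(sum(central), 2, 2)
  v[!central] <- stats::runif(sum(!central), lo, hi)
  v
}

#' Simulate a reference composition table
#'
#' Trait marginals are a mixture of a central scaled Beta(2,2) and a
#' uniform over the full range, emulating a germplasm set curated for
#' near-uniform coverage with extreme-value mass. Amylose is generated as
#' a uniform fraction of starch, clipped to its own range, so that
#' amylose <= starch row-wise. A nitrogen column is emitted with
#' `protein = nitrogen * protein_factor` holding exactly.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; fully determines the output.
#' @return a [reference_table()] with `n_samples` rows.
#' @export
simulate_compositions <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  r <- config$trait_ranges
  if (r$amylose_pct[1] > r$starch_pct[2]) {
    stop("infeasible constraint: amylose minimum exceeds starch maximum")
  }
  set.seed(seed)
  n <- config$n_samples
  cf <- config$central_frac
  protein <- draw_trait(n, r$protein_pct[1], r$protein_pct[2], cf)
  tdf     <- draw_trait(n, r$tdf_pct[1], r$tdf_pct[2], cf)
  starch  <- draw_trait(n, r$starch_pct[1], r$starch_pct[2], cf)
  oil     <- draw_trait(n, r$oil_pct[1], r$oil_pct[2], cf)
  moisture <- draw_trait(n, r$moisture_pct[1], r$moisture_pct[2], cf)
  # amylose: uniform fraction of starch, clipped to its own range
  f_lo <- r$amylose_pct[1] / r$starch_pct[2]
  f_hi <- min(1, r$amylose_pct[2] / r$starch_pct[1])
  frac <- stats::runif(n, f_lo, f_hi)
  amylose <- pmin(pmax(frac * starch, r$amylose_pct[1]), r$amylose_pct[2])
  amylose <- pmin(amylose, starch)
  nitrogen <- protein / config$protein_factor
  protein <- nitrogen * config$protein_factor
  reference_table(data.frame(
    sample_id = sprintf("ACC%04d", seq_len(n)),
    protein_pct = protein, tdf_pct = tdf, starch_pct = starch,
    amylose_pct = amylose, oil_pct = oil, moisture_pct = moisture,
    nitrogen_pct = nitrogen,
    stringsAsFactors = FALSE))
}

#' Simulate NIR absorbance spectra from compositions
#'
#' Absorbance is a linear mixture of the constituent band signatures plus a
#' fixed baseline, per-sample multiplicative scatter `b_i ~ N(1, sd^2)` and
#' additive offset `a_i ~ N(0, sd^2)`, and i.i.d. noise:
#' `A_i(lambda) = a_i + b_i * (baseline(lambda) + sum_k c_ik s_k(lambda)) + eps`.
#' With scatter and noise set to zero, spectra are exact linear functions
#' of composition.
#'
#' @param compositions a [reference_table()]; constituent columns must be
#'   covered by the band model (extra columns such as `nitrogen_pct` are
#'   ignored).
#' @param bands a [component_band_model()].
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return a [spectra_set()].
#' @export
simulate_spectra <- function(compositions, bands = component_band_model(),
                             config = simulation_config(), seed = 1) {
  stopifnot(inherits(compositions, "reference_table"),
            inherits(bands, "component_band_model"),
            inherits(config, "simulation_config"))
  if (nrow(compositions) == 0) stop("empty composition table")
  constituents <- names(bands$bands)
  missing <- setdiff(constituents, names(compositions))
  if (length(missing)) {
    stop("composition table lacks constituent column(s): ",
         paste(missing, collapse = ", "))
  }
  wl <- config$wavelengths_nm
  # signature matrix: one row per constituent
  sig <- t(vapply(constituents, function(k) {
    b <- bands$bands[[k]]
    rowSums(vapply(seq_len(nrow(b)), function(j) {
      b$amplitude[j] * exp(-(wl - b$center_nm[j])^2 / (2 * b$sigma_nm[j]^2))
    }, numeric(length(wl))))
  }, numeric(length(wl))))
  conc <- as.matrix(as.data.frame(compositions)[, constituents, drop = FALSE])
  baseline <- config$baseline_offset +
    config$baseline_slope * (wl - 400) +
    config$baseline_curvature * ((wl - 1445) / 1045)^2
  clean <- sweep(conc %*% sig, 2, baseline, "+")
  set.seed(seed)
  n <- nrow(clean)
  b_i <- stats::rnorm(n, 1, config$scatter_slope_sd)
  a_i <- stats::rnorm(n, 0, config$scatter_offset_sd)
  eps <- matrix(stats::rnorm(n * length(wl), 0, config$noise_sd),
                n, length(wl))
  if (config$noise_sd == 0) eps[] <- 0
  mat <- a_i + b_i * clean + eps
  spectra_set(mat, wl, compositions$sample_id,
              meta = list(history = character(),
                          instrument = "synthetic linear band mixer",
                          seed = seed))
}

#' Standard end-to-end study fixture
#'
#' Generates the standard synthetic study set: 500 accessions on the
#' 400-2490 nm / 2 nm grid with default band model and noise, optionally
#' written to CSV.
#'
#' @param seed integer seed (default 42).
#' @param dir optional directory; when given, `spectra.csv` and
#'   `reference.csv` are written there.
#' @param config a [simulation_config()].
#' @return list with `spectra` (a [spectra_set()]) and `reference`
#'   (a [reference_table()]).
#' @export
make_study_fixture <- function(seed = 42, dir = NULL,
                               config = simulation_config()) {
  ref <- simulate_compositions(config, seed = seed)
  # derive a distinct spectral seed so composition and noise draws are
  # independent streams but both determined by `seed`
  sp <- simulate_spectra(ref, component_band_model(), config,
                         seed = seed + 1000L)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_spectra(sp, file.path(dir, "spectra.csv"))
    write_reference(ref, file.path(dir, "reference.csv"))
  }
  list(spectra = sp, reference = ref)
}
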
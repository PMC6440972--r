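#' Simulation configuration for synthetic single-cell trace cohorts
#'
#' Collects every generative parameter of the synthetic-data module into a
#' validated list. Defaults describe the reference experiment the package
#' emulates: NIH-3T3 reporter cells carrying a dox-inducible Nluc-SMAD4 (or
#' -SMAD2) fusion and a firefly-luciferase ctgf knock-in, induced with
#' 2 ng/ml doxycycline, imaged on a 5-minute cycle for 24 h and stimulated
#' with 5 nM TGF-beta after 3 h of baseline recording.
#'
#' Timing parameters not supplied explicitly are resolved from `smad_kind`:
#' SMAD4 translocation peaks on average 55 min post-stimulus with CV 0.33,
#' SMAD2 at 66 min with CV 0.35.
#'
#' @param n_cells number of cells in the cohort.
#' @param duration recording length, minutes.
#' @param cycle_time acquisition cycle, minutes; must divide `duration`.
#' @param stim_time time of TGF-beta addition, minutes from recording start.
#' @param tgfb_dose_pM TGF-beta dose in pM (5 nM = 5000).
#' @param dox_ng_ml doxycycline dose in ng/ml; scales total SMAD fusion level
#'   linearly relative to the 2 ng/ml reference. Translocation kinetics are
#'   unaffected.
#' @param smad_kind `"SMAD4"` or `"SMAD2"`.
#' @param peak_time_mean,peak_time_cv gamma-distributed translocation peak
#'   time (minutes post-stimulus); `NULL` resolves from `smad_kind`.
#' @param baseline_nc pre-stimulus nuclear-to-cytoplasmic ratio.
#' @param nc_amplitude_mean,nc_amplitude_cv lognormal peak increment of the
#'   N/C ratio above baseline, before Hill dose scaling.
#' @param hill_K_pM,hill_n Hill constant and coefficient scaling amplitude
#'   with TGF-beta dose; K = 50 pM places 5 pM near floor and 500 pM near
#'   saturation.
#' @param pulse_shape_ratio ratio of decay to rise time constants of the
#'   difference-of-exponentials SMAD pulse (dimensionless).
#' @param smad_onset_delay minutes between ligand addition and the first
#'   rise of the nuclear signal (receptor binding and SMAD phosphorylation
#'   are not instantaneous); capped per cell at half the drawn peak time.
#'   Keeps the basal window (the three points centered on stimulation)
#'   response-free.
#' @param transient_fraction probability that a cell responds transiently.
#' @param lag_mean,lag_cv gamma-distributed delay from the SMAD nuclear peak
#'   to ctgf transcription initiation, minutes.
#' @param transient_peak_delay ctgf peak time for transient cells, minutes
#'   post-stimulus.
#' @param transient_return_time return-to-basal time of transient cells,
#'   minutes post-stimulus.
#' @param sustained_second_wave logical; sustained cells mount a second wave.
#' @param sustained_first_scale first-pulse amplitude of sustained cells
#'   relative to their drawn amplitude (the "weaker first response").
#' @param sustained_plateau inter-wave plateau as a fraction of the sustained
#'   first-pulse amplitude.
#' @param second_wave_jitter_max second-wave onset is uniform on
#'   `[transient_return_time, transient_return_time + second_wave_jitter_max]`
#'   minutes post-stimulus.
#' @param second_wave_rise,second_wave_fall rise and fall times of the second
#'   wave, minutes.
#' @param ctgf_basal,ctgf_basal_cv lognormal basal Fluc level (a.u.).
#'   `ctgf_basal = 0` switches the reporter off entirely.
#' @param ctgf_amplitude_mean,ctgf_amplitude_cv lognormal ctgf response
#'   amplitude (a.u.), Hill-scaled with dose like the SMAD amplitude.
#' @param nluc_level_mean,nluc_level_cv lognormal per-cell total SMAD fusion
#'   level (a.u.) at the reference dox dose.
#' @param sustained_level_factor multiplier on the SMAD level of sustained
#'   cells (default 1: phenotype and level are independent).
#' @param crosstalk_coeff fraction of total Nluc signal bleeding into the
#'   raw Fluc channel.
#' @param substrate_halflife Nluc substrate decay half-life, minutes; `Inf`
#'   disables decay. Applied equally to nucleus and cytoplasm, so N/C ratios
#'   are unaffected.
#' @param noise_cv multiplicative lognormal measurement noise per compartment
#'   per timepoint. Compartment means pool hundreds of pixels, so relative
#'   noise on the mean is small; 0.02 is typical of this integration time.
#' @param seed integer random seed; identical config + seed gives
#'   bit-identical cohorts.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_cells = 10, seed = 1)
#' cfg$peak_time_mean  # 55 for SMAD4
sim_config <- function(n_cells = 100,
                       duration = 1440,
                       cycle_time = 5,
                       stim_time = 180,
                       tgfb_dose_pM = 5000,
                       dox_ng_ml = 2,
                       smad_kind = c("SMAD4", "SMAD2"),
                       peak_time_mean = NULL,
                       peak_time_cv = NULL,
                       baseline_nc = 1,
                       nc_amplitude_mean = 1,
                       nc_amplitude_cv = 0.73,
                       hill_K_pM = 50,
                       hill_n = 1,
                       pulse_shape_ratio = 6,
                       smad_onset_delay = 10,
                       transient_fraction = 0.87,
                       lag_mean = 7,
                       lag_cv = 0.5,
                       transient_peak_delay = 210,
                       transient_return_time = 480,
                       sustained_second_wave = TRUE,
                       sustained_first_scale = 0.8,
                       sustained_plateau = 0.3,
                       second_wave_jitter_max = 240,
                       second_wave_rise = 100,
                       second_wave_fall = 300,
                       ctgf_basal = 100,
                       ctgf_basal_cv = 0.2,
                       ctgf_amplitude_mean = 1000,
                       ctgf_amplitude_cv = 0.6,
                       nluc_level_mean = 1000,
                       nluc_level_cv = 0.3,
                       sustained_level_factor = 1,
                       crosstalk_coeff = 0.015,
                       substrate_halflife = 600,
                       noise_cv = 0.02,
                       seed = 1L) {
  smad_kind <- match.arg(smad_kind)
  if (is.null(peak_time_mean)) {
    peak_time_mean <- if (smad_kind == "SMAD4") 55 else 66
  }
  if (is.null(peak_time_cv)) {
    peak_time_cv <- if (smad_kind == "SMAD4") 0.33 else 0.35
  }
  cfg <- list(
    n_cells = as.integer(n_cells), duration = duration,
    cycle_time = cycle_time, stim_time = stim_time,
    tgfb_dose_pM = tgfb_dose_pM, dox_ng_ml = dox_ng_ml,
    smad_kind = smad_kind,
    peak_time_mean = peak_time_mean, peak_time_cv = peak_time_cv,
    baseline_nc = baseline_nc,
    nc_amplitude_mean = nc_amplitude_mean, nc_amplitude_cv = nc_amplitude_cv,
    hill_K_pM = hill_K_pM, hill_n = hill_n,
    pulse_shape_ratio = pulse_shape_ratio,
    smad_onset_delay = smad_onset_delay,
    transient_fraction = transient_fraction,
    lag_mean = lag_mean, lag_cv = lag_cv,
    transient_peak_delay = transient_peak_delay,
    transient_return_time = transient_return_time,
    sustained_second_wave = isTRUE(sustained_second_wave),
    sustained_first_scale = sustained_first_scale,
    sustained_plateau = sustained_plateau,
    second_wave_jitter_max = second_wave_jitter_max,
    second_wave_rise = second_wave_rise,
    second_wave_fall = second_wave_fall,
    ctgf_basal = ctgf_basal, ctgf_basal_cv = ctgf_basal_cv,
    ctgf_amplitude_mean = ctgf_amplitude_mean,
    ctgf_amplitude_cv = ctgf_amplitude_cv,
    nluc_level_mean = nluc_level_mean, nluc_level_cv = nluc_level_cv,
    sustained_level_factor = sustained_level_factor,
    crosstalk_coeff = crosstalk_coeff,
    substrate_halflife = substrate_halflife,
    noise_cv = noise_cv,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_cells <= 0) abort("`n_cells` must be a positive integer.")
  if (cfg$transient_fraction < 0 || cfg$transient_fraction > 1) {
    abort("`transient_fraction` must lie in [0, 1].")
  }
  cvs <- c(cfg$peak_time_cv, cfg$nc_amplitude_cv, cfg$lag_cv,
           cfg$ctgf_basal_cv, cfg$ctgf_amplitude_cv, cfg$nluc_level_cv,
           cfg$noise_cv)
  if (any(cvs < 0)) abort("all coefficients of variation must be >= 0.")
  if (cfg$cycle_time <= 0 || cfg$duration %% cfg$cycle_time != 0) {
    abort("`cycle_time` must be positive and divide `duration`.")
  }
  if (cfg$stim_time >= cfg$duration || cfg$stim_time < 0) {
    abort("`stim_time` must lie within the recording.")
  }
  if (cfg$stim_time %% cfg$cycle_time != 0) {
    abort("`stim_time` must fall on the acquisition grid.")
  }
  if (cfg$crosstalk_coeff < 0) abort("`crosstalk_coeff` must be >= 0.")
  if (cfg$substrate_halflife <= 0) abort("`substrate_halflife` must be > 0.")
  if (cfg$pulse_shape_ratio <= 1) abort("`pulse_shape_ratio` must exceed 1.")
  if (cfg$smad_onset_delay < 0) abort("`smad_onset_delay` must be >= 0.")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d cells, %g min @ %g min/cycle, stim at %g min\n",
              x$n_cells, x$duration, x$cycle_time, x$stim_time))
  cat(sprintf("  %s, TGF-beta %g pM, dox %g ng/ml, seed %d\n",
              x$smad_kind, x$tgfb_dose_pM, x$dox_ng_ml, x$seed))
  cat(sprintf("  peak time ~ gamma(mean %g, cv %g); amplitude ~ lognormal(mean %g, cv %g)\n",
              x$peak_time_mean, x$peak_time_cv,
              x$nc_amplitude_mean, x$nc_amplitude_cv))
  cat(sprintf("  transient fraction %g, noise cv %g, crosstalk %g\n",
              x$transient_fraction, x$noise_cv, x$crosstalk_coeff))
  invisible(x)
}

#' Read or write a simulation config as JSON
#'
#' The JSON document mirrors the `sim_config` field names one-to-one.
#'
#' @param path file path.
#' @param cfg a `sim_config`.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(paste0("unknown config field(s): ", paste(extra, collapse = ", ")))
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## lognormal parameterized by arithmetic mean and CV
rlnorm_mean_cv <- function(n, mean, cv) {
  if (mean == 0) return(rep(0, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

## gamma parameterized by mean and CV; cv = 0 degenerates to the mean
rgamma_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, scale = mean / shape)
}

hill_scale <- function(dose, K, n) {
  if (dose <= 0) return(0)
  dose^n / (dose^n + K^n)
}
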
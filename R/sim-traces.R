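## Per-cell random substreams ------------------------------------------------
##
## Each cell draws from its own deterministic substream derived from the
## cohort seed, so a cell can be regenerated (or sampled standalone) without
## shifting any other cell's draws. Stage separates the SMAD sampler (1),
## the ctgf sampler (2) and the phenotype draw (0).
stream_seed <- function(seed, cell, stage = 1L, attempt = 0L) {
  s <- (as.double(seed) * 1000003 + as.double(cell) * 7919 +
          as.double(stage) * 104729 + as.double(attempt) * 15485863)
  as.integer(s %% 2147483647)
}

with_stream <- function(seed, cell, stage, fun, max_attempts = 10L) {
  for (attempt in seq_len(max_attempts) - 1L) {
    set.seed(stream_seed(seed, cell, stage, attempt))
    out <- fun()
    if (all(vapply(out, function(x) all(is.finite(x) | is.na(x)), TRUE))) {
      return(out)
    }
    warn(sprintf("non-finite draw for cell %d (stage %d); regenerating with next substream",
                 cell, stage))
  }
  abort(sprintf("cell %d: non-finite draws persisted over %d substreams",
                cell, max_attempts))
}

time_grid <- function(config) {
  seq(0, config$duration, by = config$cycle_time)
}

## SMAD pulse shape ----------------------------------------------------------
##
## Difference of exponentials g(u) = exp(-u/rho) - exp(-u) (rise time
## constant 1, decay rho), time-rescaled per cell so the drawn peak time and
## height are exact: the canonical peak sits at u* = rho log(rho) / (rho-1).
smad_pulse <- function(t_post, peak_time, amplitude, rho, onset_delay = 0) {
  d <- min(onset_delay, 0.5 * peak_time)
  ustar <- rho * log(rho) / (rho - 1)
  gmax <- exp(-ustar / rho) - exp(-ustar)
  u <- pmax(t_post - d, 0) * ustar / (peak_time - d)
  ifelse(t_post <= d, 0, amplitude * (exp(-u / rho) - exp(-u)) / gmax)
}

#' Sample one SMAD translocation trace
#'
#' Draws a single cell's two-compartment Nluc trace. The
#' nuclear-to-cytoplasmic ratio sits at `baseline_nc` before stimulation and
#' rises by a drawn amplitude `A` at a drawn time `T` post-stimulus
#' (difference-of-exponentials pulse, see [sim_config()]). `T` is gamma
#' distributed (mean `peak_time_mean`, CV `peak_time_cv`); `A` is lognormal
#' (mean `nc_amplitude_mean`, CV `nc_amplitude_cv`) scaled by a Hill
#' function of the TGF-beta dose. Total fusion protein is conserved between
#' the compartments, then both are multiplied by the common substrate-decay
#' exponential and by independent per-timepoint lognormal noise.
#'
#' @param config a [sim_config()].
#' @param cell integer cell index selecting the random substream.
#' @return A list with `time_min`, `nluc_nuc`, `nluc_cyt`, `true_peak_time`
#'   (minutes post-stimulus), `true_amplitude`, `smad_level` and `phenotype`.
#' @export
#' @examples
#' tr <- sample_smad_trace(sim_config(seed = 1), cell = 1)
#' max(tr$nluc_nuc / tr$nluc_cyt)
sample_smad_trace <- function(config, cell = 1L) {
  validate_sim_config(config)
  tt <- time_grid(config)
  nt <- length(tt)

  pheno <- with_stream(config$seed, cell, 0L, function() {
    list(sustained = runif(1) < 1 - config$transient_fraction)
  })$sustained
  phenotype <- if (pheno) "sustained" else "transient"

  draws <- with_stream(config$seed, cell, 1L, function() {
    level <- rlnorm_mean_cv(1, config$nluc_level_mean, config$nluc_level_cv) *
      (config$dox_ng_ml / 2)
    if (phenotype == "sustained") level <- level * config$sustained_level_factor
    list(
      level = level,
      peak_time = rgamma_mean_cv(1, config$peak_time_mean, config$peak_time_cv),
      amplitude = rlnorm_mean_cv(1, config$nc_amplitude_mean,
                                 config$nc_amplitude_cv) *
        hill_scale(config$tgfb_dose_pM, config$hill_K_pM, config$hill_n),
      noise_nuc = rlnorm_mean_cv(nt, 1, config$noise_cv),
      noise_cyt = rlnorm_mean_cv(nt, 1, config$noise_cv)
    )
  })

  ratio <- config$baseline_nc +
    smad_pulse(tt - config$stim_time, draws$peak_time, draws$amplitude,
               config$pulse_shape_ratio, config$smad_onset_delay)
  decay <- if (is.finite(config$substrate_halflife)) {
    exp(-tt * log(2) / config$substrate_halflife)
  } else 1
  total <- 2 * draws$level * decay
  list(
    time_min = tt,
    nluc_nuc = total * ratio / (1 + ratio) * draws$noise_nuc,
    nluc_cyt = total / (1 + ratio) * draws$noise_cyt,
    true_peak_time = draws$peak_time,
    true_amplitude = draws$amplitude,
    smad_level = draws$level,
    phenotype = phenotype
  )
}

## piecewise ctgf pulse above basal; all times absolute minutes.
## Sine rise gives a sharp, well-defined initiation; cosine decay lands on
## basal with nonzero slope so the return time is equally sharp.
ctgf_pulse <- function(tt, init, peak, ret, amplitude, phenotype,
                       plateau_frac, t2, rise2, fall2, second_wave) {
  peak <- max(peak, init + 1)
  ret <- max(ret, peak + 1)
  y <- numeric(length(tt))
  rise <- tt >= init & tt < peak
  y[rise] <- amplitude * sin(pi / 2 * (tt[rise] - init) / (peak - init))
  if (phenotype == "transient") {
    fall <- tt >= peak & tt < ret
    y[fall] <- amplitude * cos(pi / 2 * (tt[fall] - peak) / (ret - peak))
  } else {
    plateau <- plateau_frac * amplitude
    fall <- tt >= peak & tt < ret
    y[fall] <- plateau + (amplitude - plateau) *
      cos(pi / 2 * (tt[fall] - peak) / (ret - peak))
    if (!second_wave) {
      y[tt >= ret] <- plateau
    } else {
      p2 <- t2 + rise2
      y[tt >= ret & tt < t2] <- plateau
      r2 <- tt >= t2 & tt < p2
      y[r2] <- plateau + (amplitude - plateau) *
        sin(pi / 2 * (tt[r2] - t2) / rise2)
      f2 <- tt >= p2 & tt < p2 + fall2
      y[f2] <- amplitude * cos(pi / 2 * (tt[f2] - p2) / fall2)
    }
  }
  y
}

#' Sample one ctgf transcriptional reporter trace
#'
#' Draws a single cell's Fluc trace (before cross-talk). Transcription
#' initiates a gamma-distributed lag after the cell's SMAD nuclear peak.
#' Transient cells mount a single pulse peaking `transient_peak_delay`
#' minutes post-stimulus and returning to basal at `transient_return_time`;
#' sustained cells mount a weaker first pulse (`sustained_first_scale`) that
#' decays only to an elevated plateau, followed by a second wave with onset
#' jittered uniformly over `second_wave_jitter_max` minutes.
#'
#' @inheritParams sample_smad_trace
#' @param phenotype `"transient"` or `"sustained"`.
#' @param smad_peak_time the cell's SMAD peak time, minutes post-stimulus.
#' @return A list with `time_min`, `fluc` (noisy, cross-talk-free),
#'   `true_init_time` (minutes post-stimulus), `true_basal` and
#'   `true_ctgf_amplitude`.
#' @export
sample_ctgf_trace <- function(config, phenotype = c("transient", "sustained"),
                              smad_peak_time, cell = 1L) {
  validate_sim_config(config)
  phenotype <- match.arg(phenotype)
  tt <- time_grid(config)
  nt <- length(tt)

  draws <- with_stream(config$seed, cell, 2L, function() {
    list(
      lag = rgamma_mean_cv(1, config$lag_mean, config$lag_cv),
      basal = rlnorm_mean_cv(1, config$ctgf_basal, config$ctgf_basal_cv),
      amplitude = rlnorm_mean_cv(1, config$ctgf_amplitude_mean,
                                 config$ctgf_amplitude_cv) *
        hill_scale(config$tgfb_dose_pM, config$hill_K_pM, config$hill_n),
      t2_jitter = runif(1, 0, config$second_wave_jitter_max),
      noise = rlnorm_mean_cv(nt, 1, config$noise_cv)
    )
  })

  init <- config$stim_time + smad_peak_time + draws$lag
  amp <- if (phenotype == "sustained") {
    config$sustained_first_scale * draws$amplitude
  } else {
    draws$amplitude
  }
  pulse <- ctgf_pulse(
    tt,
    init = init,
    peak = config$stim_time + config$transient_peak_delay,
    ret = config$stim_time + config$transient_return_time,
    amplitude = amp,
    phenotype = phenotype,
    plateau_frac = config$sustained_plateau,
    t2 = config$stim_time + config$transient_return_time + draws$t2_jitter,
    rise2 = config$second_wave_rise,
    fall2 = config$second_wave_fall,
    second_wave = config$sustained_second_wave
  )
  list(
    time_min = tt,
    fluc = (draws$basal + pulse) * draws$noise,
    true_init_time = smad_peak_time + draws$lag,
    true_basal = draws$basal,
    true_ctgf_amplitude = amp
  )
}

#' Inject Nluc-to-Fluc channel cross-talk
#'
#' Adds the bleed-through of the Nluc emission into the raw Fluc channel:
#' `fluc_raw = fluc_true + coeff * nluc_total`. The default coefficient is
#' 1.5% of the total Nluc signal. [crosstalk_correct()] is its exact
#' algebraic inverse.
#'
#' @param nluc_total total (nuclear + cytoplasmic) Nluc signal per timepoint.
#' @param fluc_true cross-talk-free Fluc signal, same length.
#' @param coeff bleed-through fraction, `>= 0`.
#' @return Numeric vector `fluc_raw`.
#' @export
#' @examples
#' apply_crosstalk(rep(1000, 3), rep(0, 3), 0.015)  # 15 15 15
apply_crosstalk <- function(nluc_total, fluc_true, coeff = 0.015) {
  if (length(nluc_total) != length(fluc_true)) {
    abort("`nluc_total` and `fluc_true` must have equal length.")
  }
  if (coeff < 0) abort("`coeff` must be >= 0.")
  fluc_true + coeff * nluc_total
}

#' Simulate a cohort of dual-reporter single-cell traces
#'
#' Generates `config$n_cells` cells on the shared acquisition grid. Each
#' cell's phenotype is Bernoulli (sustained with probability
#' `1 - transient_fraction`); its SMAD and ctgf traces come from
#' [sample_smad_trace()] and [sample_ctgf_trace()], and the stored `fluc`
#' column is the *raw* Fluc channel after cross-talk injection
#' ([apply_crosstalk()]). Identical config + seed gives bit-identical
#' output.
#'
#' @param config a [sim_config()].
#' @return A `trace_set` tibble in long format with columns `cell_id`,
#'   `time_min`, `nluc_nuc`, `nluc_cyt`, `fluc`, `tgfb_dose_pM`,
#'   `dox_ng_ml`, `smad_kind`, carrying a per-cell ground-truth tibble
#'   (see [trace_truth()]) and the config as attributes.
#' @export
#' @examples
#' ts <- simulate_cohort(sim_config(n_cells = 5, seed = 7))
#' trace_truth(ts)
simulate_cohort <- function(config) {
  validate_sim_config(config)
  if (config$n_cells <= 0) abort("`n_cells` must be positive.")
  cells <- purrr::map(seq_len(config$n_cells), function(i) {
    smad <- sample_smad_trace(config, cell = i)
    ctgf <- sample_ctgf_trace(config, phenotype = smad$phenotype,
                              smad_peak_time = smad$true_peak_time, cell = i)
    fluc_raw <- apply_crosstalk(smad$nluc_nuc + smad$nluc_cyt, ctgf$fluc,
                                config$crosstalk_coeff)
    list(
      traces = tibble(
        cell_id = i, time_min = smad$time_min,
        nluc_nuc = smad$nluc_nuc, nluc_cyt = smad$nluc_cyt, fluc = fluc_raw
      ),
      truth = tibble(
        cell_id = i, phenotype = smad$phenotype,
        true_peak_min = smad$true_peak_time,
        true_amplitude = smad$true_amplitude,
        true_init_min = ctgf$true_init_time,
        true_basal = ctgf$true_basal,
        true_ctgf_amplitude = ctgf$true_ctgf_amplitude,
        smad_level = smad$smad_level
      )
    )
  })
  traces <- purrr::list_rbind(purrr::map(cells, "traces"))
  traces$tgfb_dose_pM <- config$tgfb_dose_pM
  traces$dox_ng_ml <- config$dox_ng_ml
  traces$smad_kind <- config$smad_kind
  new_trace_set(traces,
                truth = purrr::list_rbind(purrr::map(cells, "truth")),
                config = config)
}
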
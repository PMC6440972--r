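## centered moving average with shrinking windows at the edges
moving_avg <- function(x, w = 3) {
  if (w <= 1) return(x)
  k <- (w - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - k):min(n, i + k)])
  }, numeric(1))
}

#' Nuclear-to-cytoplasmic ratio series
#'
#' Elementwise nuclear / cytoplasmic intensity per timepoint — the
#' translocation readout, insensitive to any common multiplicative factor
#' such as substrate decay. Frames where the cytoplasmic signal falls below
#' `floor_frac` of the trace maximum are marked missing (`NA`).
#'
#' @param nuc,cyt equal-length intensity vectors.
#' @param floor_frac relative floor below which a cytoplasmic value is
#'   considered unquantifiable.
#' @return Numeric vector of ratios with `NA` at missing frames.
#' @export
#' @examples
#' nc_ratio(c(2, 4), c(2, 2))  # 1 2
nc_ratio <- function(nuc, cyt, floor_frac = 1e-6) {
  if (length(nuc) != length(cyt)) abort("compartment series lengths differ.")
  floor <- floor_frac * max(cyt, na.rm = TRUE)
  out <- nuc / cyt
  out[!is.na(cyt) & cyt <= floor] <- NA_real_
  out
}

#' Basal level around the stimulation time
#'
#' Mean of the three timepoints centered at the stimulation time (one cycle
#' before, at, and one cycle after). At a grid edge the available subset is
#' used with a warning.
#'
#' @param series intensity or ratio values on the acquisition grid.
#' @param time matching time vector, minutes.
#' @param stim_time stimulation time, minutes.
#' @return Scalar basal level.
#' @export
#' @examples
#' basal_level(c(2, 4, 6), c(175, 180, 185), 180)  # 4
basal_level <- function(series, time, stim_time) {
  cycle <- median(diff(sort(unique(time))))
  want <- stim_time + c(-cycle, 0, cycle)
  idx <- which(time %in% want)
  if (length(idx) == 0) abort("no timepoints found around `stim_time`.")
  if (length(idx) < 3) {
    warn("stimulation at grid edge; basal level uses fewer than 3 points.")
  }
  mean(series[idx], na.rm = TRUE)
}

#' Detect the post-stimulation peak of a trace
#'
#' The series is smoothed with a centered moving average (default 3
#' points); the peak time is the argmax of the smoothed series within the
#' post-stimulation search window (earliest index on ties), and the peak
#' level is the mean of the *raw* values at the peak point and its two grid
#' neighbours. A peak on the window boundary is flagged censored.
#'
#' @inheritParams basal_level
#' @param window search interval in minutes post-stimulation; the SMAD
#'   default is 0-4 h, use `c(0, 720)` for ctgf.
#' @param smooth moving-average width in points.
#' @return A list with `peak_time` (minutes post-stimulation), `peak_level`
#'   and `censored`.
#' @export
#' @examples
#' detect_peak(c(0, 0, 8, 10, 8, 0, 0), time = 0:6 * 5, stim_time = 0,
#'             window = c(0, 30))$peak_level  # 26/3
detect_peak <- function(series, time, stim_time, window = c(0, 240),
                        smooth = 3) {
  idx <- which(time >= stim_time + window[1] & time <= stim_time + window[2])
  if (length(idx) == 0) abort("search window contains no timepoints.")
  sm <- moving_avg(series, smooth)
  pk <- idx[which.max(sm[idx])]
  n <- length(series)
  list(
    peak_time = time[pk] - stim_time,
    peak_level = mean(series[max(1, pk - 1):min(n, pk + 1)], na.rm = TRUE),
    censored = pk == idx[1] || pk == idx[length(idx)]
  )
}

#' Response amplitude and fold change
#'
#' `response = peak - basal`; `fold_change = peak / basal`, undefined
#' (`NA`) when the basal level is not positive.
#'
#' @param basal,peak scalar (or equal-length vector) levels.
#' @return A tibble with columns `response` and `fold_change`.
#' @export
#' @examples
#' response_and_fold(2, 6)  # response 4, fold 3
response_and_fold <- function(basal, peak) {
  fold <- ifelse(basal > 0, peak / basal, NA_real_)
  tibble(response = peak - basal, fold_change = fold)
}

## effective basal SD with a tiny relative floor so the run rules stay
## defined on noise-free traces (which sit exactly at basal outside pulses)
basal_sd_floor <- function(basal_sd, basal) {
  max(basal_sd, 1e-8 * max(abs(basal), 1e-12), na.rm = TRUE)
}

first_run_time <- function(flag, time, m) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= m)
  if (length(hit) == 0) return(NA_real_)
  time[ends[hit[1]] - r$lengths[hit[1]] + 1]
}

#' Detect the initiation time of a transcriptional response
#'
#' First post-stimulation time where `m` consecutive points all exceed
#' `basal + k * basal_sd`, with `basal_sd` the SD of the pre-stimulation
#' points. Automates the manual annotation of where the reporter starts to
#' rise. Returns `NA` when the series never initiates.
#'
#' @inheritParams basal_level
#' @param basal basal level (see [basal_level()]).
#' @param basal_sd SD of the pre-stimulation points; when fewer than 3
#'   pre-stimulation points exist, supply the SD of the 3 basal points.
#' @param k threshold multiplier.
#' @param m number of consecutive supra-threshold points required.
#' @return Initiation time in minutes post-stimulation, or `NA`.
#' @export
detect_initiation <- function(series, time, stim_time, basal, basal_sd,
                              k = 2, m = 3) {
  thr <- basal + k * basal_sd_floor(basal_sd, basal)
  post <- time > stim_time
  t0 <- first_run_time(series[post] > thr & !is.na(series[post]),
                       time[post], m)
  if (is.na(t0)) NA_real_ else t0 - stim_time
}

#' Detect the return-to-basal time of a transcriptional response
#'
#' First time after the detected peak with `m` consecutive points below
#' `basal + k * basal_sd`. `NA` when the trace never returns within the
#' recording — the signature of a sustained response.
#'
#' @inheritParams detect_initiation
#' @param peak_time detected peak time, minutes post-stimulation.
#' @return Return time in minutes post-stimulation, or `NA`.
#' @export
detect_return <- function(series, time, stim_time, peak_time, basal,
                          basal_sd, k = 2, m = 3) {
  thr <- basal + k * basal_sd_floor(basal_sd, basal)
  ## a trace that never rose above threshold has no return to detect
  if (!any(series[time > stim_time] > thr, na.rm = TRUE)) return(NA_real_)
  post <- time > stim_time + peak_time
  t0 <- first_run_time(series[post] < thr & !is.na(series[post]),
                       time[post], m)
  if (is.na(t0)) NA_real_ else t0 - stim_time
}

#' Rescale a trace to a unit range
#'
#' `mode = "max"` divides by the trace maximum (the normalization used for
#' clustering and heatmap display); `mode = "minmax"` maps the time course
#' onto `[0, 1]`. Both are idempotent.
#'
#' @param series numeric vector.
#' @param mode `"max"` or `"minmax"`.
#' @return Rescaled numeric vector.
#' @export
#' @examples
#' normalize_trace(c(0, 5, 10))          # 0 0.5 1
#' normalize_trace(c(2, 4, 6), "minmax") # 0 0.5 1
normalize_trace <- function(series, mode = c("max", "minmax")) {
  mode <- match.arg(mode)
  if (mode == "max") {
    mx <- max(series, na.rm = TRUE)
    if (mx <= 0) abort("`max` normalization requires a positive maximum.")
    series / mx
  } else {
    rng <- range(series, na.rm = TRUE)
    if (diff(rng) == 0) {
      warn("constant trace; minmax normalization returns all zeros.")
      return(rep(0, length(series)))
    }
    (series - rng[1]) / diff(rng)
  }
}

#' Per-feature cohort statistics
#'
#' Mean, sample SD (n-1 denominator), CV (= SD/mean) and n over the defined
#' values of each requested feature column.
#'
#' @param features a features tibble (see [quantify_cohort()]).
#' @param fields character vector of feature column names.
#' @return A tibble with columns `feature`, `n`, `mean`, `sd`, `cv`.
#' @export
#' @examples
#' cohort_stats(data.frame(x = c(1, 3)), "x")  # mean 2, cv ~0.707
cohort_stats <- function(features, fields) {
  purrr::map(fields, function(f) {
    v <- features[[f]]
    if (is.null(v)) abort(paste0("no feature column `", f, "`."))
    v <- v[!is.na(v)]
    n <- length(v)
    m <- if (n > 0) mean(v) else NA_real_
    s <- if (n >= 2) sd(v) else NA_real_
    tibble(feature = f, n = n, mean = m, sd = s,
           cv = if (!is.na(s) && !is.na(m) && m != 0) s / m else NA_real_)
  }) |> purrr::list_rbind()
}

#' Quantify per-cell response features over a cohort
#'
#' Runs the full feature pipeline on a [trace_set][new_trace_set()]: N/C
#' ratio, cross-talk correction of the Fluc channel, basal levels, peak
#' detection, response amplitudes and fold changes, ctgf initiation and
#' return times, and the mean total SMAD level over the 12 h following
#' stimulation. Cells with too many unquantifiable frames or a censored
#' SMAD peak are flagged in `excluded` / `exclusion_reason`, never silently
#' dropped.
#'
#' All reported times are minutes post-stimulation.
#'
#' @param traces a `trace_set` (or data frame with its columns).
#' @param stim_time stimulation time in minutes; defaults to the trace-set
#'   attribute.
#' @param crosstalk_coeff Nluc-to-Fluc bleed-through fraction subtracted
#'   before ctgf quantification.
#' @param smad_window,ctgf_window peak search windows, minutes
#'   post-stimulation.
#' @param k,m initiation/return run-rule parameters (see
#'   [detect_initiation()]).
#' @param smooth moving-average width for peak detection.
#' @param level_window window (minutes post-stimulation) for
#'   `mean_smad_level`.
#' @param max_missing maximum tolerated fraction of missing N/C frames.
#' @return A tibble with one row per cell: identification and condition
#'   columns, all response features, and `excluded`/`exclusion_reason`.
#' @export
#' @examples
#' ts <- simulate_cohort(sim_config(n_cells = 4, seed = 1))
#' quantify_cohort(ts)[, c("cell_id", "smad_peak_time", "nc_response")]
quantify_cohort <- function(traces, stim_time = NULL,
                            crosstalk_coeff = 0.015,
                            smad_window = c(0, 240),
                            ctgf_window = c(0, 720),
                            k = 2, m = 3, smooth = 3,
                            level_window = 720,
                            max_missing = 0.2) {
  stim_time <- stim_time %||% attr(traces, "stim_time") %||% 180
  cond_cols <- intersect(c("tgfb_dose_pM", "dox_ng_ml", "smad_kind"),
                         names(traces))
  out <- as_tibble(traces) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_map(function(df, key) {
      f <- quantify_cell(df, stim_time, crosstalk_coeff, smad_window,
                         ctgf_window, k, m, smooth, level_window,
                         max_missing)
      dplyr::bind_cols(key, f,
                       df[1, cond_cols, drop = FALSE])
    }) |>
    purrr::list_rbind()
  out
}

quantify_cell <- function(df, stim_time, crosstalk_coeff, smad_window,
                          ctgf_window, k, m, smooth, level_window,
                          max_missing) {
  tt <- df$time_min
  nc <- nc_ratio(df$nluc_nuc, df$nluc_cyt)
  excluded <- FALSE
  reason <- NA_character_

  if (mean(is.na(nc)) > max_missing) {
    excluded <- TRUE
    reason <- "too_many_missing_nc_frames"
  }

  nluc_total <- df$nluc_nuc + df$nluc_cyt
  fluc_corr <- crosstalk_correct(df$fluc, nluc_total, crosstalk_coeff)

  basal_nc <- basal_level(nc, tt, stim_time)
  smad_pk <- detect_peak(nc, tt, stim_time, window = smad_window,
                         smooth = smooth)
  nc_rf <- response_and_fold(basal_nc, smad_pk$peak_level)
  if (!excluded && smad_pk$censored) {
    excluded <- TRUE
    reason <- "censored_smad_peak"
  }

  pre <- tt < stim_time
  ctgf_basal <- basal_level(fluc_corr, tt, stim_time)
  ctgf_basal_sd <- if (sum(pre) >= 3) {
    sd(fluc_corr[pre])
  } else {
    warn("fewer than 3 pre-stimulation points; basal SD from the 3 basal points.")
    cycle <- median(diff(tt))
    idx <- which(tt %in% (stim_time + c(-cycle, 0, cycle)))
    sd(fluc_corr[idx])
  }
  ctgf_pk <- detect_peak(fluc_corr, tt, stim_time, window = ctgf_window,
                         smooth = smooth)
  ctgf_rf <- response_and_fold(ctgf_basal, ctgf_pk$peak_level)
  init <- detect_initiation(fluc_corr, tt, stim_time, ctgf_basal,
                            ctgf_basal_sd, k = k, m = m)
  ret <- detect_return(fluc_corr, tt, stim_time, ctgf_pk$peak_time,
                       ctgf_basal, ctgf_basal_sd, k = k, m = m)

  lvl_idx <- tt >= stim_time & tt <= stim_time + level_window
  tibble(
    basal_nc = basal_nc,
    peak_nc = smad_pk$peak_level,
    nc_response = nc_rf$response,
    nc_fold_change = nc_rf$fold_change,
    smad_peak_time = smad_pk$peak_time,
    smad_peak_censored = smad_pk$censored,
    ctgf_basal = ctgf_basal,
    ctgf_peak = ctgf_pk$peak_level,
    ctgf_response = ctgf_rf$response,
    ctgf_fold_change = ctgf_rf$fold_change,
    ctgf_init_time = init,
    ctgf_peak_time = ctgf_pk$peak_time,
    ctgf_peak_censored = ctgf_pk$censored,
    return_time = ret,
    mean_smad_level = mean(nluc_total[lvl_idx]),
    excluded = excluded,
    exclusion_reason = reason
  )
}
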
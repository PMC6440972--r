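#' Correlation between SMAD translocation and ctgf response amplitude
#'
#' Pearson correlation (with two-sided p-value) between the per-cell SMAD
#' N/C fold change and the ctgf response amplitude, computed per dose.
#' Spearman's rho is reported alongside for robustness.
#'
#' @param features a [quantify_cohort()] tibble.
#' @param x,y feature columns to correlate.
#' @param by grouping columns (default: dose and SMAD kind when present).
#' @return A tibble with one row per group: `n`, `r`, `p_value`,
#'   `spearman_rho`, `spearman_p`, and `reason` (`NA` unless undefined).
#'   Groups with fewer than 3 complete cells get `NA` estimates.
#' @export
amplitude_correlation <- function(features, x = "nc_fold_change",
                                  y = "ctgf_response",
                                  by = intersect(c("tgfb_dose_pM", "smad_kind"),
                                                 names(features))) {
  feature_correlation(features, x, y, by)
}

#' Correlation between SMAD peak timing and ctgf initiation timing
#'
#' @inheritParams amplitude_correlation
#' @return As [amplitude_correlation()].
#' @export
timing_correlation <- function(features, x = "smad_peak_time",
                               y = "ctgf_init_time",
                               by = intersect(c("tgfb_dose_pM", "smad_kind"),
                                              names(features))) {
  feature_correlation(features, x, y, by)
}

feature_correlation <- function(features, x, y, by) {
  df <- as_tibble(features)
  for (col in c(x, y)) {
    if (!col %in% names(df)) abort(paste0("no feature column `", col, "`."))
  }
  grouped <- if (length(by) > 0) {
    dplyr::group_by(df, dplyr::across(dplyr::all_of(by)))
  } else {
    dplyr::group_by(df, .tmp = 1)
  }
  out <- dplyr::group_modify(grouped, function(g, key) {
    ok <- complete.cases(g[[x]], g[[y]])
    n <- sum(ok)
    if (n < 3) {
      return(tibble(n = n, r = NA_real_, p_value = NA_real_,
                    spearman_rho = NA_real_, spearman_p = NA_real_,
                    reason = "fewer than 3 complete cells"))
    }
    pe <- cor.test(g[[x]][ok], g[[y]][ok], method = "pearson")
    sp <- suppressWarnings(
      cor.test(g[[x]][ok], g[[y]][ok], method = "spearman")
    )
    tibble(n = n, r = unname(pe$estimate), p_value = pe$p.value,
           spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
           reason = NA_character_)
  }) |> dplyr::ungroup()
  out[, setdiff(names(out), ".tmp")]
}

#' Per-dose response summaries
#'
#' Summarizes features per (TGF-beta dose, SMAD kind): cell count,
#' responder fraction (cells with a defined ctgf initiation time), medians
#' and IQRs of the SMAD and ctgf response amplitudes (amplitudes among
#' responders), and median timing features. Graded amplitude medians at
#' near-constant responder fractions across doses indicate analog rather
#' than digital dose encoding.
#'
#' @param features a [quantify_cohort()] tibble covering >= 2 doses (or a
#'   single dose, for which the summary is still returned).
#' @param by grouping columns.
#' @return A tibble with one row per condition.
#' @export
dose_profile <- function(features,
                         by = intersect(c("tgfb_dose_pM", "smad_kind"),
                                        names(features))) {
  if (length(by) == 0) abort("`features` lacks condition columns to group by.")
  as_tibble(features) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarize(
      n = dplyr::n(),
      responder_fraction = mean(!is.na(.data$ctgf_init_time)),
      nc_response_median = median(.data$nc_response, na.rm = TRUE),
      nc_response_iqr = stats::IQR(.data$nc_response, na.rm = TRUE),
      ctgf_response_median = med_or_na(
        .data$ctgf_response[!is.na(.data$ctgf_init_time)]),
      ctgf_response_iqr = iqr_or_na(
        .data$ctgf_response[!is.na(.data$ctgf_init_time)]),
      smad_peak_time_median = median(.data$smad_peak_time, na.rm = TRUE),
      ctgf_init_time_median = med_or_na(.data$ctgf_init_time),
      ctgf_peak_time_median = median(.data$ctgf_peak_time, na.rm = TRUE),
      .groups = "drop"
    )
}

med_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else median(x)
}

iqr_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else stats::IQR(x)
}
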
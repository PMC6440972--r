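#' Trace-set container
#'
#' A `trace_set` is a long-format tibble of per-cell, per-timepoint
#' two-channel intensities (`cell_id`, `time_min`, `nluc_nuc`, `nluc_cyt`,
#' `fluc`, plus the condition columns `tgfb_dose_pM`, `dox_ng_ml`,
#' `smad_kind`). Simulated sets additionally carry a ground-truth tibble and
#' the generating [sim_config()] as attributes; sets read from measured data
#' simply lack them.
#'
#' @param traces a data frame with at least the five core columns.
#' @param truth optional per-cell ground-truth tibble.
#' @param config optional [sim_config()].
#' @param stim_time stimulation time in minutes; taken from `config` when
#'   present.
#' @return A tibble of class `trace_set`.
#' @export
new_trace_set <- function(traces, truth = NULL, config = NULL,
                          stim_time = NULL) {
  need <- c("cell_id", "time_min", "nluc_nuc", "nluc_cyt", "fluc")
  missing <- setdiff(need, names(traces))
  if (length(missing) > 0) {
    abort(paste0("trace set lacks column(s): ", paste(missing, collapse = ", ")))
  }
  out <- as_tibble(traces)
  if (any(out$nluc_nuc < 0 | out$nluc_cyt < 0 | out$fluc < 0, na.rm = TRUE)) {
    abort("intensities must be >= 0.")
  }
  grids <- split(out$time_min, out$cell_id)
  if (length(unique(vapply(grids, function(g) paste(g, collapse = ","), ""))) > 1) {
    abort("all cells must share the same time grid.")
  }
  attr(out, "truth") <- if (!is.null(truth)) as_tibble(truth)
  attr(out, "config") <- config
  attr(out, "stim_time") <- stim_time %||% config$stim_time
  class(out) <- c("trace_set", class(tibble()))
  out
}

#' @rdname new_trace_set
#' @param x a `trace_set`.
#' @export
trace_truth <- function(x) attr(x, "truth")

#' @rdname new_trace_set
#' @export
trace_config <- function(x) attr(x, "config")

#' @export
print.trace_set <- function(x, ...) {
  n_cells <- dplyr::n_distinct(x$cell_id)
  nt <- dplyr::n_distinct(x$time_min)
  cat(sprintf("<trace_set> %d cells x %d timepoints%s\n", n_cells, nt,
              if (is.null(trace_truth(x))) "" else " (with ground truth)"))
  NextMethod()
}

#' Write / read a trace set as CSV
#'
#' The main file holds the long-format table
#' `cell_id,time_min,nluc_nuc,nluc_cyt,fluc,tgfb_dose_pM,dox_ng_ml,smad_kind`;
#' ground truth, when present, goes to a `<path>_truth.csv` sidecar
#' (`cell_id,phenotype,true_peak_min,true_amplitude,true_init_min,...`).
#'
#' @param x a `trace_set`.
#' @param path CSV path for the trace table.
#' @param stim_time stimulation time for a set read from plain CSV (minutes).
#' @return `write_trace_set()` returns `path` invisibly; `read_trace_set()`
#'   a `trace_set`.
#' @export
write_trace_set <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  tr <- trace_truth(x)
  if (!is.null(tr)) readr::write_csv(tr, truth_sidecar(path))
  invisible(path)
}

#' @rdname write_trace_set
#' @export
read_trace_set <- function(path, stim_time = 180) {
  traces <- readr::read_csv(path, show_col_types = FALSE)
  side <- truth_sidecar(path)
  truth <- if (file.exists(side)) {
    readr::read_csv(side, show_col_types = FALSE)
  }
  new_trace_set(traces, truth = truth, stim_time = stim_time)
}

truth_sidecar <- function(path) {
  sub("(\\.[^.]+)?$", "_truth.csv", path, perl = TRUE)
}

#' Plot single-cell traces
#'
#' Draws the N/C ratio and raw Fluc time courses of (a subset of) cells,
#' colored by ground-truth phenotype when available.
#'
#' @param object a `trace_set`.
#' @param cells cell ids to draw (default: up to 20).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.trace_set <- function(object, cells = NULL, ...) {
  cells <- cells %||% head(unique(object$cell_id), 20)
  df <- dplyr::filter(object, .data$cell_id %in% cells)
  df <- dplyr::mutate(df, nc_ratio = .data$nluc_nuc / .data$nluc_cyt)
  truth <- trace_truth(object)
  if (!is.null(truth)) {
    df <- dplyr::left_join(df, truth[, c("cell_id", "phenotype")], by = "cell_id")
  } else {
    df$phenotype <- "unknown"
  }
  long <- tidyr::pivot_longer(df, c("nc_ratio", "fluc"),
                              names_to = "channel", values_to = "value")
  stim <- attr(object, "stim_time")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$value,
                                          group = .data$cell_id,
                                          color = .data$phenotype)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL, color = "phenotype")
  if (!is.null(stim)) {
    p <- p + ggplot2::geom_vline(xintercept = stim, linetype = "dashed")
  }
  p
}
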
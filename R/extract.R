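#' Extract background- and compartment-resolved traces from a movie
#'
#' For every trajectory frame, quantifies the mean pixel intensity of the
#' nuclear disc (radius `params$nucleus_radius` around the tracked
#' centroid) and of the cytoplasmic annulus (`annulus_gap` /
#' `annulus_width` outside the disc, with pixels contested between
#' neighbouring cells assigned to the nearest centroid and pixels inside
#' any nucleus excluded) in both channels, minus the per-frame background
#' (the `background_percentile` of pixels outside all masks). The Fluc
#' value is the area-weighted mean over nucleus plus annulus. Negative
#' background-subtracted values are clipped to zero with a warning.
#'
#' @param stack a `movie_stack` from [render_movie()] (or read from TIFF).
#' @param trajectories a [track()] tibble.
#' @param params a [segmentation_params()].
#' @return A [trace_set][new_trace_set()] tibble; `time_min` is
#'   `(frame - 1) * cycle_time`.
#' @export
extract_traces <- function(stack, trajectories, params = segmentation_params()) {
  if (!identical(dim(stack$nluc), dim(stack$fluc))) {
    abort("Nluc and Fluc stacks must share dimensions and frame count.")
  }
  traj <- as_tibble(trajectories)
  if (nrow(traj) == 0) {
    return(new_trace_set(tibble(cell_id = integer(), time_min = numeric(),
                                nluc_nuc = numeric(), nluc_cyt = numeric(),
                                fluc = numeric()),
                         stim_time = stack$stim_time))
  }
  dims <- dim(stack$nluc)[1:2]
  cycle <- stack$cycle_time %||% 5
  nuc_off <- disc_offsets(params$nucleus_radius)
  ann_off <- ring_offsets(params$nucleus_radius + params$annulus_gap,
                          params$nucleus_radius + params$annulus_gap +
                            params$annulus_width)
  clipped <- FALSE

  rows <- purrr::map(sort(unique(traj$frame)), function(f) {
    cells <- traj[traj$frame == f, ]
    nluc <- stack$nluc[, , f]
    fluc <- stack$fluc[, , f]
    px <- assign_pixels(cells, nuc_off, ann_off, dims)
    bg_mask <- px$owner_nuc == 0 & px$owner_ann == 0
    prob <- params$background_percentile / 100
    bg_n <- quantile(nluc[bg_mask], prob, names = FALSE)
    bg_f <- quantile(fluc[bg_mask], prob, names = FALSE)
    purrr::map(seq_len(nrow(cells)), function(ci) {
      nuc_idx <- which(px$owner_nuc == ci)
      ann_idx <- which(px$owner_ann == ci)
      if (length(ann_idx) == 0 || length(nuc_idx) == 0) {
        return(tibble(cell_id = cells$cell_id[ci],
                      time_min = (f - 1) * cycle,
                      nluc_nuc = NA_real_, nluc_cyt = NA_real_,
                      fluc = NA_real_))
      }
      vals <- c(
        nluc_nuc = mean(nluc[nuc_idx]) - bg_n,
        nluc_cyt = mean(nluc[ann_idx]) - bg_n,
        fluc = mean(fluc[c(nuc_idx, ann_idx)]) - bg_f
      )
      if (any(vals < 0)) {
        clipped <<- TRUE
        vals <- pmax(vals, 0)
      }
      tibble(cell_id = cells$cell_id[ci], time_min = (f - 1) * cycle,
             nluc_nuc = vals[["nluc_nuc"]], nluc_cyt = vals[["nluc_cyt"]],
             fluc = vals[["fluc"]])
    }) |> purrr::list_rbind()
  })
  if (clipped) warn("negative background-subtracted intensities clipped to 0.")
  traces <- purrr::list_rbind(rows) |>
    dplyr::arrange(.data$cell_id, .data$time_min)
  ## missing frames (unquantifiable cells) are dropped cell-wise only if a
  ## cell lacks the full grid; keep cells present at every frame
  full <- dplyr::add_count(traces, .data$cell_id)
  nt <- dplyr::n_distinct(traces$time_min)
  traces <- dplyr::filter(full, .data$n == nt, !is.na(.data$nluc_nuc))
  traces <- dplyr::select(traces, -"n")
  new_trace_set(traces, stim_time = stack$stim_time)
}

## per-frame pixel ownership: nuclear discs win outright; annulus pixels go
## to the nearest claiming centroid and never overlap any nucleus
assign_pixels <- function(cells, nuc_off, ann_off, dims) {
  owner_nuc <- matrix(0L, dims[1], dims[2])
  owner_ann <- matrix(0L, dims[1], dims[2])
  ann_dist <- matrix(Inf, dims[1], dims[2])
  for (ci in seq_len(nrow(cells))) {
    cy <- round(cells$y[ci])
    cx <- round(cells$x[ci])
    ny <- nuc_off$dy + cy
    nx <- nuc_off$dx + cx
    ok <- ny >= 1 & ny <= dims[1] & nx >= 1 & nx <= dims[2]
    owner_nuc[cbind(ny[ok], nx[ok])] <- ci
  }
  for (ci in seq_len(nrow(cells))) {
    cy <- round(cells$y[ci])
    cx <- round(cells$x[ci])
    ay <- ann_off$dy + cy
    ax <- ann_off$dx + cx
    ok <- ay >= 1 & ay <= dims[1] & ax >= 1 & ax <= dims[2]
    idx <- cbind(ay[ok], ax[ok])
    d <- sqrt((ay[ok] - cells$y[ci])^2 + (ax[ok] - cells$x[ci])^2)
    closer <- d < ann_dist[idx]
    idx <- idx[closer, , drop = FALSE]
    owner_ann[idx] <- ci
    ann_dist[idx] <- d[closer]
  }
  owner_ann[owner_nuc > 0] <- 0L
  list(owner_nuc = owner_nuc, owner_ann = owner_ann)
}

#' Correct Nluc-to-Fluc channel cross-talk
#'
#' Subtracts the bleed-through of the Nluc emission from the raw Fluc
#' channel: `fluc_corrected = fluc_raw - coeff * nluc_total`, the exact
#' algebraic inverse of [apply_crosstalk()]. Negative corrected values are
#' clipped to zero with a warning.
#'
#' @param fluc_raw raw Fluc series.
#' @param nluc_total total (nuclear + cytoplasmic) Nluc series, same
#'   length.
#' @param coeff bleed-through fraction (default 1.5%).
#' @param quiet suppress the clipping warning.
#' @return Corrected Fluc vector.
#' @export
#' @examples
#' crosstalk_correct(rep(15, 3), rep(1000, 3), 0.015)  # 0 0 0
crosstalk_correct <- function(fluc_raw, nluc_total, coeff = 0.015,
                              quiet = FALSE) {
  if (length(fluc_raw) != length(nluc_total)) {
    abort("`fluc_raw` and `nluc_total` must have equal length.")
  }
  out <- fluc_raw - coeff * nluc_total
  neg <- !is.na(out) & out < 0
  if (any(neg)) {
    if (!quiet) warn("negative cross-talk-corrected values clipped to 0.")
    out[neg] <- 0
  }
  out
}
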
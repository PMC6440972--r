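#' Render a trace cohort as a two-channel synthetic movie
#'
#' Draws every cell as a bright nuclear disc (Nluc nuclear value) with a
#' dimmer cytoplasmic surround (Nluc cytoplasmic value) in the Nluc
#' channel, and as a uniform disc at the cell's Fluc value in the Fluc
#' channel, on a constant background, one frame per timepoint. Cells
#' undergo small reflected random walks; overlapping luminescence adds.
#' Optional Poisson shot noise is applied per pixel. Ground-truth positions
#' are recorded per frame. Purely synthetic plumbing: a stand-in for real
#' luminescence acquisitions with known truth.
#'
#' Initial positions are integer-rounded and rejected below a
#' centre-to-centre distance of `2 * r_cell + 2` px; if a valid layout
#' cannot be found the function errors advising a larger frame.
#'
#' @param trace_set a [simulate_cohort()] result.
#' @param frame_size `c(rows, cols)` in pixels.
#' @param r_nuc,r_cell nuclear and whole-cell radii, pixels; the cytoplasm
#'   occupies the band between them and must be at least
#'   `annulus_gap + annulus_width` wide for downstream quantification.
#' @param motion_sd per-frame random-walk step SD, pixels.
#' @param background constant background level added to both channels.
#' @param shot_noise logical; apply Poisson noise per pixel.
#' @param pixel_size microns per pixel (metadata only).
#' @param seed seed for placement, motion and shot noise.
#' @return A `movie_stack`: list with `nluc` and `fluc` arrays
#'   `[row, col, frame]`, `truth` tibble (`frame, cell_id, x, y, r_nuc`),
#'   `cycle_time`, `stim_time`, `pixel_size` and `geometry`.
#' @export
render_movie <- function(trace_set, frame_size = c(160, 160), r_nuc = 6,
                         r_cell = 14, motion_sd = 0.3, background = 10,
                         shot_noise = TRUE, pixel_size = 1, seed = 1L) {
  df <- as_tibble(trace_set)
  ids <- unique(df$cell_id)
  n <- length(ids)
  tt <- sort(unique(df$time_min))
  nf <- length(tt)
  cfg <- trace_config(trace_set)
  if (!is.null(cfg) && nf != cfg$duration / cfg$cycle_time + 1) {
    abort("frame count must equal duration / cycle_time + 1.")
  }
  set.seed(seed)

  lo <- r_cell + 2
  hi_y <- frame_size[1] - r_cell - 1
  hi_x <- frame_size[2] - r_cell - 1
  if (hi_y <= lo || hi_x <= lo) abort("frame too small for the cell radius.")
  pos <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(200)) {
      p <- c(round(runif(1, lo, hi_y)), round(runif(1, lo, hi_x)))
      if (i == 1 || all(sqrt(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                                        matrix(p, i - 1, 2, byrow = TRUE))^2)) >
                          2 * r_cell + 2)) {
        pos[i, ] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort("could not place cells without overlap; use a larger frame or fewer cells.")
    }
  }

  ## reflected random walks, one (y, x) path per cell
  paths <- array(NA_real_, c(n, nf, 2))
  paths[, 1, ] <- pos
  if (nf > 1) {
    for (f in 2:nf) {
      step <- matrix(stats::rnorm(2 * n, 0, motion_sd), n, 2)
      p <- paths[, f - 1, ] + step
      p[, 1] <- reflect_into(p[, 1], lo, hi_y)
      p[, 2] <- reflect_into(p[, 2], lo, hi_x)
      paths[, f, ] <- p
    }
  }

  wide <- function(col) {
    m <- tidyr::pivot_wider(df[, c("cell_id", "time_min", col)],
                            names_from = "time_min",
                            values_from = dplyr::all_of(col))
    as.matrix(m[match(ids, m$cell_id), -1])
  }
  v_nuc <- wide("nluc_nuc")
  v_cyt <- wide("nluc_cyt")
  v_fluc <- wide("fluc")

  nuc_off <- disc_offsets(r_nuc)
  cyt_off <- ring_offsets(r_nuc, r_cell)
  cell_off <- disc_offsets(r_cell)
  nluc <- array(background, c(frame_size[1], frame_size[2], nf))
  fluc <- array(background, c(frame_size[1], frame_size[2], nf))
  add_px <- function(img, off, cy, cx, value) {
    yy <- off$dy + cy
    xx <- off$dx + cx
    ok <- yy >= 1 & yy <= frame_size[1] & xx >= 1 & xx <= frame_size[2]
    idx <- cbind(yy[ok], xx[ok])
    img[idx] <- img[idx] + value
    img
  }
  for (f in seq_len(nf)) {
    fn <- nluc[, , f]
    ff <- fluc[, , f]
    for (i in seq_len(n)) {
      cy <- round(paths[i, f, 1])
      cx <- round(paths[i, f, 2])
      fn <- add_px(fn, nuc_off, cy, cx, v_nuc[i, f])
      fn <- add_px(fn, cyt_off, cy, cx, v_cyt[i, f])
      ff <- add_px(ff, cell_off, cy, cx, v_fluc[i, f])
    }
    if (shot_noise) {
      fn <- matrix(rpois(length(fn), fn), nrow(fn))
      ff <- matrix(rpois(length(ff), ff), nrow(ff))
    }
    nluc[, , f] <- fn
    fluc[, , f] <- ff
  }

  truth <- purrr::map(seq_len(nf), function(f) {
    tibble(frame = f, cell_id = ids, x = paths[, f, 2], y = paths[, f, 1],
           r_nuc = r_nuc)
  }) |> purrr::list_rbind()

  structure(
    list(nluc = nluc, fluc = fluc, truth = truth,
         cycle_time = if (nf > 1) tt[2] - tt[1] else 5,
         stim_time = attr(trace_set, "stim_time"),
         pixel_size = pixel_size,
         geometry = list(frame_size = frame_size, r_nuc = r_nuc,
                         r_cell = r_cell, motion_sd = motion_sd,
                         background = background)),
    class = "movie_stack"
  )
}

reflect_into <- function(x, lo, hi) {
  x <- ifelse(x < lo, 2 * lo - x, x)
  ifelse(x > hi, 2 * hi - x, x)
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$nluc)
  cat(sprintf("<movie_stack> %dx%d px, %d frames, %d cells\n",
              d[1], d[2], d[3], dplyr::n_distinct(x$truth$cell_id)))
  invisible(x)
}

#' Write / read a two-channel movie as multi-page TIFF
#'
#' One 16-bit multi-page TIFF per channel (`nluc.tif`, `fluc.tif`; frame
#' index = time index) plus ground truth, when present, as
#' `truth.csv` (`frame,cell_id,x,y,r_nuc`). Intensities are rounded to
#' integers on write.
#'
#' @param stack a `movie_stack`.
#' @param dir output directory (created if needed).
#' @param cycle_time,stim_time acquisition metadata for a stack read back
#'   from plain TIFFs.
#' @return `write_movie_stack()` returns `dir` invisibly;
#'   `read_movie_stack()` a `movie_stack`.
#' @export
write_movie_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in c("nluc", "fluc")) {
    frames <- lapply(seq_len(dim(stack[[ch]])[3]), function(f) {
      pmin(pmax(round(stack[[ch]][, , f]), 0), 65535) / 65535
    })
    tiff::writeTIFF(frames, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 16)
  }
  if (!is.null(stack$truth)) {
    readr::write_csv(stack$truth, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}

#' @rdname write_movie_stack
#' @export
read_movie_stack <- function(dir, cycle_time = 5, stim_time = 180) {
  read_ch <- function(name) {
    frames <- tiff::readTIFF(file.path(dir, paste0(name, ".tif")), all = TRUE)
    simplify2array(lapply(frames, function(m) round(m * 65535)))
  }
  truth_path <- file.path(dir, "truth.csv")
  structure(
    list(nluc = read_ch("nluc"), fluc = read_ch("fluc"),
         truth = if (file.exists(truth_path)) {
           readr::read_csv(truth_path, show_col_types = FALSE)
         },
         cycle_time = cycle_time, stim_time = stim_time,
         pixel_size = 1, geometry = NULL),
    class = "movie_stack"
  )
}
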
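#' Segmentation parameters
#'
#' Tunables of the movie-analysis stages: the radii of the cell-like
#' matched-filter bank, the adaptive-threshold block, the size filter, the
#' cytoplasmic annulus geometry, the nuclear-disc radius used for
#' quantification and the background percentile.
#'
#' @param filter_radii pixel radii of the blob-enhancing filter bank.
#' @param adaptive_block side (pixels, odd) of the local-mean window for
#'   adaptive thresholding.
#' @param offset_frac threshold offset as a fraction of the maximum filter
#'   response, so segmentation is invariant to global intensity scaling.
#' @param min_area smallest component kept, pixels.
#' @param annulus_gap,annulus_width gap between nucleus and annulus, and
#'   annulus thickness, pixels.
#' @param nucleus_radius radius (pixels) of the nuclear disc quantified
#'   around each detection centroid.
#' @param background_percentile percentile of off-cell pixels used as the
#'   per-frame background estimate.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(filter_radii = c(6, 10, 14),
                                adaptive_block = 51,
                                offset_frac = 0.1,
                                min_area = 30,
                                annulus_gap = 2,
                                annulus_width = 5,
                                nucleus_radius = 6,
                                background_percentile = 50) {
  if (any(filter_radii <= 0)) abort("`filter_radii` must be positive.")
  if (annulus_width < 1) abort("`annulus_width` must be >= 1.")
  if (background_percentile < 0 || background_percentile > 100) {
    abort("`background_percentile` must lie in [0, 100].")
  }
  structure(
    list(filter_radii = filter_radii, adaptive_block = adaptive_block,
         offset_frac = offset_frac, min_area = min_area,
         annulus_gap = annulus_gap, annulus_width = annulus_width,
         nucleus_radius = nucleus_radius,
         background_percentile = background_percentile),
    class = "segmentation_params"
  )
}

## exact euclidean disc offsets (dx, dy) with dx^2 + dy^2 <= r^2
disc_offsets <- function(r) {
  r <- ceiling(r)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

ring_offsets <- function(r_in, r_out) {
  r <- ceiling(r_out)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- g$dx^2 + g$dy^2
  g[d2 > r_in^2 & d2 <= r_out^2, , drop = FALSE]
}

## center-surround matched filter: normalized disc minus normalized ring,
## zero response on flat background
matched_kernel <- function(r) {
  size <- 2 * ceiling(2 * r) + 1
  c0 <- ceiling(2 * r) + 1
  d2 <- outer(seq_len(size) - c0, seq_len(size) - c0,
              function(i, j) i^2 + j^2)
  disc <- d2 <= r^2
  ring <- d2 > r^2 & d2 <= (2 * r)^2
  disc / sum(disc) - ring / sum(ring)
}

local_mean <- function(img, block) {
  block <- 2 * (block %/% 2) + 1  # force odd
  k <- matrix(1 / block^2, block, block)
  as.matrix(EBImage::filter2(img, k, boundary = "replicate"))
}

#' Segment cell-like blobs in one frame
#'
#' Convolves the frame with a bank of center-surround disc-matched filters
#' at `params$filter_radii`, takes the per-pixel maximum response, binarizes
#' with a local adaptive threshold (local mean over `adaptive_block` windows
#' plus an offset proportional to the maximum response), labels connected
#' components and drops those below `min_area`. Masks are disjoint by
#' construction.
#'
#' @param image 2-D non-negative numeric matrix.
#' @param params a [segmentation_params()].
#' @return A list with `labels` (integer matrix, 0 = background) and
#'   `cells`, a tibble `det, x, y, area` of centroids (pixel units, x =
#'   column, y = row). A blank frame yields zero detections.
#' @export
segment_frame <- function(image, params = segmentation_params()) {
  image <- as.matrix(image)
  if (any(image < 0)) abort("`image` must be non-negative.")
  empty <- list(labels = matrix(0L, nrow(image), ncol(image)),
                cells = tibble(det = integer(), x = numeric(),
                               y = numeric(), area = integer()))
  if (length(image) == 0 || max(image) == 0) return(empty)
  resp <- NULL
  for (r in params$filter_radii) {
    one <- as.matrix(EBImage::filter2(image, matched_kernel(r),
                                      boundary = "replicate"))
    resp <- if (is.null(resp)) one else pmax(resp, one)
  }
  ## a flat frame leaves only FFT residue in the matched-filter response
  if (max(resp) <= 1e-9 * max(image)) return(empty)
  thr <- local_mean(resp, params$adaptive_block) +
    params$offset_frac * max(resp)
  bw <- resp > thr
  lab <- EBImage::bwlabel(bw)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params$min_area)
  if (length(keep) == 0) return(empty)
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  labels <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  labels[nz] <- relab[lab[nz]]
  idx <- which(labels > 0, arr.ind = TRUE)
  cells <- tibble(
    det = labels[labels > 0],
    y = idx[, 1], x = idx[, 2]
  ) |>
    dplyr::group_by(.data$det) |>
    dplyr::summarize(x = mean(.data$x), y = mean(.data$y),
                     area = dplyr::n(), .groups = "drop") |>
    dplyr::select("det", "x", "y", "area")
  list(labels = labels, cells = cells)
}

#' Cytoplasmic annulus around a nuclear mask
#'
#' Morphological band: `dilate(mask, gap + width)` minus
#' `dilate(mask, gap)`, clipped to the frame, minus pixels claimed by
#' neighbouring nuclei or their annuli (contested pixels go to the nearest
#' nucleus centroid).
#'
#' @param nuclear_mask logical matrix.
#' @param gap,width gap and thickness of the band, pixels.
#' @param neighbor_masks list of logical matrices of neighbouring nuclei.
#' @return Logical matrix; all-`FALSE` (with a warning) when the annulus is
#'   empty after clipping, in which case the cell is unquantifiable for the
#'   frame.
#' @export
make_annulus <- function(nuclear_mask, gap = 2, width = 5,
                         neighbor_masks = list()) {
  band <- annulus_band(nuclear_mask, gap, width)
  if (length(neighbor_masks) > 0) {
    ctr <- mask_centroid(nuclear_mask)
    for (nb in neighbor_masks) {
      band <- band & !nb
      nb_band <- annulus_band(nb, gap, width)
      contested <- band & nb_band
      if (any(contested)) {
        nb_ctr <- mask_centroid(nb)
        idx <- which(contested, arr.ind = TRUE)
        d_own <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
        d_nb <- (idx[, 1] - nb_ctr[1])^2 + (idx[, 2] - nb_ctr[2])^2
        lose <- d_nb < d_own
        band[idx[lose, , drop = FALSE]] <- FALSE
      }
    }
  }
  if (!any(band)) {
    warn("annulus empty after clipping; cell unquantifiable for this frame.")
  }
  band
}

annulus_band <- function(mask, gap, width) {
  mask <- mask != 0
  outer_m <- EBImage::dilate(mask, EBImage::makeBrush(2 * (gap + width) + 1,
                                                      "disc")) != 0
  inner_m <- if (gap > 0) {
    EBImage::dilate(mask, EBImage::makeBrush(2 * gap + 1, "disc")) != 0
  } else {
    mask
  }
  outer_m & !inner_m
}

mask_centroid <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))  # (row, col)
}
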
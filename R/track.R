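#' Linking parameters for cell tracking
#'
#' @param max_link_dist maximum frame-to-frame link distance, pixels.
#' @param max_gap maximum number of consecutive missed frames closed by
#'   gap closing.
#' @param min_track_len tracks shorter than this (frames) are discarded
#'   *before* gap closing, so spurious detections are never linked into a
#'   real trajectory.
#' @return A list of class `linking_params`.
#' @export
linking_params <- function(max_link_dist = 15, max_gap = 2,
                           min_track_len = 3) {
  if (max_link_dist < 0 || max_gap < 0 || min_track_len < 0) {
    abort("linking parameters must be >= 0.")
  }
  structure(list(max_link_dist = max_link_dist, max_gap = max_gap,
                 min_track_len = min_track_len),
            class = "linking_params")
}

#' Segment every frame of a movie channel
#'
#' @param stack a [render_movie()] result (or any `movie_stack`).
#' @param params a [segmentation_params()].
#' @param channel channel to segment (detection runs on the Nluc channel).
#' @return A list with `detections` (tibble `frame, det, x, y, area`) and
#'   `labels` (list of per-frame label matrices).
#' @export
segment_movie <- function(stack, params = segmentation_params(),
                          channel = "nluc") {
  frames <- dim(stack[[channel]])[3]
  segs <- purrr::map(seq_len(frames), function(f) {
    segment_frame(stack[[channel]][, , f], params)
  })
  detections <- purrr::imap(segs, function(s, f) {
    dplyr::mutate(s$cells, frame = f, .before = 1)
  }) |> purrr::list_rbind()
  list(detections = detections, labels = purrr::map(segs, "labels"))
}

#' Link detections into cell trajectories
#'
#' Frame-to-frame linking by minimum-distance assignment (exact
#' assignment solve when detection counts or nearest neighbours conflict)
#' under `max_link_dist`; tracks shorter than `min_track_len` are discarded;
#' remaining track ends are then joined to track starts across gaps of up to
#' `max_gap` frames (greedy nearest pairs, allowance scaled by the gap
#' length), with positions linearly interpolated and flagged at gap frames.
#' Unlinked detections start new tracks, so the number of (trajectory,
#' frame) assignments never exceeds the number of detections.
#'
#' @param detections tibble `frame, det, x, y, area` (see
#'   [segment_movie()]); frames are consecutive integers starting at 1.
#' @param params a [linking_params()].
#' @return A tibble `cell_id, frame, x, y, area, det, gap_flag`, one row
#'   per trajectory frame; `det` is `NA` on interpolated gap frames.
#' @export
track <- function(detections, params = linking_params()) {
  det <- as_tibble(detections)
  if (nrow(det) == 0) {
    return(tibble(cell_id = integer(), frame = integer(), x = numeric(),
                  y = numeric(), area = numeric(), det = integer(),
                  gap_flag = logical()))
  }
  det$row <- seq_len(nrow(det))
  frames <- sort(unique(det$frame))
  by_frame <- split(det, det$frame)
  succ <- rep(NA_integer_, nrow(det))
  for (i in seq_len(length(frames) - 1)) {
    a <- by_frame[[as.character(frames[i])]]
    b <- by_frame[[as.character(frames[i + 1])]]
    if (frames[i + 1] != frames[i] + 1) next
    if (nrow(a) == 0 || nrow(b) == 0) next
    cost <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(p, q) {
      sqrt((a$x[p] - b$x[q])^2 + (a$y[p] - b$y[q])^2)
    })
    cost[cost > params$max_link_dist] <- Inf
    match <- solve_assignment_capped(cost, params$max_link_dist)
    ok <- !is.na(match)
    succ[a$row[ok]] <- b$row[match[ok]]
  }

  ## build tracks by following successor pointers
  has_pred <- rep(FALSE, nrow(det))
  has_pred[succ[!is.na(succ)]] <- TRUE
  tracks <- list()
  for (start in det$row[!has_pred]) {
    path <- start
    while (!is.na(succ[path[length(path)]])) {
      path <- c(path, succ[path[length(path)]])
    }
    tracks[[length(tracks) + 1]] <- path
  }
  tracks <- tracks[lengths(tracks) >= params$min_track_len]
  if (length(tracks) == 0) {
    return(tibble(cell_id = integer(), frame = integer(), x = numeric(),
                  y = numeric(), area = numeric(), det = integer(),
                  gap_flag = logical()))
  }

  seg <- purrr::imap(tracks, function(rows, id) {
    d <- det[rows, ]
    tibble(track = id, frame = d$frame, x = d$x, y = d$y, area = d$area,
           det = d$det, gap_flag = FALSE)
  })

  ## gap closing: join ends to starts across <= max_gap missing frames
  repeat {
    ends <- purrr::map(seg, ~ .x[nrow(.x), ])
    starts <- purrr::map(seg, ~ .x[1, ])
    cand <- NULL
    for (i in seq_along(seg)) {
      for (j in seq_along(seg)) {
        if (i == j) next
        g <- starts[[j]]$frame - ends[[i]]$frame - 1
        if (g < 1 || g > params$max_gap) next
        d <- sqrt((ends[[i]]$x - starts[[j]]$x)^2 +
                    (ends[[i]]$y - starts[[j]]$y)^2)
        if (d > params$max_link_dist * (g + 1)) next
        cand <- rbind(cand, data.frame(i = i, j = j, d = d))
      }
    }
    if (is.null(cand) || nrow(cand) == 0) break
    best <- cand[which.min(cand$d), ]
    a <- seg[[best$i]]
    b <- seg[[best$j]]
    gap_frames <- (a$frame[nrow(a)] + 1):(b$frame[1] - 1)
    interp <- tibble(
      track = a$track[1], frame = gap_frames,
      x = approx(c(a$frame[nrow(a)], b$frame[1]),
                 c(a$x[nrow(a)], b$x[1]), xout = gap_frames)$y,
      y = approx(c(a$frame[nrow(a)], b$frame[1]),
                 c(a$y[nrow(a)], b$y[1]), xout = gap_frames)$y,
      area = approx(c(a$frame[nrow(a)], b$frame[1]),
                    c(a$area[nrow(a)], b$area[1]), xout = gap_frames)$y,
      det = NA_integer_, gap_flag = TRUE
    )
    b$track <- a$track[1]
    seg[[best$i]] <- dplyr::bind_rows(a, interp, b)
    seg[[best$j]] <- NULL
  }

  out <- purrr::imap(seg, function(s, id) {
    s$track <- id
    s
  }) |> purrr::list_rbind()
  dplyr::transmute(out, cell_id = .data$track, frame = .data$frame,
                   x = .data$x, y = .data$y, area = .data$area,
                   det = .data$det, gap_flag = .data$gap_flag) |>
    dplyr::arrange(.data$cell_id, .data$frame)
}
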
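test_that("the assignment solver matches brute force on random costs", {
  set.seed(41)
  for (n in 2:5) {
    for (rep in 1:5) {
      cost <- matrix(runif(n * n, 0, 10), n)
      a <- solve_assignment(cost)
      expect_equal(sum(cost[cbind(seq_len(n), a)]),
                   brute_assignment_cost(cost), tolerance = 1e-9)
    }
  }
  # rectangular: every row of the smaller side is matched
  cost <- matrix(runif(12), 3, 4)
  a <- solve_assignment(cost)
  expect_equal(sort(unique(a[a > 0])), a[a > 0][order(a[a > 0])])
})

test_that("segmentation finds rendered cells and ignores blank frames", {
  params <- segmentation_params()
  blank <- matrix(5, 100, 100)
  expect_equal(nrow(segment_frame(blank, params)$cells), 0)
  expect_equal(nrow(segment_frame(matrix(0, 50, 50), params)$cells), 0)

  mv <- small_movie(n_cells = 1, noise_cv = 0, shot_noise = FALSE,
                    motion_sd = 0)
  seg <- segment_frame(mv$nluc[, , 1], params)
  expect_equal(nrow(seg$cells), 1)
  truth1 <- mv$truth[mv$truth$frame == 1, ]
  expect_lt(sqrt((seg$cells$x - truth1$x)^2 + (seg$cells$y - truth1$y)^2), 1)

  mv2 <- small_movie(n_cells = 2, noise_cv = 0, shot_noise = FALSE,
                     motion_sd = 0, frame_size = c(200, 200))
  expect_equal(nrow(segment_frame(mv2$nluc[, , 1], params)$cells), 2)
})

test_that("segmentation is equivariant to integer translation and scaling", {
  mv <- small_movie(n_cells = 1, noise_cv = 0, shot_noise = FALSE,
                    motion_sd = 0)
  img <- mv$nluc[, , 1]
  params <- segmentation_params()
  base <- segment_frame(img, params)$cells
  shifted <- matrix(min(img), nrow(img), ncol(img))
  shifted[7:nrow(img), 4:ncol(img)] <- img[1:(nrow(img) - 6), 1:(ncol(img) - 3)]
  sh <- segment_frame(shifted, params)$cells
  expect_equal(sh$y, base$y + 6, tolerance = 1e-6)
  expect_equal(sh$x, base$x + 3, tolerance = 1e-6)
  sc <- segment_frame(img * 7.5, params)$cells
  expect_equal(sc[c("x", "y", "area")], base[c("x", "y", "area")])
})

test_that("annulus morphology identities hold", {
  m <- matrix(FALSE, 40, 40)
  off <- smadtrace:::disc_offsets(5)
  m[cbind(20 + off$dy, 20 + off$dx)] <- TRUE
  ann <- make_annulus(m, gap = 0, width = 3)
  dil <- EBImage::dilate(m, EBImage::makeBrush(7, "disc")) != 0
  expect_equal(ann, dil & !m)
  expect_false(any(ann & m))

  # two nearby cells: annuli never overlap each other or either nucleus
  m2 <- matrix(FALSE, 40, 40)
  m2[cbind(20 + off$dy, 31 + off$dx)] <- TRUE
  a1 <- make_annulus(m, gap = 2, width = 5, neighbor_masks = list(m2))
  a2 <- make_annulus(m2, gap = 2, width = 5, neighbor_masks = list(m))
  expect_false(any(a1 & a2))
  expect_false(any(a1 & m2))
  expect_false(any(a2 & m))
})

test_that("tracking follows static cells and closes single-frame gaps", {
  det <- data.frame(frame = 1:10, det = 1, x = 50, y = 50, area = 100)
  trj <- track(det, linking_params())
  expect_equal(nrow(trj), 10)
  expect_equal(unique(trj$cell_id), 1)

  det_gap <- det[-5, ]
  trj2 <- track(det_gap, linking_params(max_gap = 2))
  expect_equal(nrow(trj2), 10)
  expect_equal(sum(trj2$gap_flag), 1)
  expect_equal(trj2$frame[trj2$gap_flag], 5)
  expect_equal(trj2$x[trj2$gap_flag], 50)

  # assignments never exceed detections
  set.seed(42)
  det3 <- do.call(rbind, lapply(1:6, function(f) {
    data.frame(frame = f, det = 1:3, x = c(10, 40, 70) + rnorm(3),
               y = c(10, 40, 70) + rnorm(3), area = 50)
  }))
  trj3 <- track(det3, linking_params())
  expect_lte(sum(!trj3$gap_flag), nrow(det3))
  expect_equal(dplyr::n_distinct(trj3$cell_id), 3)
})

test_that("noise-free rendered movies round-trip through the full pipeline", {
  mv <- small_movie(n_cells = 4, noise_cv = 0, shot_noise = FALSE,
                    motion_sd = 0, frame_size = c(220, 220))
  params <- segmentation_params()
  seg <- segment_movie(mv, params)
  trj <- track(seg$detections, linking_params())
  expect_equal(dplyr::n_distinct(trj$cell_id), 4)
  ts <- extract_traces(mv, trj, params)
  expect_equal(dplyr::n_distinct(ts$cell_id), 4)

  truth_ts <- simulate_cohort(short_config(n_cells = 4, noise_cv = 0, seed = 1))
  # match extracted tracks to ground-truth cells by position at frame 1
  t1 <- mv$truth[mv$truth$frame == 1, ]
  link <- trj[trj$frame == 1, ]
  map <- vapply(seq_len(nrow(link)), function(i) {
    t1$cell_id[which.min((t1$x - link$x[i])^2 + (t1$y - link$y[i])^2)]
  }, numeric(1))
  for (i in seq_len(nrow(link))) {
    got <- ts[ts$cell_id == link$cell_id[i], ]
    want <- truth_ts[truth_ts$cell_id == map[i], ]
    expect_equal(got$nluc_nuc, want$nluc_nuc, tolerance = 0.01)
    expect_equal(got$nluc_cyt, want$nluc_cyt, tolerance = 0.01)
    expect_equal(got$fluc, want$fluc, tolerance = 0.01)
  }
})

test_that("extracted traces scale linearly and N/C ratios are scale-free", {
  mv <- small_movie(n_cells = 2, noise_cv = 0, shot_noise = FALSE,
                    motion_sd = 0)
  params <- segmentation_params()
  seg <- segment_movie(mv, params)
  trj <- track(seg$detections, linking_params())
  ts1 <- extract_traces(mv, trj, params)
  mv3 <- mv
  mv3$nluc <- mv$nluc * 3
  mv3$fluc <- mv$fluc * 3
  ts3 <- extract_traces(mv3, trj, params)
  expect_equal(ts3$nluc_nuc, 3 * ts1$nluc_nuc, tolerance = 1e-9)
  expect_equal(ts3$nluc_nuc / ts3$nluc_cyt, ts1$nluc_nuc / ts1$nluc_cyt,
               tolerance = 1e-9)
})

test_that("empty trajectories give an empty trace set", {
  mv <- small_movie(n_cells = 1, motion_sd = 0)
  empty <- track(data.frame(frame = integer(), det = integer(),
                            x = numeric(), y = numeric(), area = numeric()),
                 linking_params())
  ts <- extract_traces(mv, empty, segmentation_params())
  expect_equal(nrow(ts), 0)
})

test_that("movie stacks survive a TIFF round trip", {
  mv <- small_movie(n_cells = 2, motion_sd = 0.2)
  dir <- withr::local_tempdir()
  write_movie_stack(mv, dir)
  back <- read_movie_stack(dir, cycle_time = mv$cycle_time,
                           stim_time = mv$stim_time)
  expect_equal(dim(back$nluc), dim(mv$nluc))
  expect_equal(back$nluc, round(mv$nluc), tolerance = 1e-9)
  expect_equal(back$truth$x, mv$truth$x, tolerance = 1e-6)
})

test_that("overcrowded frames error with advice", {
  ts <- simulate_cohort(short_config(n_cells = 30))
  expect_error(render_movie(ts, frame_size = c(80, 80)), "larger frame")
})
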
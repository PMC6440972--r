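test_that("nc_ratio divides compartments and cancels common factors", {
  expect_equal(nc_ratio(c(2, 4, 6), c(2, 2, 2)), c(1, 2, 3))
  t <- 0:50
  nuc <- (1 + 0.5 * sin(t / 5)) * exp(-t / 30)
  cyt <- rep(1, 51) * exp(-t / 30)
  expect_equal(nc_ratio(nuc, cyt), 1 + 0.5 * sin(t / 5), tolerance = 1e-12)
  r <- nc_ratio(c(1, 1, 1), c(1, 1e-9, 1))
  expect_true(is.na(r[2]) && !anyNA(r[-2]))
})

test_that("basal_level averages the three points centered on stimulation", {
  tt <- seq(0, 100, by = 5)
  expect_equal(basal_level(rep(3, 21), tt, 50), 3)
  v <- rep(0, 21)
  v[tt %in% c(45, 50, 55)] <- c(2, 4, 6)
  expect_equal(basal_level(v, tt, 50), 4)
  expect_warning(basal_level(1:21, tt, 0), "edge")
})

test_that("detect_peak reports the smoothed argmax and 3-point mean level", {
  tt <- 0:6 * 5
  pk <- detect_peak(c(0, 0, 8, 10, 8, 0, 0), tt, stim_time = 0,
                    window = c(0, 30))
  expect_equal(pk$peak_level, 26 / 3)
  expect_equal(pk$peak_time, 15)
  expect_false(pk$censored)
  mono <- detect_peak(seq(1, 7), tt, 0, window = c(0, 30))
  expect_true(mono$censored)
})

test_that("response and fold change follow their definitions", {
  expect_equal(response_and_fold(2, 6), tibble::tibble(response = 4,
                                                       fold_change = 3))
  expect_equal(response_and_fold(5, 5)$fold_change, 1)
  expect_true(is.na(response_and_fold(0, 5)$fold_change))
  expect_equal(response_and_fold(0, 5)$response, 5)
})

test_that("initiation and return run rules handle flat, step and pulse traces", {
  tt <- 0:40 * 5
  flat <- rep(10, 41)
  expect_true(is.na(detect_initiation(flat, tt, 50, 10, 0.5)))
  step <- c(rep(10, 21), rep(100, 20))
  expect_equal(detect_initiation(step, tt, 50, 10, 0.5), 105 - 50)
  expect_true(is.na(detect_return(flat, tt, 50, 10, basal = 10,
                                  basal_sd = 0.5)))
})

test_that("cohort_stats computes mean, sample SD and CV over defined values", {
  s <- cohort_stats(data.frame(a = c(1, 1, 1), b = c(1, 3, NA)), c("a", "b"))
  expect_equal(s$cv[1], 0)
  expect_equal(s$mean[2], 2)
  expect_equal(s$sd[2], sqrt(2))
  expect_equal(s$cv[2], sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(s$n, c(3L, 2L))
})

test_that("trace normalization modes rescale and are idempotent", {
  expect_equal(normalize_trace(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(normalize_trace(c(2, 4, 6), "minmax"), c(0, 0.5, 1))
  x <- runif(20, 2, 9)
  expect_equal(normalize_trace(normalize_trace(x)), normalize_trace(x))
  expect_error(normalize_trace(c(-2, -1)), "positive maximum")
  expect_warning(z <- normalize_trace(rep(4, 5), "minmax"), "constant")
  expect_equal(z, rep(0, 5))
})

test_that("noise-free cohort features recover generator truth", {
  cfg <- sim_config(n_cells = 25, noise_cv = 0, seed = 21)
  ts <- simulate_cohort(cfg)
  f <- quantify_cohort(ts)
  m <- dplyr::inner_join(f, trace_truth(ts), by = "cell_id")
  expect_true(all(abs(m$smad_peak_time - m$true_peak_min) <= cfg$cycle_time))
  ## the 3-point peak average slightly underestimates pulses whose peak time
  ## is within a few cycles of stimulation; elsewhere recovery is exact
  rel <- abs(m$nc_response - m$true_amplitude) / m$true_amplitude
  expect_lt(median(rel), 0.01)
  expect_true(all(rel[m$true_peak_min >= 4 * cfg$cycle_time] < 0.05))
  expect_true(all(abs(m$basal_nc - 1) < 1e-9))
  expect_true(all(abs(m$ctgf_basal - m$true_basal) < 1e-6))
  # initiation is grid-quantized upward from the true onset
  expect_true(all(m$ctgf_init_time - m$true_init_min >= 0))
  expect_true(all(m$ctgf_init_time - m$true_init_min <= cfg$cycle_time))
  tr <- m[m$phenotype == "transient", ]
  expect_true(all(abs(tr$return_time - 480) <= cfg$cycle_time))
  sus <- m[m$phenotype == "sustained", ]
  expect_true(all(is.na(sus$return_time) | sus$return_time > 480))
})

test_that("features are invariant under common rescaling of both channels", {
  ts <- simulate_cohort(sim_config(n_cells = 6, seed = 22))
  scaled <- dplyr::mutate(tibble::as_tibble(ts),
                          nluc_nuc = nluc_nuc * 3, nluc_cyt = nluc_cyt * 3,
                          fluc = fluc * 3)
  scaled <- new_trace_set(scaled, stim_time = 180)
  f1 <- quantify_cohort(ts)
  f2 <- quantify_cohort(scaled)
  ratio_cols <- c("basal_nc", "peak_nc", "nc_response", "nc_fold_change",
                  "smad_peak_time", "ctgf_init_time", "return_time")
  expect_equal(f1[ratio_cols], f2[ratio_cols], tolerance = 1e-9)
  expect_equal(f2$ctgf_response, 3 * f1$ctgf_response, tolerance = 1e-9)
  expect_equal(f2$mean_smad_level, 3 * f1$mean_smad_level, tolerance = 1e-9)
})

test_that("feature cohort means converge to the generative means with n", {
  errs <- vapply(c(100, 1000), function(n) {
    tr <- trace_truth(simulate_cohort(sim_config(n_cells = n, seed = 33)))
    abs(mean(tr$true_peak_min) - 55)
  }, numeric(1))
  se <- 55 * 0.33 / sqrt(c(100, 1000))
  expect_true(all(errs < 3 * se))
})
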
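test_that("no-response limit keeps the N/C ratio at baseline", {
  cfg <- sim_config(noise_cv = 0, substrate_halflife = Inf,
                    nc_amplitude_mean = 0, seed = 3)
  tr <- sample_smad_trace(cfg, cell = 1)
  expect_equal(tr$nluc_nuc / tr$nluc_cyt, rep(1, length(tr$time_min)))
})

test_that("translocation peak times follow the configured gamma law", {
  # SMAD4 defaults: mean 55 min, CV 0.33
  set.seed(99)
  draws <- smadtrace:::rgamma_mean_cv(10000, 55, 0.33)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 55), 2 * se)
  expect_lt(abs(sd(draws) / mean(draws) - 0.33), 0.01)
  # cohort truth carries the same draws
  tr <- trace_truth(simulate_cohort(sim_config(n_cells = 400, seed = 5)))
  expect_lt(abs(mean(tr$true_peak_min) - 55),
            2 * sd(tr$true_peak_min) / sqrt(400) + 2)
})

test_that("substrate decay cancels exactly in the N/C ratio", {
  cfg_on <- sim_config(noise_cv = 0, substrate_halflife = 600, seed = 4)
  cfg_off <- sim_config(noise_cv = 0, substrate_halflife = Inf, seed = 4)
  on <- sample_smad_trace(cfg_on, cell = 2)
  off <- sample_smad_trace(cfg_off, cell = 2)
  expect_equal(on$nluc_nuc / on$nluc_cyt, off$nluc_nuc / off$nluc_cyt,
               tolerance = 1e-12)
  expect_lt(max(on$nluc_nuc + on$nluc_cyt), max(off$nluc_nuc + off$nluc_cyt))
})

test_that("transient ctgf traces sit at basal outside the response window", {
  cfg <- sim_config(noise_cv = 0, seed = 6)
  tr <- sample_ctgf_trace(cfg, "transient", smad_peak_time = 55, cell = 1)
  init_abs <- cfg$stim_time + tr$true_init_time
  ret_abs <- cfg$stim_time + cfg$transient_return_time
  outside <- tr$time_min < init_abs | tr$time_min >= ret_abs
  expect_equal(tr$fluc[outside], rep(tr$true_basal, sum(outside)))
  expect_gt(max(tr$fluc), tr$true_basal)
})

test_that("ctgf initiation lags the SMAD peak by the configured mean", {
  # lag ~ gamma(mean 7 min, cv 0.5)
  tr <- trace_truth(simulate_cohort(sim_config(n_cells = 1000, seed = 7)))
  lag <- tr$true_init_min - tr$true_peak_min
  expect_lt(abs(mean(lag) - 7), 2 * sd(lag) / sqrt(length(lag)))
})

test_that("cross-talk injection is linear and exactly invertible", {
  expect_equal(apply_crosstalk(1:5, 10:14, 0), 10:14)
  expect_equal(apply_crosstalk(rep(1000, 4), rep(0, 4), 0.015), rep(15, 4))
  set.seed(1)
  nluc <- runif(50, 100, 2000)
  fluc <- runif(50, 50, 500)
  raw <- apply_crosstalk(nluc, fluc, 0.015)
  expect_equal(crosstalk_correct(raw, nluc, 0.015), fluc, tolerance = 1e-12)
  expect_error(apply_crosstalk(1:3, 1:4), "length")
})

test_that("cohort phenotype mixture and determinism behave as configured", {
  ts <- simulate_cohort(sim_config(n_cells = 301, seed = 12))
  n_sus <- sum(trace_truth(ts)$phenotype == "sustained")
  expect_lt(abs(n_sus - 301 * 0.13), 3 * sqrt(301 * 0.13 * 0.87))

  a <- simulate_cohort(sim_config(n_cells = 10, seed = 42))
  b <- simulate_cohort(sim_config(n_cells = 10, seed = 42))
  expect_identical(a, b)
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_trace_set(a, pa)
  write_trace_set(b, pb)
  expect_identical(unname(tools::md5sum(pa)), unname(tools::md5sum(pb)))

  all_tr <- simulate_cohort(sim_config(n_cells = 40, transient_fraction = 1,
                                       seed = 2))
  expect_true(all(trace_truth(all_tr)$phenotype == "transient"))
})

test_that("phenotype draws follow the binomial mixture across cohorts", {
  # 400 cohorts of 25 cells via the per-cell streams
  counts <- vapply(seq_len(400), function(s) {
    sum(vapply(1:25, function(cell) {
      set.seed(smadtrace:::stream_seed(s, cell, 0L))
      runif(1) < 0.13
    }, logical(1)))
  }, numeric(1))
  probs <- dbinom(0:25, 25, 0.13)
  obs <- tabulate(counts + 1, 26)
  # pool rare outcomes into one bin so expected counts stay reasonable
  keep <- probs * 400 >= 5
  obs_p <- c(obs[keep], sum(obs[!keep]))
  exp_p <- c(probs[keep], sum(probs[!keep]))
  gof <- suppressWarnings(chisq.test(obs_p, p = exp_p))
  expect_gt(gof$p.value, 0.01)
})

test_that("mean amplitude is non-decreasing in TGF-beta dose", {
  doses <- c(5, 50, 500, 5000)
  means <- vapply(doses, function(d) {
    tr <- trace_truth(simulate_cohort(
      sim_config(n_cells = 100, tgfb_dose_pM = d, seed = 31)))
    mean(tr$true_amplitude)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
  # 5 pM sits near the floor, 500 pM near saturation (Hill K = 50 pM)
  expect_lt(means[1] / means[4], 0.15)
  expect_gt(means[3] / means[4], 0.85)
})

test_that("zero ctgf expression yields pure bleed-through in the raw channel", {
  ts <- simulate_cohort(sim_config(n_cells = 20, ctgf_basal = 0,
                                   ctgf_amplitude_mean = 0, seed = 8))
  expect_equal(ts$fluc, 0.015 * (ts$nluc_nuc + ts$nluc_cyt), tolerance = 1e-12)
})
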
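test_that("correlation distance matches the covariance definition", {
  x <- 1:10
  expect_equal(correlation_distance(x, 2 * x + 3), 0, tolerance = 1e-12)
  expect_equal(correlation_distance(x, -x), 2, tolerance = 1e-12)
  set.seed(14)
  for (i in 1:10) {
    a <- rnorm(30)
    b <- rnorm(30)
    expect_equal(correlation_distance(a, b), 1 - pearson_direct(a, b),
                 tolerance = 1e-12)
  }
  expect_error(correlation_distance(rep(1, 5), 1:5), "zero-variance")
})

test_that("silhouette values equal the brute-force double loop and stay bounded", {
  set.seed(15)
  x <- matrix(rnorm(8 * 12), 8)
  cl <- rep(1:2, each = 4)
  expect_equal(silhouette_scores(x, cl), silhouette_direct(x, cl),
               tolerance = 1e-12)
  # random labelings stay within [-1, 1]
  for (i in 1:5) {
    y <- matrix(rnorm(20 * 15), 20)
    lab <- sample(1:3, 20, replace = TRUE)
    lab[1:3] <- 1:3  # guarantee all clusters present
    s <- silhouette_scores(y, lab)
    expect_true(all(s >= -1 & s <= 1))
    expect_equal(s, silhouette_direct(y, lab), tolerance = 1e-12)
  }
  expect_error(silhouette_scores(x, rep(1, 8)), "2 clusters")
})

test_that("a cell equidistant between two tight clusters scores zero", {
  base <- sin((1:20) / 3)
  g1 <- rbind(base, base)                     # identical pair: d = 0 inside
  g2 <- rbind(rev(base), rev(base))
  probe <- base + rev(base) + rnorm(20, 0, 1e-8)
  x <- rbind(g1, probe, g2)
  cl <- c(1, 1, 1, 2, 2)
  s <- silhouette_scores(x, cl)
  # a_probe and b_probe are equal up to numerical noise
  expect_lt(abs(s[3]), 1e-3)
})

test_that("k-means separates duplicated shapes perfectly", {
  base1 <- sin((1:30) / 4)
  base2 <- exp(-(1:30) / 10)
  x <- rbind(matrix(rep(base1, 10), 10, byrow = TRUE) + 0.01 * matrix(rnorm(300), 10),
             matrix(rep(base2, 10), 10, byrow = TRUE) + 0.01 * matrix(rnorm(300), 10))
  fit <- kmeans_cluster(x, k = 2, seed = 2, restarts = 10)
  expect_equal(length(unique(fit$cluster[1:10])), 1)
  expect_equal(length(unique(fit$cluster[11:20])), 1)
  expect_true(fit$cluster[1] != fit$cluster[11])
  expect_gt(mean(silhouette_scores(x, fit$cluster)), 0.9)
  expect_error(kmeans_cluster(matrix(1, 4, 10), k = 2), "zero-variance")
  expect_error(kmeans_cluster(x[1:3, ], k = 5), "exceeds")
})

test_that("k-means attains the exhaustive best 2-partition for small n", {
  set.seed(16)
  for (rep in 1:5) {
    x <- matrix(rnorm(8 * 10), 8)
    fit <- kmeans_cluster(x, k = 2, seed = rep, restarts = 80)
    expect_equal(fit$inertia, best_two_partition_inertia(x),
                 tolerance = 1e-8)
  }
})

test_that("the k-means objective is non-increasing within a restart", {
  set.seed(17)
  x <- matrix(rnorm(40 * 20), 40)
  z <- smadtrace:::row_standardize(x)
  for (i in 1:5) {
    fit <- smadtrace:::kmeans_once(x, z, 3, 300)
    expect_true(all(diff(fit$history) <= 1e-10))
  }
})

test_that("clustering is deterministic under a seed", {
  ts <- simulate_cohort(sim_config(n_cells = 40, seed = 19))
  a <- classify_traces(ts, seed = 5, restarts = 10)
  b <- classify_traces(ts, seed = 5, restarts = 10)
  expect_identical(tidy(a), tidy(b))
})

test_that("cluster labels are content-based and recover the ground truth", {
  ts <- simulate_cohort(sim_config(n_cells = 120, seed = 20))
  truth <- trace_truth(ts)
  cr <- classify_traces(ts, seed = 3, restarts = 25)
  m <- dplyr::inner_join(tidy(cr), truth, by = "cell_id")
  expect_gt(mean(m$label == m$phenotype), 0.9)
  # majority phenotype per cluster agrees with the assigned name
  maj <- dplyr::summarize(dplyr::group_by(m, cluster),
                          truth_major = names(which.max(table(phenotype))),
                          label = label[1])
  expect_equal(maj$label, maj$truth_major)
  # swapping cluster ids cannot change content-based labels
  swapped <- cr
  swapped$cluster_labels <- NULL
  swapped$centers <- cr$centers[c(2, 1), , drop = FALSE]
  swapped$cells$cluster <- 3L - cr$cells$cluster
  relab <- label_clusters(swapped)
  expect_equal(relab$cells$label, cr$cells$label)
})

test_that("labels recover >= 90% of phenotypes at high noise", {
  ts <- simulate_cohort(sim_config(n_cells = 80, noise_cv = 0.2, seed = 23))
  cr <- classify_traces(ts, seed = 4, restarts = 25)
  m <- dplyr::inner_join(tidy(cr), trace_truth(ts), by = "cell_id")
  expect_gte(mean(m$label == m$phenotype), 0.9)
})

test_that("an all-transient cohort forced to k = 2 still labels both clusters", {
  ts <- simulate_cohort(sim_config(n_cells = 30, transient_fraction = 1,
                                   seed = 24))
  cr <- classify_traces(ts, seed = 1, restarts = 10)
  expect_setequal(cr$cluster_labels, c("transient", "sustained"))
  expect_equal(nrow(tidy(cr)), 30)
})

test_that("the fraction test matches closed-form tables", {
  ft0 <- fraction_test(rbind(c(10, 10), c(10, 10)))
  expect_equal(ft0$statistic, 0)
  expect_equal(ft0$p_value, 1)
  ft1 <- fraction_test(rbind(c(50, 0), c(0, 50)))
  expect_equal(ft1$statistic, 100)
  expect_equal(ft1$dof, 1)
  expect_error(fraction_test(matrix(1:2, 1)), "2 conditions")
  df <- data.frame(condition = rep(c("a", "b"), each = 4),
                   label = rep(c("transient", "sustained"), 4))
  expect_equal(fraction_test(df)$statistic, 0)
  expect_warning(fraction_test(rbind(c(1, 0), c(0, 1))), "below 1")
})

test_that("level comparison is a Welch t-test with class guards", {
  f <- data.frame(cell_id = 1:8, mean_smad_level = c(1, 2, 3, 4, 1, 2, 3, 4))
  lab <- data.frame(cell_id = 1:8,
                    label = rep(c("transient", "sustained"), each = 4))
  same <- level_comparison(f, lab)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  f2 <- f
  f2$mean_smad_level <- c(0, 0, 0, 0, 10, 10, 10, 10) + rnorm(8, 0, 1e-3)
  expect_lt(level_comparison(f2, lab)$p_value, 1e-3)
  expect_error(level_comparison(f[c(1, 5:8), ], lab[c(1, 5:8), ]), ">= 2")
})

test_that("SMAD-level coupling produces a detectable class difference", {
  cfg <- sim_config(n_cells = 250, sustained_level_factor = 1.6, seed = 25)
  ts <- simulate_cohort(cfg)
  f <- quantify_cohort(ts)
  lab <- data.frame(cell_id = trace_truth(ts)$cell_id,
                    label = trace_truth(ts)$phenotype)
  res <- level_comparison(f, lab)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$mean_sustained, res$mean_transient)
})
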
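# short-recording config used across tests: 61 frames, stimulus at 60 min
short_config <- function(n_cells = 8, seed = 1, ...) {
  sim_config(n_cells = n_cells, duration = 300, stim_time = 60,
             transient_peak_delay = 120, transient_return_time = 200,
             second_wave_jitter_max = 60, second_wave_rise = 30,
             second_wave_fall = 60, seed = seed, ...)
}

# render a small movie from a short cohort
small_movie <- function(n_cells = 6, noise_cv = 0.02, shot_noise = TRUE,
                        motion_sd = 0.3, frame_size = c(140, 140),
                        seed = 1, ...) {
  ts <- simulate_cohort(short_config(n_cells = n_cells, noise_cv = noise_cv,
                                     seed = seed, ...))
  render_movie(ts, frame_size = frame_size, motion_sd = motion_sd,
               shot_noise = shot_noise, seed = seed)
}

# brute-force Pearson correlation from the covariance definition
pearson_direct <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# O(n^2) silhouette oracle: double loop over all pairs
silhouette_direct <- function(x, cl) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- 1 - pearson_direct(x[i, ], x[j, ])
    }
  }
  vapply(seq_len(n), function(i) {
    same <- which(cl == cl[i] & seq_len(n) != i)
    if (length(same) == 0) return(0)
    a <- mean(d[i, same])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g) {
      mean(d[i, cl == g])
    }, numeric(1)))
    if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# exhaustive best 2-partition by total within-cluster correlation distance
# to the cluster mean trace
best_two_partition_inertia <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (code in seq_len(2^(n - 1) - 1)) {
    grp <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)])
    obj <- 0
    for (g in 0:1) {
      rows <- which(grp == g)
      ctr <- colMeans(x[rows, , drop = FALSE])
      obj <- obj + sum(vapply(rows, function(i) {
        1 - pearson_direct(x[i, ], ctr)
      }, numeric(1)))
    }
    best <- min(best, obj)
  }
  best
}

# brute-force minimum-cost assignment over all permutations (square matrix)
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  min(vapply(perms(seq_len(n)), function(p) {
    sum(cost[cbind(seq_len(n), p)])
  }, numeric(1)))
}
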
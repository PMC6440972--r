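#' Correlation distance between two traces
#'
#' `d = 1 - Pearson correlation`, in `[0, 2]`: 0 for perfectly correlated
#' shapes, 2 for perfectly anticorrelated ones. The distance metric used
#' for clustering dynamic patterns irrespective of absolute level.
#'
#' @param x,y equal-length numeric vectors with nonzero variance.
#' @return Scalar distance.
#' @export
#' @examples
#' correlation_distance(1:5, 2 * (1:5) + 3)  # 0
correlation_distance <- function(x, y) {
  if (length(x) != length(y)) abort("series lengths differ.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero-variance series: correlation distance undefined.")
  }
  1 - cor(x, y)
}

## rows scaled to zero mean, unit sum of squares, so Z %*% t(Z) is the
## Pearson correlation matrix of the rows
row_standardize <- function(x, what = "trace") {
  ctr <- x - rowMeans(x)
  ss <- sqrt(rowSums(ctr^2))
  bad <- which(ss == 0)
  if (length(bad) > 0) {
    ids <- rownames(x)[bad] %||% as.character(bad)
    abort(paste0("zero-variance ", what, "(s): ",
                 paste(head(ids, 5), collapse = ", ")))
  }
  ctr / ss
}

cor_dist_matrix <- function(x) {
  z <- row_standardize(x)
  d <- 1 - tcrossprod(z)
  diag(d) <- 0
  d
}

#' k-means clustering of traces under correlation distance
#'
#' Partitions rows of a trace matrix into `k` clusters. Seeding is
#' distance-weighted (k-means++ analog: each next seed is drawn with
#' probability proportional to the squared correlation distance to the
#' nearest chosen seed); assignment minimizes correlation distance to the
#' arithmetic mean trace of each cluster; iteration runs to an assignment
#' fixpoint (or `max_iter`). The best of `restarts` runs by total
#' within-cluster distance is returned. Deterministic under `seed`. An
#' empty cluster is re-seeded from the point farthest from its centroid.
#'
#' @param x numeric matrix, rows = cells, columns = timepoints (typically
#'   max-normalized post-stimulation traces).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param restarts number of random restarts.
#' @param max_iter iteration cap per restart.
#' @return A list with `cluster` (integer vector), `centers` (k x T mean
#'   traces), `inertia` (total within-cluster distance), `iter`, `k`,
#'   `seed`, `restarts`.
#' @export
#' @examples
#' x <- rbind(matrix(rep(sin(1:20 / 3), 5), 5, byrow = TRUE),
#'            matrix(rep(cos(1:20 / 3), 5), 5, byrow = TRUE))
#' kmeans_cluster(x, k = 2, seed = 1, restarts = 5)$cluster
kmeans_cluster <- function(x, k = 2, seed = 1L, restarts = 50L,
                           max_iter = 300L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) abort("`k` exceeds the number of traces.")
  z <- row_standardize(x)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- kmeans_once(x, z, k, max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best$k <- k
  best$seed <- as.integer(seed)
  best$restarts <- as.integer(restarts)
  best
}

kmeans_once <- function(x, z, k, max_iter) {
  n <- nrow(x)
  ## ++-style seeding on the standardized rows
  seeds <- integer(k)
  seeds[1] <- sample.int(n, 1)
  if (k > 1) {
    d_near <- 1 - as.vector(z %*% z[seeds[1], ])
    for (j in 2:k) {
      w <- pmax(d_near, 0)^2
      seeds[j] <- if (sum(w) == 0) sample.int(n, 1) else sample.int(n, 1, prob = w)
      d_near <- pmin(d_near, 1 - as.vector(z %*% z[seeds[j], ]))
    }
  }
  centers <- x[seeds, , drop = FALSE]
  assign_prev <- rep(0L, n)
  iter <- 0L
  history <- numeric(0)
  repeat {
    iter <- iter + 1L
    cz <- row_standardize(centers, what = "centroid")
    sim <- tcrossprod(z, cz)              # n x k Pearson correlations
    assign <- max.col(sim, ties.method = "first")
    ## re-seed any emptied cluster from the globally farthest point
    for (j in which(tabulate(assign, k) == 0)) {
      far <- which.min(sim[cbind(seq_len(n), assign)])
      assign[far] <- j
    }
    history <- c(history, sum(1 - sim[cbind(seq_len(n), assign)]))
    if (identical(assign, assign_prev) || iter >= max_iter) {
      inertia <- sum(1 - sim[cbind(seq_len(n), assign)])
      return(list(cluster = assign, centers = centers, inertia = inertia,
                  iter = iter, history = history))
    }
    assign_prev <- assign
    centers <- do.call(rbind, lapply(seq_len(k), function(j) {
      colMeans(x[assign == j, , drop = FALSE])
    }))
  }
}

#' Per-cell silhouette values
#'
#' `S_i = (b_i - a_i) / max(a_i, b_i)` under correlation distance, where
#' `a_i` is the mean distance from cell i to the other members of its own
#' cluster and `b_i` the minimum over other clusters of the mean distance
#' to that cluster's members. Always in `[-1, 1]`; cells in singleton
#' clusters score 0.
#'
#' @param x trace matrix (rows = cells).
#' @param cluster integer cluster assignment per row.
#' @return Numeric vector of silhouette values.
#' @export
silhouette_scores <- function(x, cluster) {
  x <- as.matrix(x)
  cl <- as.integer(factor(cluster))
  if (length(unique(cl)) < 2) abort("silhouette requires at least 2 clusters.")
  d <- cor_dist_matrix(x)
  n <- nrow(x)
  sizes <- tabulate(cl)
  ## mean distance from every point to every cluster
  msum <- rowsum(t(d), cl)                 # k x n sums of distances
  vapply(seq_len(n), function(i) {
    own <- cl[i]
    if (sizes[own] == 1) return(0)
    a <- msum[own, i] / (sizes[own] - 1)
    b <- min(msum[-own, i] / sizes[-own])
    if (a == 0 && b == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
}

#' Classify ctgf traces into transient and sustained responders
#'
#' The user-facing clustering verb. Crops each cell's cross-talk-corrected
#' Fluc trace to the post-stimulation window, max-normalizes it (so
#' dynamics rather than amplitude drive the classes), clusters with
#' [kmeans_cluster()] at `k = 2`, scores every cell with
#' [silhouette_scores()] and names the clusters with [label_clusters()].
#'
#' @param traces a [trace_set][new_trace_set()] or data frame with its
#'   columns.
#' @param k number of clusters.
#' @param seed,restarts passed to [kmeans_cluster()].
#' @param normalize `"max"` (default) or `"none"` for absolute traces.
#' @param crosstalk_coeff bleed-through fraction removed before clustering.
#' @param stim_time stimulation time, minutes; defaults to the trace-set
#'   attribute.
#' @param features optional features tibble ([quantify_cohort()]) used for
#'   the labeling tie-break.
#' @return A `cluster_result`: use [tidy()] for per-cell labels and
#'   silhouettes, [glance()] for run-level statistics, `$counts` for
#'   per-condition class counts.
#' @export
#' @examples
#' ts <- simulate_cohort(sim_config(n_cells = 30, seed = 2))
#' cr <- classify_traces(ts, seed = 1, restarts = 10)
#' glance(cr)
classify_traces <- function(traces, k = 2, seed = 1L, restarts = 50L,
                            normalize = c("max", "none"),
                            crosstalk_coeff = 0.015, stim_time = NULL,
                            features = NULL) {
  normalize <- match.arg(normalize)
  stim_time <- stim_time %||% attr(traces, "stim_time") %||% 180
  df <- as_tibble(traces) |>
    dplyr::mutate(fluc_corr = crosstalk_correct(
      .data$fluc, .data$nluc_nuc + .data$nluc_cyt, crosstalk_coeff,
      quiet = TRUE
    )) |>
    dplyr::filter(.data$time_min >= stim_time)
  wide <- tidyr::pivot_wider(df[, c("cell_id", "time_min", "fluc_corr")],
                             names_from = "time_min",
                             values_from = "fluc_corr")
  ids <- wide$cell_id
  x <- as.matrix(wide[, -1])
  rownames(x) <- ids
  time_post <- as.numeric(colnames(wide)[-1]) - stim_time
  if (normalize == "max") {
    x <- t(apply(x, 1, normalize_trace, mode = "max"))
  }
  fit <- kmeans_cluster(x, k = k, seed = seed, restarts = restarts)
  sil <- silhouette_scores(x, fit$cluster)
  res <- structure(
    list(
      cells = tibble(cell_id = ids, cluster = fit$cluster, silhouette = sil),
      centers = fit$centers,
      time_post = time_post,
      k = fit$k, seed = fit$seed, restarts = fit$restarts,
      inertia = fit$inertia,
      mean_silhouette = mean(sil),
      stim_time = stim_time
    ),
    class = "cluster_result"
  )
  res <- label_clusters(res, features = features)
  cond_cols <- intersect(c("tgfb_dose_pM", "dox_ng_ml", "smad_kind"),
                         names(traces))
  if (length(cond_cols) > 0) {
    conds <- dplyr::distinct(as_tibble(traces)[, c("cell_id", cond_cols)])
    res$counts <- dplyr::left_join(res$cells, conds, by = "cell_id") |>
      dplyr::count(dplyr::across(dplyr::all_of(c(cond_cols, "label"))))
  }
  res
}

#' Name clusters transient or sustained by their late dynamics
#'
#' The cluster whose mean max-normalized trace has the larger average value
#' in the late window (8-12 h post-stimulation) is labeled sustained; ties
#' are broken toward the cluster with the larger fraction of cells with an
#' undefined return time (requires `features`). The label depends only on
#' trace content, so it is invariant to cluster id permutation.
#'
#' @param result a `cluster_result` (see [classify_traces()]).
#' @param features optional [quantify_cohort()] tibble for the tie-break.
#' @param late_window window in minutes post-stimulation.
#' @return The `cluster_result` with a `label` column added to `$cells` and
#'   a `cluster_labels` map.
#' @export
label_clusters <- function(result, features = NULL,
                           late_window = c(480, 720)) {
  stopifnot(inherits(result, "cluster_result"))
  idx <- result$time_post >= late_window[1] & result$time_post <= late_window[2]
  cmax <- pmax(apply(result$centers, 1, max), .Machine$double.eps)
  late <- rowSums(result$centers[, idx, drop = FALSE]) / sum(idx) / cmax
  sustained <- which.max(late)
  if (sum(late == max(late)) > 1) {
    tied <- which(late == max(late))
    if (!is.null(features)) {
      undef <- vapply(tied, function(j) {
        cells <- result$cells$cell_id[result$cells$cluster == j]
        mean(is.na(features$return_time[features$cell_id %in% cells]))
      }, numeric(1))
      sustained <- tied[which.max(undef)]
    } else {
      warn("late-window tie between clusters; first tied cluster labeled sustained.")
    }
  }
  labels <- rep("transient", result$k)
  labels[sustained] <- "sustained"
  result$cluster_labels <- labels
  result$cells$label <- labels[result$cells$cluster]
  result
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, %d cells, inertia %.4f, mean silhouette %.3f\n",
              x$k, nrow(x$cells), x$inertia, x$mean_silhouette))
  print(table(x$cells$label))
  invisible(x)
}

#' Chi-squared test of class fractions across conditions
#'
#' Pearson chi-squared (no continuity correction) on the condition-by-class
#' contingency table of transient/sustained counts.
#'
#' @param counts either a matrix/table (rows = conditions, columns =
#'   classes) or a data frame with columns `condition`, `label` and
#'   optionally `n` (precomputed counts).
#' @return A `fraction_test` object; [tidy()] gives the table in long form,
#'   [glance()] the statistic, degrees of freedom and p-value.
#' @export
#' @examples
#' fraction_test(rbind(c(50, 0), c(0, 50)))$statistic  # 100
fraction_test <- function(counts) {
  tab <- if (is.matrix(counts) || is.table(counts)) {
    as.matrix(counts)
  } else {
    df <- as_tibble(counts)
    if (!all(c("condition", "label") %in% names(df))) {
      abort("data-frame input needs `condition` and `label` columns.")
    }
    if (!"n" %in% names(df)) df <- dplyr::count(df, .data$condition, .data$label)
    tidyr::pivot_wider(df, names_from = "label", values_from = "n",
                       values_fill = 0) |>
      tibble::column_to_rownames("condition") |>
      as.matrix()
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("fraction test needs >= 2 conditions and >= 2 classes.")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 1)) {
    warn("some expected counts are below 1; chi-squared approximation is poor.")
  }
  structure(
    list(table = tab, statistic = unname(ht$statistic),
         dof = unname(ht$parameter), p_value = ht$p.value,
         expected = ht$expected),
    class = "fraction_test"
  )
}

#' @export
print.fraction_test <- function(x, ...) {
  cat(sprintf("<fraction_test> X-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$dof, x$p_value))
  print(x$table)
  invisible(x)
}

#' Compare a feature between response classes
#'
#' Welch two-sample t-test of any per-cell feature (by default the mean
#' SMAD expression level over the 12 h post-stimulation) between the
#' transient and sustained classes.
#'
#' @param features a [quantify_cohort()] tibble.
#' @param labels a data frame with `cell_id` and `label` (e.g.
#'   `tidy(classify_traces(...))`).
#' @param field feature column to compare.
#' @return A one-row tibble with group means, Welch statistic, df and
#'   p-value.
#' @export
level_comparison <- function(features, labels, field = "mean_smad_level") {
  df <- dplyr::inner_join(as_tibble(features),
                          as_tibble(labels)[, c("cell_id", "label")],
                          by = "cell_id")
  groups <- split(df[[field]], df$label)
  if (length(groups) != 2 || any(lengths(lapply(groups, stats::na.omit)) < 2)) {
    abort("both classes must have >= 2 defined values.")
  }
  ht <- t.test(groups[["transient"]], groups[["sustained"]], var.equal = FALSE)
  tibble(
    field = field,
    mean_transient = mean(groups[["transient"]], na.rm = TRUE),
    mean_sustained = mean(groups[["sustained"]], na.rm = TRUE),
    n_transient = sum(!is.na(groups[["transient"]])),
    n_sustained = sum(!is.na(groups[["sustained"]])),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}
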
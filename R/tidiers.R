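#' Tidiers for fitted objects
#'
#' Broom-style methods: `tidy()` returns per-observation results,
#' `glance()` a one-row model summary.
#'
#' @param x a `cluster_result` or `fraction_test`.
#' @param ... unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.cluster_result <- function(x, ...) {
  x$cells
}

#' @rdname tidiers
#' @export
glance.cluster_result <- function(x, ...) {
  tab <- table(factor(x$cells$label, levels = c("transient", "sustained")))
  tibble(
    k = x$k, n = nrow(x$cells), seed = x$seed, restarts = x$restarts,
    inertia = x$inertia, mean_silhouette = x$mean_silhouette,
    n_transient = unname(tab["transient"]),
    n_sustained = unname(tab["sustained"]),
    transient_fraction = unname(tab["transient"]) / nrow(x$cells)
  )
}

#' @rdname tidiers
#' @export
tidy.fraction_test <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$table))) |>
    setNames(c("condition", "label", "n"))
}

#' @rdname tidiers
#' @export
glance.fraction_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$dof, p_value = x$p_value)
}

#' Plot a clustering result
#'
#' Shows the mean max-normalized trace of each class (the tabular analog
#' of the transient/sustained population averages) or, with
#' `type = "silhouette"`, the sorted per-cell silhouette values per class.
#'
#' @param object a `cluster_result`.
#' @param type `"centers"` or `"silhouette"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_result <- function(object, type = c("centers", "silhouette"),
                                    ...) {
  type <- match.arg(type)
  if (type == "centers") {
    df <- purrr::imap(seq_len(object$k), function(j, .) {
      tibble(label = object$cluster_labels[j], time_post = object$time_post,
             value = object$centers[j, ] / max(object$centers[j, ]))
    }) |> purrr::list_rbind()
    ggplot2::ggplot(df, ggplot2::aes(.data$time_post, .data$value,
                                     color = .data$label)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time post-stimulation (min)",
                    y = "mean normalized ctgf", color = "class")
  } else {
    df <- object$cells |>
      dplyr::arrange(.data$label, dplyr::desc(.data$silhouette)) |>
      dplyr::mutate(rank = dplyr::row_number())
    ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$silhouette,
                                     fill = .data$label)) +
      ggplot2::geom_col(width = 1) +
      ggplot2::labs(x = "cells (sorted)", y = "silhouette value",
                    fill = "class")
  }
}
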
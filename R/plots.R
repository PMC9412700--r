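#' Plot the channels of one trial
#'
#' Faceted line plot of a time-by-channel trial matrix, one facet per digit
#' with one line per joint.
#'
#' @param values Time-by-channel matrix (15 glove channels or any named
#'   columns).
#' @param sample_rate Sampling rate in Hz (x axis in seconds).
#' @return A ggplot object.
#' @export
plot_trial <- function(values, sample_rate = 100) {
  values <- as.matrix(values)
  cn <- colnames_or_default(values)
  df <- tibble::tibble(
    time = rep((seq_len(nrow(values)) - 1) / sample_rate, ncol(values)),
    channel = rep(cn, each = nrow(values)),
    value = as.vector(values)
  )
  df$digit <- substr(df$channel, 1, 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~digit, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = "sensor value") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap for a cross-validation result
#'
#' @param object A `grip_cv`.
#' @param ... Unused.
#' @return A ggplot object: row-normalized confusion matrix with counts.
#' @method autoplot grip_cv
#' @export
autoplot.grip_cv <- function(object, ...) {
  conf <- object$confusion
  df <- tibble::as_tibble(as.data.frame.table(conf, responseName = "n"))
  df <- df |>
    dplyr::group_by(.data$true) |>
    dplyr::mutate(frac = .data$n / max(sum(.data$n), 1)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$frac)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1), name = "row fraction") +
    ggplot2::labs(
      x = "predicted task", y = "true task",
      title = sprintf("%s / %s: DA %.1f%%", object$spec$classifier,
                      object$spec$scheme, object$da)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Permutation-distribution histogram
#'
#' @param object A `grip_permtest`.
#' @param observed_da Optional observed decoding accuracy to mark.
#' @param ... Unused.
#' @return A ggplot object with the chance-level distribution, its 95%
#'   percentile CI, and optionally the observed DA.
#' @method autoplot grip_permtest
#' @export
autoplot.grip_permtest <- function(object, observed_da = NULL, ...) {
  df <- tibble::tibble(da = object$das)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$da)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$ci, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$mean, colour = "steelblue") +
    ggplot2::labs(x = "decoding accuracy [%]", y = "permutations",
                  title = sprintf("chance level %.1f%% (CI %.1f-%.1f%%)",
                                  object$mean, object$ci[1], object$ci[2])) +
    ggplot2::theme_minimal()
  if (!is.null(observed_da)) {
    p <- p + ggplot2::geom_vline(xintercept = observed_da, colour = "firebrick")
  }
  p
}
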
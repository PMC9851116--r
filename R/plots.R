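# ggplot2 visualizations for each result type.

#' Plot FVEP waveforms by class
#'
#' @param records Record tibble.
#' @param max_per_class Sweeps drawn per class.
#' @return A ggplot object: amplitude vs time, coloured by class.
#' @export
plot_waveforms <- function(records, max_per_class = 8L) {
  check_records(records)
  sub <- records %>%
    group_by(.data$label) %>%
    dplyr::slice_head(n = max_per_class) %>%
    ungroup() %>%
    mutate(.rec = dplyr::row_number())
  long <- sub %>%
    mutate(time_ms = list(fvep_time_axis())) %>%
    tidyr::unnest(c("signal", "time_ms"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms, y = .data$signal,
                                     group = .data$.rec,
                                     colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time after flash (ms)", y = "amplitude (uV)",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mcac_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log,
                              c("loss", "train_accuracy"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training curves (dotted: selected epoch)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fvep_autoencoder <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch, y = .data$mse)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "reconstruction MSE",
                  title = "Autoencoder pretraining") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.imf_set <- function(object, ...) {
  td <- tidy(object)
  td$component <- factor(td$component, levels = unique(td$component))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component),
                        scales = "free_y") +
    ggplot2::labs(x = "sample", y = "amplitude (uV)") +
    ggplot2::theme_minimal()
}

#' Histogram of OOD scores by method
#'
#' @param scores Tibble with columns `method`, `score` and a logical or 0/1
#'   column `is_ood` marking the true status.
#' @return A ggplot object.
#' @export
plot_ood_scores <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$score,
                                       fill = factor(.data$is_ood))) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
    ggplot2::facet_wrap(~method, scales = "free") +
    ggplot2::labs(fill = "out-of-distribution") +
    ggplot2::theme_minimal()
}
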
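#' Plot the positional error distribution
#'
#' Bar histogram of error counts per sequencing cycle, total and without
#' homopolymer association (unstacked, homopolymer-free counts in front).
#'
#' @param pos Result of [positional_distribution()].
#' @return A ggplot object.
#' @export
plot_positional_errors <- function(pos) {
  h <- pos$histogram
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_total, fill = "total"),
                      width = 1) +
    ggplot2::labs(x = "read position [bp]", y = "errors", fill = NULL) +
    ggplot2::theme_minimal()
  if (!all(is.na(h$n_non_hp))) {
    p <- p + ggplot2::geom_col(ggplot2::aes(y = .data$n_non_hp,
                                            fill = "non-homopolymer"),
                               width = 1)
  }
  p + ggplot2::scale_fill_manual(values = c(total = "grey80",
                                            `non-homopolymer` = "grey40"))
}

#' Plot estimated versus empirical quality
#'
#' The diagonal marks perfect calibration; points above it mean the
#' instrument overestimates its own performance.
#'
#' @param calib A [calibration_curve()] table.
#' @return A ggplot object.
#' @export
plot_calibration <- function(calib) {
  ggplot2::ggplot(filter(calib, !.data$undefined),
                  ggplot2::aes(x = .data$empirical_q, y = .data$estimated_q)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "red",
                         linewidth = 0.3) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "empirical quality", y = "estimated quality") +
    ggplot2::theme_minimal()
}

#' Plot homopolymer length classes: errors versus background
#'
#' @param err_ctx [error_context_distribution()] table.
#' @param background [background_distribution()] table.
#' @return A ggplot object.
#' @export
plot_context_distribution <- function(err_ctx, background) {
  x <- bind_rows(
    mutate(select(err_ctx, "hp_class", "fraction"), set = "errors"),
    mutate(select(background, "hp_class", "fraction"), set = "reference")
  )
  ggplot2::ggplot(x, ggplot2::aes(x = factor(.data$hp_class, levels = unique(.data$hp_class)),
                                  y = .data$fraction, fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "homopolymer length", y = "fraction", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-position mean quality
#'
#' @param ppq [per_position_quality()] table.
#' @return A ggplot object.
#' @export
plot_position_quality <- function(ppq) {
  ggplot2::ggplot(ppq, ggplot2::aes(x = .data$position, y = .data$mean_q)) +
    ggplot2::geom_line(color = "darkred") +
    ggplot2::labs(x = "read position [bp]", y = "mean quality (error-rate space)") +
    ggplot2::theme_minimal()
}

#' Boxplot data of error versus neighborhood quality per run
#'
#' @param nbq [error_neighborhood_quality()] result.
#' @return A ggplot object.
#' @export
plot_error_quality <- function(nbq) {
  x <- tidyr::pivot_longer(nbq$per_event, c("q_error", "q_neighborhood"),
                           names_to = "what", values_to = "q")
  ggplot2::ggplot(x, ggplot2::aes(x = .data$run_id, y = .data$q,
                                  fill = .data$what)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(x = NULL, y = "phred quality", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.error_profile <- function(object, ...) {
  plot_positional_errors(object$positional)
}
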
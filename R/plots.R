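#' Plot a ranked candidate list
#'
#' UCB score against rank, with the top fraction highlighted.
#'
#' @param object A [rank_candidates()] result.
#' @param top_f Fraction to highlight (default 0.01).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ranked_candidates <- function(object, top_f = 0.01, ...) {
  n_top <- ceiling(top_f * nrow(object))
  df <- dplyr::mutate(object, selected = .data$rank <= n_top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$ucb,
                                   colour = .data$selected)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "rank", y = expression(mu + beta * sigma),
                  title = sprintf("UCB-ranked candidates (top %d highlighted)",
                                  n_top)) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation correlations
#'
#' @param object A [cross_validate()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$folds, c("rho", "tau"),
                            names_to = "metric", values_to = "value")
  means <- tibble::tibble(metric = c("rho", "tau"),
                          value = c(object$mean_rho, object$mean_tau))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::geom_point(data = means, colour = "firebrick", size = 3,
                        shape = 18) +
    ggplot2::labs(x = NULL, y = "rank correlation (per fold)",
                  title = sprintf("%d-fold CV, %s model",
                                  object$config$k, object$config$model)) +
    ggplot2::theme_minimal()
}

#' Plot a Michaelis-Menten fit
#'
#' Measured points with the fitted saturation curve.
#'
#' @param object An [mm_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble::tibble(S = seq(0, max(object$data$S), length.out = 200))
  grid$v <- object$Vmax * grid$S / (object$Km + grid$S)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$S, y = .data$v)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "[S] (mM)", y = "v",
                  title = sprintf("Vmax = %.3g, Km = %.3g mM",
                                  object$Vmax, object$Km)) +
    ggplot2::theme_minimal()
}

#' Bar chart of substitution-site frequencies
#'
#' @param freq A [position_frequency()] table.
#' @return A ggplot object.
#' @export
plot_position_frequency <- function(freq) {
  ggplot2::ggplot(freq, ggplot2::aes(x = factor(.data$position,
                                                levels = .data$position),
                                     y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "parent position", y = "count in selection",
                  title = "substitution-site frequency") +
    ggplot2::theme_minimal()
}
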
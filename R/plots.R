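# ggplot2 views of the main result types.

#' @export
autoplot.lv_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("x", "y"), names_to = "species",
                              values_to = "density")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$density,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(x = "#1b9e77", y = "#d95f02"),
                                 labels = c(x = "prey", y = "predator")) +
    ggplot2::labs(x = "time", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ecopinn_ice <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$grid_value, .data$P_mean,
                                       colour = .data$season)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = unique(object$variable),
                  y = expression(paste("GPP (g C ", m^-2, " ", day^-1, ")")),
                  colour = "season") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ecopinn_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_fold,
                  ggplot2::aes(.data$model, .data$mae)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "test MAE per fold") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.ecopinn_posterior <- function(object, ...) {
  long <- tidyr::pivot_longer(object$draws,
                              cols = object$bounds$name,
                              names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value,
                                     colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(colour = "chain") +
    ggplot2::theme_minimal()
}

#' Per-epoch training-loss curve of a fitted variant
#'
#' @param fit an `ecopinn_fit` (or trained `ecopinn_mlp`).
#' @return a ggplot.
#' @export
plot_loss_curve <- function(fit) {
  curve <- if (inherits(fit, "ecopinn_fit")) fit$loss_curve
           else attr(fit, "loss_curve")
  if (is.null(curve)) abort("no loss curve recorded")
  df <- tibble(epoch = seq_along(curve), loss = curve)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::theme_minimal()
}
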
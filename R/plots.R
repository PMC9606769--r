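# ggplot2 visualizations for the result types.

#' @exportS3Method ggplot2::autoplot
autoplot.std_regression <- function(object, ...) {
  d <- tidy(object)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot(d, aes(x = .data$beta_star, y = .data$term,
                fill = .data$effect_band)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(aes(label = .data$stars),
                       hjust = ifelse(d$beta_star >= 0, -0.2, 1.2)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = expression(beta^"*"), y = NULL,
      title = sprintf("%s (adj R² = %.2f)", object$response,
                      object$r_squared_adj),
      fill = "effect") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.sip_correlation <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$var1, y = .data$var2, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(aes(label = sprintf("%.2f", .data$rho)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(rho)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.slope_preference <- function(object, ...) {
  d <- tidy(object)
  grid <- tidyr::expand_grid(
    dimension = d$dimension,
    set_slope = seq(min(-5), max(0), length.out = 101))
  grid <- dplyr::inner_join(grid, d, by = "dimension")
  grid$fitted <- grid$a + grid$b * grid$set_slope +
    grid$c * grid$set_slope^2
  ggplot(grid, aes(x = .data$set_slope, y = .data$fitted,
                   color = .data$dimension)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "set Fourier slope", y = "fitted mean rating",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cluster_result <- function(object, ...) {
  d <- tidyr::pivot_longer(object$diagnostics,
                           c("wss", "silhouette", "gap"),
                           names_to = "criterion")
  ggplot(d, aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2,
                        color = "firebrick") +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "number of clusters k", y = NULL) +
    ggplot2::theme_minimal()
}

#' Boxplots of a SIP across image categories
#'
#' @param sips A SIP table with a `category` column.
#' @param sip SIP column name to plot.
#' @return A ggplot object.
#' @export
plot_sip_distributions <- function(sips, sip) {
  stopifnot(sip %in% names(sips))
  ggplot(sips, aes(x = .data$category, y = .data[[sip]],
                   fill = .data$category)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = sip) +
    ggplot2::theme_minimal()
}
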
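#' Plot the posterior of one bin
#'
#' Draws the continuous posterior density of the methylation level with the
#' analytic mean, any point masses at 0/1 (as segments), and optionally a
#' credible interval band.
#'
#' @param object A [meth_posterior()].
#' @param interval Interval type to shade, or `NULL`.
#' @param level Credibility level for the band.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meth_posterior
#' @export
autoplot.meth_posterior <- function(object, interval = "hpd", level = 0.95,
                                    ...) {
  mu <- seq(0.001, 0.999, length.out = 512)
  df <- tibble::tibble(mu = mu, density = object$density(mu))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mu, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$mean, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = expression(mu), y = "posterior density")
  if (!is.null(interval)) {
    ci <- switch(interval,
                 hpd = hpd_interval(object, level),
                 quantile = quantile_interval(object, level),
                 wald = wald_interval(object$mean, object$variance, level))
    p <- p + ggplot2::annotate("rect", xmin = ci$lo, xmax = ci$hi,
                               ymin = 0, ymax = Inf, alpha = 0.15,
                               fill = "grey30")
  }
  if (object$atom0 > 0 || object$atom1 > 0) {
    at <- tibble::tibble(mu = c(0, 1), w = c(object$atom0, object$atom1))
    at <- at[at$w > 0, ]
    p <- p + ggplot2::geom_segment(
      data = at, ggplot2::aes(x = .data$mu, xend = .data$mu,
                              y = 0, yend = .data$w * max(df$density)),
      colour = "steelblue", linewidth = 1.2)
  }
  p
}

#' Plot fitted class hyperparameters with the prior predictive band
#'
#' For a SssI-aware fit, shows per CpG class the prior-predictive negative
#' binomial mean of the control counts with a central 95% band — the
#' read-depth-versus-CpG-density relation the empirical Bayes step captures.
#'
#' @param object A `meth_eb_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meth_eb_fit
#' @export
autoplot.meth_eb_fit <- function(object, ...) {
  cls <- tidy(object)
  cls$lo <- purrr::map2_dbl(cls$alpha, cls$beta,
                            ~ prior_predictive_sssi(.x, .y)$quantile(0.025))
  cls$hi <- purrr::map2_dbl(cls$alpha, cls$beta,
                            ~ prior_predictive_sssi(.x, .y)$quantile(0.975))
  ggplot2::ggplot(cls, ggplot2::aes(x = .data$cpg_class)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "darkgreen", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pp_mean), colour = "darkgreen") +
    ggplot2::labs(x = "CpG density class",
                  y = "prior predictive control reads",
                  title = "Fitted read-density priors by CpG class")
}

#' Scatter of estimates against truth
#'
#' @param data Tibble with estimate and truth columns.
#' @param estimate,truth Column names (tidy-select).
#' @return A ggplot object with the identity line.
#' @export
plot_estimates_vs_truth <- function(data, estimate = mean, truth = mu_true) {
  ggplot2::ggplot(data, ggplot2::aes(x = {{ truth }}, y = {{ estimate }})) +
    ggplot2::geom_point(alpha = 0.25, size = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "darkgreen",
                         linetype = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "true methylation", y = "estimated methylation")
}
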
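#' Tidy a fitted empirical Bayes class model
#'
#' @param x A `meth_eb_fit` from [fit_meth_model()].
#' @param ... Unused.
#' @return One row per CpG class with the fitted hyperparameters and, via
#'   [prior_predictive_sssi()], the implied prior-predictive mean and
#'   variance of the control counts.
#' @method tidy meth_eb_fit
#' @export
tidy.meth_eb_fit <- function(x, ...) {
  dplyr::mutate(x$classes,
                pp_mean = .data$alpha / .data$beta,
                pp_variance = .data$alpha * (.data$beta + 1) / .data$beta^2)
}

#' @rdname tidy.meth_eb_fit
#' @return `glance()`: a one-row summary (mode, number of classes, total
#'   log-likelihood, masked fraction, offset).
#' @method glance meth_eb_fit
#' @export
glance.meth_eb_fit <- function(x, ...) {
  cls <- x$classes
  fitted_cls <- cls[!duplicated(cls$fit_class), ]
  tibble::tibble(
    mode = x$mode,
    prior = x$prior$kind,
    k = nrow(cls),
    k_fitted = nrow(fitted_cls),
    n_bins = sum(cls$n_bins),
    n_masked = sum(cls$n_masked),
    logLik = sum(fitted_cls$loglik),
    converged = all(cls$converged),
    f = x$f
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
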
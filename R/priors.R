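#' Prior distributions for the regional methylation level
#'
#' Constructs the prior on the methylation level \eqn{\mu \in [0, 1]} used by
#' the posterior machinery. Three families are supported:
#'
#' * `"uniform"` — flat on \eqn{(0,1)}; equivalent to a single Beta(1, 1)
#'   component. The default when a fully methylated (SssI) control is modeled
#'   jointly with the sample of interest.
#' * `"beta_mixture"` — a weighted mixture of Beta components.
#' * `"dbd"` — Dirac-Beta-Dirac: point masses at 0 and 1 (weights `w0`, `w1`)
#'   with a Beta middle component. The default for SssI-free runs uses weights
#'   (0.1, 0.8, 0.1) with the Beta shape parameters left free for the
#'   empirical Bayes fit.
#'
#' Beta shape parameters may be `NA` to mark them as free hyperparameters to
#' be estimated by [fit_meth_model()].
#'
#' @param kind Prior family.
#' @param a,b Beta shape parameters (vectors for `"beta_mixture"`); `NA` means
#'   "estimate by empirical Bayes".
#' @param weights Component weights for `"beta_mixture"`; must sum to 1.
#' @param w0,w1 Point-mass weights at 0 and 1 for `"dbd"`.
#' @return An object of class `meth_prior`: a list with elements `kind`, `w0`,
#'   `w1` and `components` (a tibble with columns `weight`, `a`, `b`).
#' @examples
#' meth_prior("uniform")
#' meth_prior("dbd", w0 = 0.1, w1 = 0.1)                # free Beta middle
#' meth_prior("beta_mixture", weights = c(.5, .5), a = c(1, 5), b = c(5, 1))
#' @export
meth_prior <- function(kind = c("uniform", "beta_mixture", "dbd"),
                       a = NA_real_, b = NA_real_,
                       weights = NULL, w0 = 0.1, w1 = 0.1) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    comp <- tibble::tibble(weight = 1, a = 1, b = 1)
    w0 <- w1 <- 0
  } else if (kind == "dbd") {
    stopifnot(w0 >= 0, w1 >= 0, w0 + w1 < 1)
    comp <- tibble::tibble(weight = 1 - w0 - w1, a = a[1], b = b[1])
  } else {
    if (is.null(weights)) weights <- rep(1 / length(a), length(a))
    stopifnot(length(weights) == length(a), length(a) == length(b),
              all(weights >= 0), abs(sum(weights) - 1) < 1e-8)
    comp <- tibble::tibble(weight = weights, a = a, b = b)
    w0 <- w1 <- 0
  }
  bad <- !is.na(comp$a) & comp$a <= 0 | !is.na(comp$b) & comp$b <= 0
  if (any(bad)) stop("beta shape parameters must be positive", call. = FALSE)
  structure(list(kind = kind, w0 = w0, w1 = w1, components = comp),
            class = "meth_prior")
}

#' @export
print.meth_prior <- function(x, ...) {
  cat("<meth_prior> kind:", x$kind, "\n")
  if (x$w0 > 0 || x$w1 > 0) {
    cat("  point masses: w0 =", x$w0, " w1 =", x$w1, "\n")
  }
  print(x$components)
  invisible(x)
}

# TRUE if any beta shape parameter is left free for empirical Bayes
.prior_has_free_ab <- function(prior) {
  any(is.na(prior$components$a)) || any(is.na(prior$components$b))
}

# replace free shape parameters with concrete values
.prior_fill_ab <- function(prior, a, b) {
  prior$components$a[is.na(prior$components$a)] <- a
  prior$components$b[is.na(prior$components$b)] <- b
  prior
}

#' Sample methylation levels from a `meth_prior`
#'
#' @param n Number of draws.
#' @param prior A [meth_prior()] object with concrete (non-`NA`) parameters.
#' @return Numeric vector in \[0, 1\].
#' @export
rmeth_prior <- function(n, prior) {
  stopifnot(inherits(prior, "meth_prior"))
  if (.prior_has_free_ab(prior)) {
    stop("prior has free (NA) shape parameters; fit or fix them first",
         call. = FALSE)
  }
  comp <- prior$components
  probs <- c(prior$w0, prior$w1, comp$weight)
  pick <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  out <- numeric(n)
  out[pick == 1] <- 0
  out[pick == 2] <- 1
  for (j in seq_len(nrow(comp))) {
    idx <- pick == j + 2
    out[idx] <- stats::rbeta(sum(idx), comp$a[j], comp$b[j])
  }
  out
}

# prior log density of the continuous part (without atoms), vectorized in mu
.dmeth_prior_cont <- function(mu, prior) {
  comp <- prior$components
  dens <- rep(0, length(mu))
  for (j in seq_len(nrow(comp))) {
    dens <- dens + comp$weight[j] * stats::dbeta(mu, comp$a[j], comp$b[j])
  }
  dens
}
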
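#' Gauss hypergeometric function 2F1 for the methylation posterior
#'
#' Numerically stable evaluation of the Gauss hypergeometric function
#' \eqn{{}_2F_1(a, b; c; z)} in the parameter region used by the closed-form
#' methylation posterior: \eqn{c > b > 0} and \eqn{z < 1} (negative \eqn{z}
#' allowed). `lhyp2f1()` returns the natural logarithm, which is the form the
#' rest of the package consumes; `hyp2f1()` exponentiates it.
#'
#' For \eqn{0 \le z < 1} the defining series is accumulated in log space
#' (running log-sum-exp over chunks), so shape parameters in the thousands do
#' not overflow. For \eqn{z < 0} the Pfaff transformation
#' \eqn{{}_2F_1(a,b;c;z) = (1-z)^{-a} {}_2F_1(a, c-b; c; z/(z-1))} maps the
#' argument into \eqn{(0,1)} with all-positive parameters. If the series has
#' not met `tol` within `max_terms` terms, a log-scaled adaptive quadrature of
#' the Euler integral representation is used instead.
#'
#' @param a,b,c Function parameters; the implementation requires `c > b > 0`
#'   and (after the Pfaff step) `a > 0`, which the methylation model always
#'   satisfies.
#' @param z Argument, `z < 1`.
#' @param tol Relative truncation tolerance of the series.
#' @param max_terms Maximum number of series terms before falling back to
#'   quadrature.
#' @return `lhyp2f1()`: the log of the function value; `hyp2f1()`: the value.
#' @examples
#' hyp2f1(1, 1, 2, 1 / 3)       # equals -log(1 - z) / z = 3 log(3/2)
#' lhyp2f1(507, 1, 9, 0.33)     # large-parameter case, no overflow
#' @export
lhyp2f1 <- function(a, b, c, z, tol = 1e-12, max_terms = 2e6) {
  stopifnot(length(a) == 1, length(b) == 1, length(c) == 1, length(z) == 1)
  if (!is.finite(a) || !is.finite(b) || !is.finite(c) || !is.finite(z)) {
    stop("non-finite 2F1 parameters", call. = FALSE)
  }
  if (z >= 1) stop("2F1 requires z < 1", call. = FALSE)
  if (!(c > b && b > 0)) stop("2F1 requires c > b > 0", call. = FALSE)
  if (z == 0) return(0)
  if (z < 0) {
    # Pfaff: all parameters positive, argument in (0, 1)
    if (a <= 0) stop("2F1 requires a > 0", call. = FALSE)
    return(-a * log1p(-z) + lhyp2f1(a, c - b, c, z / (z - 1), tol, max_terms))
  }
  if (a <= 0) stop("2F1 requires a > 0 for z > 0 in this model", call. = FALSE)
  out <- .lhyp2f1_series(a, b, c, z, tol, max_terms)
  if (is.na(out)) out <- .lhyp2f1_quad(a, b, c, z)
  out
}

#' @rdname lhyp2f1
#' @export
hyp2f1 <- function(a, b, c, z, tol = 1e-12, max_terms = 2e6) {
  exp(lhyp2f1(a, b, c, z, tol = tol, max_terms = max_terms))
}

# Direct series with positive terms, accumulated as a running log-sum-exp in
# chunks; returns NA if the truncation target is not met within max_terms.
.lhyp2f1_series <- function(a, b, c, z, tol, max_terms) {
  chunk <- 128L
  log_z <- log(z)
  lsum <- 0           # log of partial sum, term n = 0 contributes exp(0) = 1
  lterm0 <- 0         # log of the last term of the previous chunk
  n0 <- 0
  while (n0 < max_terms) {
    n <- n0 + seq_len(chunk) - 1L
    incr <- log(a + n) + log(b + n) + log_z - log(c + n) - log(n + 1)
    lterms <- lterm0 + cumsum(incr)   # log terms n0+1 .. n0+chunk
    m <- max(lsum, lterms)
    lsum <- m + log(exp(lsum - m) + sum(exp(lterms - m)))
    lterm0 <- lterms[chunk]
    n0 <- n0 + chunk
    # remaining tail is bounded by t_n * z / (1 - z)
    if (lterm0 < lsum + log(tol) + log1p(-z)) return(lsum)
    chunk <- min(chunk * 2L, 65536L)
  }
  NA_real_
}

# Fallback: log-scaled adaptive quadrature of the Euler integral
#   2F1(a,b;c;z) = 1/B(b, c-b) int_0^1 u^{b-1} (1-u)^{c-b-1} (1-z u)^{-a} du
.lhyp2f1_quad <- function(a, b, c, z) {
  logf <- function(u) {
    (b - 1) * log(u) + (c - b - 1) * log1p(-u) - a * log1p(-z * u)
  }
  grid <- seq(1e-9, 1 - 1e-9, length.out = 2001)
  shift <- max(logf(grid))
  val <- stats::integrate(function(u) exp(logf(u) - shift), 0, 1,
                          rel.tol = 1e-10, abs.tol = 0,
                          subdivisions = 500L)
  if (val$message != "OK") stop("2F1 quadrature fallback failed", call. = FALSE)
  shift + log(val$value) - lbeta(b, c - b)
}
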
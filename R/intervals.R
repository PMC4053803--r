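#' Credible intervals for regional methylation levels
#'
#' Three interval types are available for the closed-form posterior of a bin:
#'
#' * `hpd_interval()` — highest posterior density: the shortest interval
#'   holding the requested posterior mass, found by minimizing
#'   `Q(t + level) - Q(t)` over `t` with `Q` the gridded posterior quantile
#'   function. For a unimodal posterior this is the density superlevel set;
#'   when that set is a union of disjoint intervals (or split point masses)
#'   the smallest single covering interval is returned and
#'   `multimodal = TRUE` is flagged. Point masses at 0/1 are absorbed at
#'   their exact locations.
#' * `quantile_interval()` — equal-tailed: posterior quantiles at
#'   \eqn{(1-\gamma)/2} and \eqn{1-(1-\gamma)/2}. Atoms can pin a bound to
#'   exactly 0 or 1.
#' * `wald_interval()` — delta-method interval on the logit scale:
#'   \eqn{\mathrm{logit}(\hat\mu) \pm z_\gamma \, \hat\sigma} with
#'   \eqn{\hat\sigma = \sqrt{\mathrm{Var}(\mu)} / (\hat\mu (1 - \hat\mu))},
#'   transformed back; bounds are therefore always inside (0, 1).
#'
#' @param posterior A [meth_posterior()] object.
#' @param level Credibility level in (0, 1); default 0.95.
#' @param grid_points Number of grid cells used for the numeric interval
#'   types.
#' @return A tibble with columns `lo`, `hi`, `level` (and `multimodal` for
#'   HPD).
#' @examples
#' p <- meth_posterior(4, 12, alpha = 2, beta = 1, e = 1)
#' hpd_interval(p)
#' quantile_interval(p)
#' wald_interval(p$mean, p$variance)
#' @name credible_intervals
NULL

# grid representation: midpoint-rule cell masses + atoms at the exact ends
# (midpoints avoid evaluating the density at 0/1, where beta components with
# shape < 1 diverge)
.post_grid <- function(posterior, grid_points) {
  # first pass: coarse uniform scan to locate the posterior mass
  mu0 <- seq(0, 1, length.out = 1025)
  mid0 <- (mu0[-1] + mu0[-1025]) / 2
  d0 <- posterior$density(mid0)
  d0[!is.finite(d0)] <- max(d0[is.finite(d0)], 1) * 1e6
  cdf0 <- c(0, cumsum(d0 * diff(mu0)))
  cdf0 <- cdf0 / max(cdf0[1025], 1e-300)
  # second pass: half the nodes uniform, half spaced at equal posterior mass
  qs <- stats::approx(cdf0, mu0, xout = seq(0, 1, length.out = grid_points %/% 2),
                      ties = "ordered")$y
  # geometric refinement toward 0 and 1 resolves integrable endpoint
  # singularities of beta components with shape < 1
  edge <- 10^seq(log10(0.5 / grid_points), -12, length.out = 40)
  mu <- sort(unique(c(seq(0, 1, length.out = grid_points %/% 2 + 1), qs,
                      edge, 1 - edge)))
  mid <- (mu[-1] + mu[-length(mu)]) / 2
  d <- posterior$density(mid)
  d[!is.finite(d)] <- max(d[is.finite(d)], 1) * 1e6
  cell <- d * diff(mu)
  s <- sum(cell)
  if (s > 0) cell <- cell * posterior$cont_weight / s
  list(mu = mu, dens = d, cell = cell)
}

#' @rdname credible_intervals
#' @export
hpd_interval <- function(posterior, level = 0.95, grid_points = 2048) {
  stopifnot(inherits(posterior, "meth_posterior"), level > 0, level < 1)
  # a single atom can satisfy the level by itself: degenerate interval
  if (max(posterior$atom0, posterior$atom1) >= level) {
    at1 <- posterior$atom1 >= posterior$atom0
    return(tibble::tibble(lo = as.numeric(at1), hi = as.numeric(at1),
                          level = level, multimodal = FALSE))
  }
  g <- .post_grid(posterior, grid_points)
  a0 <- posterior$atom0; a1 <- posterior$atom1
  # shortest interval [Q(t), Q(t + level)] over t, with Q the posterior
  # quantile function (piecewise-linear CDF inversion, atoms at 0/1)
  cdf <- a0 + c(0, cumsum(g$cell))
  total <- cdf[length(cdf)] + a1
  qf <- function(p) {
    p <- p * total
    out <- numeric(length(p))
    out[p >= cdf[length(cdf)]] <- 1
    mid <- p > a0 & p < cdf[length(cdf)]
    if (any(mid)) {
      i <- findInterval(p[mid], cdf, rightmost.closed = TRUE)
      lo <- g$mu[i]
      out[mid] <- lo + (g$mu[i + 1] - lo) * (p[mid] - cdf[i]) /
        pmax(cdf[i + 1] - cdf[i], 1e-300)
    }
    out
  }
  t_grid <- seq(0, 1 - level, length.out = 1024)
  widths <- qf(t_grid + level) - qf(t_grid)
  t0 <- t_grid[which.min(widths)]
  opt <- stats::optimize(function(t) qf(t + level) - qf(t),
                         lower = max(0, t0 - 2 / 1024),
                         upper = min(1 - level, t0 + 2 / 1024))
  lo <- qf(opt$minimum); hi <- qf(opt$minimum + level)
  # flag when the equivalent density superlevel set is not one interval
  ord <- order(g$dens, decreasing = TRUE)
  cum <- a0 + a1 + cumsum(g$cell[ord])
  k <- which(cum >= level - 1e-12)[1]
  sel <- logical(length(ord))
  sel[ord[seq_len(if (is.na(k)) length(ord) else k)]] <- TRUE
  multimodal <- sum(rle(sel)$values) > 1 ||
    (a0 > 0 && a1 > 0 && lo > 0 && hi < 1)
  tibble::tibble(lo = lo, hi = hi, level = level, multimodal = multimodal)
}

#' @rdname credible_intervals
#' @export
quantile_interval <- function(posterior, level = 0.95, grid_points = 2048) {
  stopifnot(inherits(posterior, "meth_posterior"), level > 0, level < 1)
  q <- .post_quantiles(posterior, c((1 - level) / 2, 1 - (1 - level) / 2),
                       grid_points)
  tibble::tibble(lo = q[1], hi = q[2], level = level)
}

# posterior quantiles by monotone inversion of the gridded CDF (atoms at 0/1)
.post_quantiles <- function(posterior, probs, grid_points = 2048) {
  g <- .post_grid(posterior, grid_points)
  cdf <- posterior$atom0 + c(0, cumsum(g$cell))   # CDF at grid nodes
  total <- cdf[length(cdf)] + posterior$atom1
  vapply(probs, function(p) {
    p <- p * total
    if (p <= posterior$atom0) return(0)
    if (p >= cdf[length(cdf)]) return(1)
    i <- findInterval(p, cdf, rightmost.closed = TRUE)
    lo <- g$mu[i]
    step <- g$mu[i + 1] - lo
    lo + step * (p - cdf[i]) / max(cdf[i + 1] - cdf[i], 1e-300)
  }, numeric(1))
}

#' @rdname credible_intervals
#' @param mean,variance Analytic posterior mean and variance, e.g. from
#'   [posterior_moments()].
#' @export
wald_interval <- function(mean, variance, level = 0.95) {
  stopifnot(level > 0, level < 1, all(variance >= 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  degenerate <- mean <= 0 | mean >= 1
  m <- pmin(pmax(mean, 1e-12), 1 - 1e-12)
  sig <- sqrt(variance) / (m * (1 - m))
  lg <- stats::qlogis(m)
  tibble::tibble(
    lo = ifelse(degenerate, mean, stats::plogis(lg - z * sig)),
    hi = ifelse(degenerate, mean, stats::plogis(lg + z * sig)),
    level = level,
    degenerate = degenerate
  )
}

#' Credible intervals of several types at once
#'
#' Convenience wrapper computing any subset of HPD, quantile and Wald
#' intervals for one bin posterior, in the wide column layout used by
#' [quantify_methylation()] (`hpd_lo`, `hpd_hi`, ...).
#'
#' @inheritParams credible_intervals
#' @param types Character subset of `c("hpd", "quantile", "wald")`.
#' @return A one-row tibble with `<type>_lo` / `<type>_hi` columns.
#' @export
credible_intervals <- function(posterior, types = c("hpd", "quantile", "wald"),
                               level = 0.95, grid_points = 2048) {
  types <- match.arg(types, several.ok = TRUE)
  out <- tibble::tibble(.rows = 1)
  if ("hpd" %in% types) {
    h <- hpd_interval(posterior, level, grid_points)
    out$hpd_lo <- h$lo; out$hpd_hi <- h$hi
  }
  if ("quantile" %in% types) {
    q <- quantile_interval(posterior, level, grid_points)
    out$quantile_lo <- q$lo; out$quantile_hi <- q$hi
  }
  if ("wald" %in% types) {
    w <- wald_interval(posterior$mean, posterior$variance, level)
    out$wald_lo <- w$lo; out$wald_hi <- w$hi
  }
  out
}
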
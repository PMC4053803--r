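#' Closed-form posterior machinery for regional methylation levels
#'
#' The observation model for a genomic bin is
#' \deqn{y_S \mid \mu, \lambda \sim \mathrm{Poisson}(E \mu \lambda), \qquad
#'       y_C \mid \lambda \sim \mathrm{Poisson}(\lambda),}
#' where \eqn{y_S} is the read count of the sample of interest, \eqn{y_C} the
#' count of the fully methylated (SssI) control, \eqn{\lambda \sim
#' \mathrm{Ga}(\alpha, \beta)} the region-specific read density at full
#' methylation, \eqn{\mu \in (0,1)} the regional methylation level, and
#' \eqn{E = f \cdot cn / ccn} the effective multiplier combining the library
#' normalization offset \eqn{f} with the copy-number ratio. Integrating
#' \eqn{\lambda} out gives a marginal posterior for \eqn{\mu} in closed form
#' involving the Gauss hypergeometric function; all moments are ratios of
#' \eqn{{}_2F_1} values and no sampling is required.
#'
#' When `y_c` is `NULL` the SssI-free variant is used: only the Poisson model
#' for the sample of interest is kept, and identifiability comes from the
#' gamma and beta priors.
#'
#' All computations are carried out in log space; the functions are
#' vectorized over bins (`y_s`, `y_c`, `e` are recycled to a common length)
#' and deduplicate repeated `(y_s, y_c, e)` tuples internally.
#'
#' @param y_s Non-negative integer counts for the sample of interest.
#' @param y_c Non-negative integer counts for the SssI control, or `NULL` for
#'   the SssI-free model.
#' @param alpha,beta Gamma prior shape and rate for the read density (both
#'   positive scalars).
#' @param e Effective multiplier \eqn{E = f \, cn / ccn} per bin (positive;
#'   recycled).
#' @param prior A [meth_prior()] with concrete shape parameters.
#' @return `log_marginal_likelihood()`: numeric vector of
#'   \eqn{\log p(y_S, y_C)} (or \eqn{\log p(y_S)}).
#'   `posterior_moments()`: tibble with columns `mean`, `variance`, `atom0`,
#'   `atom1` (posterior point-mass weights at 0 and 1).
#' @examples
#' # closed-form identity: p(0, 0) = log(3/2) for alpha = beta = E = 1
#' log_marginal_likelihood(0, 0, alpha = 1, beta = 1, e = 1)
#' posterior_moments(5, 10, alpha = 2, beta = 1, e = 1)
#' @name posterior
NULL

# scalar core: everything the posterior of one (y_s, y_c, e) tuple needs.
# y_c = NA -> SssI-free. Returns list(lmarg, atom0, atom1, wcomp, mean,
# variance, comp (tibble), dens_pars) with wcomp the posterior component
# weights of the continuous part.
.post_core <- function(y_s, y_c, alpha, beta, e, prior, need_moments = TRUE) {
  comp <- prior$components
  sssi <- !is.na(y_c)
  ylog_e <- if (y_s == 0) 0 else y_s * log(e)

  if (sssi) {
    cc <- alpha + y_s + y_c
    z <- e / (beta + 1 + e)
    base <- lgamma(cc) - lgamma(alpha) - lfactorial(y_s) - lfactorial(y_c) +
      alpha * log(beta) + ylog_e - cc * log(beta + 1 + e)
    lmom <- function(a, b, m) {   # log of E[mu^m] numerator integral
      lbeta(y_s + a + m, b) + lhyp2f1(cc, b, y_s + a + m + b, z)
    }
    latom0 <- if (y_s == 0) {
      stats::dnbinom(y_c, size = alpha, prob = beta / (beta + 1), log = TRUE)
    } else -Inf
    latom1 <- base
  } else {
    z <- -e / beta
    base <- lgamma(alpha + y_s) - lgamma(alpha) - lfactorial(y_s) +
      alpha * log(beta) + ylog_e - (alpha + y_s) * log(beta)
    lmom <- function(a, b, m) {
      lbeta(y_s + a + m, b) + lhyp2f1(alpha + y_s, y_s + a + m, y_s + a + m + b, z)
    }
    latom0 <- if (y_s == 0) 0 else -Inf
    latom1 <- stats::dnbinom(y_s, size = alpha, prob = beta / (beta + e),
                             log = TRUE)
  }

  ncomp <- nrow(comp)
  lm0 <- lm1 <- lm2 <- numeric(ncomp)
  for (j in seq_len(ncomp)) {
    a <- comp$a[j]; b <- comp$b[j]
    lm0[j] <- lmom(a, b, 0)
    if (need_moments) {
      lm1[j] <- lmom(a, b, 1)
      lm2[j] <- lmom(a, b, 2)
    }
  }
  lcomp <- base + lm0 - lbeta(comp$a, comp$b)   # component log marginals

  lw <- c(log(prior$w0) + latom0, log(prior$w1) + latom1,
          log(comp$weight) + lcomp)
  lw[is.nan(lw)] <- -Inf                         # 0-weight atoms
  lmarg <- .logsumexp(lw)
  w <- exp(lw - lmarg)
  atom0 <- w[1]; atom1 <- w[2]; wcomp <- w[-(1:2)]

  if (need_moments) {
    m1 <- atom1 + sum(wcomp * exp(lm1 - lm0))
    m2 <- atom1 + sum(wcomp * exp(lm2 - lm0))
    v <- m2 - m1^2
    if (v < 0) {
      if (v < -1e-12) warning("posterior variance clipped from ", v)
      v <- 0
    }
  } else m1 <- v <- NA_real_
  list(lmarg = lmarg, atom0 = atom0, atom1 = atom1, wcomp = wcomp,
       mean = m1, variance = v, z = z, base = base, lm0 = lm0,
       sssi = sssi, y_s = y_s, y_c = y_c, alpha = alpha, beta = beta, e = e,
       comp = comp)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# vectorize a scalar-core extractor over deduplicated (y_s, y_c, e) tuples
.post_apply <- function(y_s, y_c, alpha, beta, e, prior, extract,
                        need_moments = TRUE) {
  stopifnot(length(alpha) == 1, length(beta) == 1,
            alpha > 0, beta > 0, all(e >= 0),
            all(y_s >= 0), all(y_s == floor(y_s)))
  if (.prior_has_free_ab(prior)) {
    stop("prior has free (NA) shape parameters; fit or fix them first",
         call. = FALSE)
  }
  n <- max(length(y_s), length(e), length(y_c %||% 0))
  y_s <- rep_len(y_s, n)
  e <- rep_len(e, n)
  y_c <- if (is.null(y_c)) rep_len(NA_real_, n) else {
    stopifnot(all(y_c >= 0), all(y_c == floor(y_c)))
    rep_len(y_c, n)
  }
  key <- paste(y_s, y_c, e)
  uni <- !duplicated(key)
  res <- purrr::map(which(uni), function(i) {
    extract(.post_core(y_s[i], y_c[i], alpha, beta, e[i], prior,
                       need_moments = need_moments))
  })
  names(res) <- key[uni]
  res[key]
}

#' @rdname posterior
#' @export
log_marginal_likelihood <- function(y_s, y_c = NULL, alpha, beta, e = 1,
                                    prior = meth_prior("uniform")) {
  unlist(.post_apply(y_s, y_c, alpha, beta, e, prior,
                     function(core) core$lmarg, need_moments = FALSE),
         use.names = FALSE)
}

#' @rdname posterior
#' @export
posterior_moments <- function(y_s, y_c = NULL, alpha, beta, e = 1,
                              prior = meth_prior("uniform")) {
  res <- .post_apply(y_s, y_c, alpha, beta, e, prior, function(core) {
    c(core$mean, core$variance, core$atom0, core$atom1)
  })
  m <- unname(do.call(rbind, res))
  tibble::tibble(mean = m[, 1], variance = m[, 2],
                 atom0 = m[, 3], atom1 = m[, 4])
}

#' Posterior distribution object for a single bin
#'
#' Bundles the closed-form posterior of the methylation level of one bin:
#' point masses at 0 and 1 (when the prior places them there), the normalized
#' continuous density, and the analytic mean and variance. Interval functions
#' ([hpd_interval()], [quantile_interval()]) and [autoplot.meth_posterior()]
#' consume this object.
#'
#' @inheritParams posterior
#' @return An object of class `meth_posterior` with elements `mean`,
#'   `variance`, `atom0`, `atom1`, `cont_weight` and `density` (a function of
#'   `mu` returning the continuous part, normalized so that the continuous
#'   integral equals `cont_weight`... i.e. density + atoms integrate to 1).
#' @examples
#' p <- meth_posterior(3, 10, alpha = 2, beta = 1, e = 1)
#' p$mean
#' hpd_interval(p)
#' @export
meth_posterior <- function(y_s, y_c = NULL, alpha, beta, e = 1,
                           prior = meth_prior("uniform")) {
  stopifnot(length(y_s) == 1, is.null(y_c) || length(y_c) == 1)
  if (.prior_has_free_ab(prior)) {
    stop("prior has free (NA) shape parameters; fit or fix them first",
         call. = FALSE)
  }
  core <- .post_core(y_s, if (is.null(y_c)) NA_real_ else y_c,
                     alpha, beta, e, prior)
  dens <- function(mu) .post_density_cont(mu, core)
  structure(list(mean = core$mean, variance = core$variance,
                 atom0 = core$atom0, atom1 = core$atom1,
                 cont_weight = 1 - core$atom0 - core$atom1,
                 density = dens, core = core),
            class = "meth_posterior")
}

# continuous part of the posterior density at mu (vectorized in mu),
# normalized together with the atoms
.post_density_cont <- function(mu, core) {
  stopifnot(all(mu >= 0), all(mu <= 1))
  comp <- core$comp
  out <- rep(0, length(mu))
  inside <- mu > 0 & mu < 1
  m <- mu[inside]
  for (j in seq_len(nrow(comp))) {
    if (core$wcomp[j] == 0) next
    a <- comp$a[j]; b <- comp$b[j]
    if (core$sssi) {
      cc <- core$alpha + core$y_s + core$y_c
      ld <- (core$y_s + a - 1) * log(m) + (b - 1) * log1p(-m) -
        cc * log1p(-core$z * (1 - m)) - core$lm0[j]
    } else {
      ld <- (core$y_s + a - 1) * log(m) + (b - 1) * log1p(-m) -
        (core$alpha + core$y_s) * log1p(-core$z * m) - core$lm0[j]
    }
    out[inside] <- out[inside] + core$wcomp[j] * exp(ld)
  }
  out
}

#' @rdname posterior
#' @param mu Methylation levels in \[0, 1\] at which to evaluate the
#'   continuous part of the posterior density (for a single bin).
#' @export
posterior_density <- function(mu, y_s, y_c = NULL, alpha, beta, e = 1,
                              prior = meth_prior("uniform")) {
  meth_posterior(y_s, y_c, alpha, beta, e, prior)$density(mu)
}

#' @export
print.meth_posterior <- function(x, ...) {
  cat(sprintf("<meth_posterior> mean %.4f sd %.4f", x$mean, sqrt(x$variance)))
  if (x$atom0 > 0 || x$atom1 > 0) {
    cat(sprintf("  atoms: P(mu=0) = %.3f, P(mu=1) = %.3f", x$atom0, x$atom1))
  }
  cat("\n")
  invisible(x)
}
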
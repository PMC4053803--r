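# Independent numerical oracles used across the suite. They integrate the
# raw Poisson x Poisson x gamma x prior model directly (log-scaled adaptive
# quadrature), never touching the closed-form 2F1 path under test.

# log of the mu-kernel: log integral over lambda of the likelihood times the
# gamma density, at a single mu (mu = 0/1 allowed; prior factor NOT included)
.oracle_log_inner <- function(mu, y_s, y_c, alpha, beta, e) {
  lg <- function(l) {
    out <- dpois(y_s, e * mu * l, log = TRUE) +
      dgamma(l, alpha, rate = beta, log = TRUE)
    if (!is.null(y_c)) out <- out + dpois(y_c, l, log = TRUE)
    out
  }
  grid <- exp(seq(log(1e-7), log(1e6), length.out = 600))
  shift <- max(lg(grid))
  if (!is.finite(shift)) return(-Inf)
  v <- stats::integrate(function(l) exp(lg(l) - shift), 0, Inf,
                        rel.tol = 1e-11, abs.tol = 0, subdivisions = 400L,
                        stop.on.error = FALSE)$value
  shift + log(v)
}

# marginal likelihood, posterior mean/variance and atom weights by direct
# quadrature of the generative model, entirely in log scale
oracle_posterior <- function(y_s, y_c, alpha, beta, e,
                             prior = meth_prior("uniform")) {
  logprior <- function(mu) log(methquant:::.dmeth_prior_cont(mu, prior))
  logker <- function(mu) {
    vapply(mu, function(m) {
      .oracle_log_inner(m, y_s, y_c, alpha, beta, e) + logprior(m)
    }, numeric(1))
  }
  mu_grid <- c(1e-6, seq(0.005, 0.995, length.out = 200), 1 - 1e-6)
  shift <- max(logker(mu_grid))
  la0 <- if (prior$w0 > 0) {
    log(prior$w0) + .oracle_log_inner(0, y_s, y_c, alpha, beta, e)
  } else -Inf
  la1 <- if (prior$w1 > 0) {
    log(prior$w1) + .oracle_log_inner(1, y_s, y_c, alpha, beta, e)
  } else -Inf
  shift <- max(shift, la0, la1)
  iq <- function(f) {
    stats::integrate(function(m) f(m) * exp(logker(m) - shift), 0, 1,
                     rel.tol = 1e-10, abs.tol = 0, subdivisions = 400L,
                     stop.on.error = FALSE)$value
  }
  z0 <- iq(function(m) 1)
  a0 <- exp(la0 - shift); a1 <- exp(la1 - shift)
  marg <- z0 + a0 + a1
  m1 <- (iq(function(m) m) + a1) / marg
  m2 <- (iq(function(m) m^2) + a1) / marg
  list(lmarg = shift + log(marg), mean = m1, variance = m2 - m1^2,
       atom0 = a0 / marg, atom1 = a1 / marg)
}

# brute-force shortest-window HPD on a fixed grid: for every left endpoint
# find the smallest right endpoint accumulating `level` mass
oracle_hpd <- function(posterior, level, grid_points = 2048) {
  mu <- seq(0, 1, length.out = grid_points + 1)
  d <- posterior$density(mu)
  d[!is.finite(d)] <- max(d[is.finite(d)]) * 1e6
  cell <- (d[-1] + d[-length(d)]) / 2 * diff(mu)
  cell <- cell * posterior$cont_weight / sum(cell)
  cum <- c(0, cumsum(cell))
  nn <- length(mu)
  best <- c(lo = 0, hi = 1, width = 1)
  for (i in seq_len(nn)) {
    target <- level - (if (i == 1) posterior$atom0 else 0)
    j <- which(cum >= cum[i] + target)
    j <- j[j > i]
    if (length(j) == 0) {
      # interval must run to 1 and absorb the upper atom
      if (cum[nn] - cum[i] + posterior$atom1 >= target) j <- nn else next
    } else j <- j[1]
    w <- mu[j] - mu[i]
    if (w < best["width"]) best <- c(lo = mu[i], hi = mu[j], width = w)
  }
  best[c("lo", "hi")]
}

# random concrete prior of each family; smooth = TRUE keeps beta shapes
# >= 1 (no density singularities at the endpoints)
random_prior <- function(kind, smooth = FALSE) {
  lo <- if (smooth) 1 else 0.5
  switch(kind,
    uniform = meth_prior("uniform"),
    beta_mixture = meth_prior("beta_mixture",
                              weights = c(0.4, 0.6),
                              a = runif(2, lo, 4), b = runif(2, lo, 4)),
    dbd = meth_prior("dbd", a = runif(1, lo, 4), b = runif(1, lo, 4),
                     w0 = runif(1, 0.02, 0.2), w1 = runif(1, 0.02, 0.2))
  )
}

# faster oracle: lambda integrated analytically (elementary gamma integral,
# no hypergeometric functions), mu by adaptive quadrature in log scale
oracle_posterior_fast <- function(y_s, y_c, alpha, beta, e,
                                  prior = meth_prior("uniform")) {
  sssi <- !is.null(y_c)
  logk <- if (sssi) {
    cc <- alpha + y_s + y_c
    function(mu) {
      lgamma(cc) - lgamma(alpha) - lfactorial(y_s) - lfactorial(y_c) +
        alpha * log(beta) + ifelse(y_s == 0 & mu == 0, 0, y_s * log(e * mu)) -
        cc * log(beta + 1 + e * mu) +
        log(methquant:::.dmeth_prior_cont(mu, prior))
    }
  } else {
    function(mu) {
      lgamma(alpha + y_s) - lgamma(alpha) - lfactorial(y_s) +
        alpha * log(beta) + ifelse(y_s == 0 & mu == 0, 0, y_s * log(e * mu)) -
        (alpha + y_s) * log(beta + e * mu) +
        log(methquant:::.dmeth_prior_cont(mu, prior))
    }
  }
  lik_at <- function(mu) {   # likelihood of the atoms, same closed algebra
    if (sssi) {
      if (mu == 0) {
        if (y_s > 0) return(-Inf)
        dnbinom(y_c, size = alpha, prob = beta / (beta + 1), log = TRUE)
      } else {
        cc <- alpha + y_s + y_c
        lgamma(cc) - lgamma(alpha) - lfactorial(y_s) - lfactorial(y_c) +
          alpha * log(beta) + y_s * log(e) - cc * log(beta + 1 + e)
      }
    } else {
      if (mu == 0) return(if (y_s > 0) -Inf else 0)
      dnbinom(y_s, size = alpha, prob = beta / (beta + e), log = TRUE)
    }
  }
  grid <- seq(1e-6, 1 - 1e-6, length.out = 512)
  shift <- max(logk(grid))
  la0 <- if (prior$w0 > 0) log(prior$w0) + lik_at(0) else -Inf
  la1 <- if (prior$w1 > 0) log(prior$w1) + lik_at(1) else -Inf
  shift <- max(shift, la0, la1)
  iq <- function(f) {
    stats::integrate(function(m) f(m) * exp(logk(m) - shift), 0, 1,
                     rel.tol = 1e-11, abs.tol = 0, subdivisions = 400L,
                     stop.on.error = FALSE)$value
  }
  z0 <- iq(function(m) 1)
  a0 <- exp(la0 - shift); a1 <- exp(la1 - shift)
  marg <- z0 + a0 + a1
  m1 <- (iq(function(m) m) + a1) / marg
  m2 <- (iq(function(m) m^2) + a1) / marg
  list(lmarg = shift + log(marg), mean = m1, variance = m2 - m1^2,
       atom0 = a0 / marg, atom1 = a1 / marg)
}
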
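test_that("high-count masking flags only class-wise outliers", {
  cnt <- tibble::tibble(y_s = rep(5, 100), y_c = rep(8, 100),
                        cpg_class = rep(1:2, 50))
  expect_false(any(mask_high_counts(cnt)))
  cnt$y_s[7] <- 1e6
  m <- mask_high_counts(cnt)
  expect_identical(which(m), 7L)
  # order-statistics bound on the masked fraction per class
  set.seed(91)
  cnt2 <- tibble::tibble(y_s = rpois(2000, 20), y_c = rpois(2000, 30),
                         cpg_class = rep(1:4, each = 500))
  q <- 0.98
  m2 <- mask_high_counts(cnt2, mask_quantile = q)
  for (k in 1:4) {
    n_k <- 500
    frac <- mean(m2[cnt2$cpg_class == k])
    expect_lte(frac, 2 * (1 - q) + 2 / n_k)  # two count columns
  }
})

test_that("method-of-moments initializer reproduces the sample mean", {
  set.seed(92)
  y <- rnbinom(5000, size = 5, prob = 2 / 3)   # alpha = 5, beta = 2
  m <- mean(y); v <- var(y)
  beta0 <- m / (v - m); alpha0 <- m * beta0
  expect_equal(alpha0 / beta0, m)
})

test_that("empirical Bayes recovers the generating hyperparameters", {
  sim <- simulate_methylation_dataset(n_classes = 1, bins_per_class = 5000,
                                      alpha = 5, beta = 2, f = 1, seed = 93)
  fit <- fit_meth_model(sim, f = 1)
  expect_s3_class(fit, "meth_eb_fit")
  expect_true(all(fit$classes$converged))
  expect_lt(abs(fit$classes$alpha / 5 - 1), 0.1)
  expect_lt(abs(fit$classes$beta / 2 - 1), 0.1)
  # the optimum cannot be worse than the method-of-moments start
  m <- mean(sim$y_c); v <- var(sim$y_c)
  b0 <- m / (v - m); a0 <- m * b0
  ll0 <- sum(log_marginal_likelihood(sim$y_s, sim$y_c, alpha = a0, beta = b0,
                                     e = 1))
  expect_gte(fit$classes$loglik, ll0)
})

test_that("masking keeps one extreme outlier from moving the fit", {
  sim <- simulate_methylation_dataset(n_classes = 1, bins_per_class = 5000,
                                      alpha = 5, beta = 2, f = 1, seed = 94)
  fit0 <- fit_meth_model(sim, f = 1)
  spiked <- sim
  spiked$y_s[1] <- 1e6
  spiked$y_c[1] <- 1e6
  fit1 <- fit_meth_model(spiked, f = 1)
  expect_lt(abs(fit1$classes$alpha / fit0$classes$alpha - 1), 0.01)
  expect_lt(abs(fit1$classes$beta / fit0$classes$beta - 1), 0.01)
  expect_true(fit1$masked[1])
})

test_that("SssI-free fit recovers the generating count distribution", {
  # without a control the (alpha, beta, a, b) surface has a near-flat ridge:
  # very different parameter sets give almost the same marginal distribution
  # of y_s, so raw hyperparameter recovery is not a stable property at this
  # sample size. What maximum likelihood does guarantee is (i) a fit at
  # least as likely as the truth on the fitting data and (ii) a fitted
  # marginal close to the generating one in total variation.
  prior <- meth_prior("dbd", a = 2, b = 2, w0 = 0.1, w1 = 0.1)
  sim <- simulate_methylation_dataset(n_classes = 1, bins_per_class = 10000,
                                      alpha = 4, beta = 1, prior = prior,
                                      f = 30, with_sssi = FALSE, seed = 95)
  fit <- fit_meth_model(sim, prior = meth_prior("dbd", w0 = 0.1, w1 = 0.1),
                        f = 30)
  expect_equal(fit$mode, "sssi_free")
  expect_true(fit$classes$converged)
  d <- dplyr::count(sim, .data$y_s)
  ll_truth <- sum(d$n * log_marginal_likelihood(d$y_s, NULL, alpha = 4,
                                                beta = 1, e = 30,
                                                prior = prior))
  expect_gte(fit$classes$loglik, ll_truth)
  fitted_prior <- meth_prior("dbd", a = fit$classes$a, b = fit$classes$b,
                             w0 = 0.1, w1 = 0.1)
  y <- 0:3000
  p_fit <- exp(log_marginal_likelihood(y, NULL, alpha = fit$classes$alpha,
                                       beta = fit$classes$beta, e = 30,
                                       prior = fitted_prior))
  p_true <- exp(log_marginal_likelihood(y, NULL, alpha = 4, beta = 1, e = 30,
                                        prior = prior))
  expect_lt(sum(abs(p_fit - p_true)) / 2, 0.02)   # total variation
})

test_that("small classes merge into their nearest density neighbor", {
  sim <- simulate_methylation_dataset(n_classes = 3, bins_per_class = 200,
                                      alpha = c(2, 2, 6), beta = c(1, 1, 1),
                                      seed = 96)
  sim$cpg_class[sim$cpg_class == 2][1:180] <- 1L   # leave class 2 with 20 bins
  fit <- fit_meth_model(sim, f = 1, min_class_bins = 50)
  cls <- fit$classes
  expect_equal(cls$fit_class[cls$cpg_class == 2], 1)
  expect_equal(cls$alpha[cls$cpg_class == 2], cls$alpha[cls$cpg_class == 1])
  expect_equal(nrow(cls), 3)
})

test_that("prior predictive matches gamma-Poisson Monte Carlo", {
  pp <- prior_predictive_sssi(5, 2)
  expect_equal(pp$mean, 2.5)
  expect_equal(pp$variance, 3.75)
  set.seed(97)
  draws <- rpois(1e6, rgamma(1e6, 5, rate = 2))
  expect_equal(mean(draws), pp$mean, tolerance = 0.01)
  expect_equal(var(draws), pp$variance, tolerance = 0.01)
  expect_equal(pp$quantile(0.5), qnbinom(0.5, size = 5, prob = 2 / 3))
})

test_that("fitted models serialize to TSV and restore identically", {
  sim <- simulate_methylation_dataset(n_classes = 2, bins_per_class = 300,
                                      seed = 98)
  fit <- fit_meth_model(sim, f = 1.3)
  path <- tempfile(fileext = ".tsv")
  write_meth_fit(fit, path)
  back <- read_meth_fit(path)
  expect_equal(back$classes$alpha, fit$classes$alpha)
  expect_equal(back$classes$beta, fit$classes$beta)
  expect_equal(back$f, fit$f)
  expect_equal(back$mode, fit$mode)
  g <- glance(fit)
  expect_equal(g$k, 2L)
  td <- tidy(fit)
  expect_equal(td$pp_mean, td$alpha / td$beta)
})

test_that("degenerate all-zero classes are reported as non-identifiable", {
  cnt <- tibble::tibble(y_s = rep(0L, 200), cpg_class = 1L)
  fit <- suppressWarnings(
    fit_meth_model(cnt, prior = meth_prior("dbd", a = 1, b = 1,
                                           w0 = 0.98, w1 = 0.01),
                   f = 1))
  # likelihood nearly flat in (alpha, beta): fit must not blow up
  expect_true(is.finite(fit$classes$alpha))
  expect_true(is.finite(fit$classes$beta))
})
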
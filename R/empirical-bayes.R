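#' Flag unusually high counts before hyperparameter fitting
#'
#' Within each CpG-density class, bins whose sample or control count exceeds
#' the class-specific empirical `mask_quantile` (default 0.999, nearest-rank)
#' are flagged. Flagged bins are excluded from the empirical Bayes fit —
#' extreme counts (often unannotated copy-number gains) destabilize the
#' optimization — but still receive methylation estimates downstream.
#'
#' @param counts Tibble with `y_s`, optionally `y_c`, and `cpg_class`.
#' @param mask_quantile Class-wise quantile above which counts are masked.
#' @return Logical vector, `TRUE` for masked bins.
#' @export
mask_high_counts <- function(counts, mask_quantile = 0.999) {
  stopifnot(mask_quantile > 0, mask_quantile < 1,
            all(c("y_s", "cpg_class") %in% names(counts)))
  has_c <- "y_c" %in% names(counts)
  mask <- logical(nrow(counts))
  for (k in unique(counts$cpg_class)) {
    idx <- which(counts$cpg_class == k)
    # interpolated quantile: a single extreme outlier is masked even in
    # small classes, while constant counts never are
    thr_s <- stats::quantile(counts$y_s[idx], mask_quantile, names = FALSE)
    m <- counts$y_s[idx] > thr_s
    if (has_c) {
      thr_c <- stats::quantile(counts$y_c[idx], mask_quantile, names = FALSE)
      m <- m | counts$y_c[idx] > thr_c
    }
    mask[idx] <- m
  }
  mask
}

#' Empirical Bayes fit of the per-class read-density priors
#'
#' Estimates, separately for each CpG-density class, the gamma prior
#' \eqn{\lambda \sim \mathrm{Ga}(\alpha_k, \beta_k)} of the region-specific
#' read density — and, when the methylation prior has free Beta shape
#' parameters, those as well — by maximizing the analytic marginal likelihood
#' of the observed counts over the class's bins. With a SssI control the
#' joint marginal \eqn{p(y_S, y_C)} is used; without one, the SssI-free
#' marginal \eqn{p(y_S)}.
#'
#' Optimization is Nelder-Mead over log-parameters with random restarts
#' around a method-of-moments initializer (for the control counts,
#' \eqn{\beta_0 = m / \max(v - m, \epsilon)}, \eqn{\alpha_0 = m \beta_0}).
#' Classes with fewer than `min_class_bins` unmasked bins are merged into
#' their nearest density neighbor. Unusually high counts are masked first
#' (see [mask_high_counts()]).
#'
#' @param counts Tibble with `y_s`, `cpg_class`, optionally `y_c` (presence
#'   selects the SssI-aware model) and `cn`.
#' @param prior A [meth_prior()]; `NA` shape parameters are estimated.
#'   Defaults to uniform with a control, Dirac-Beta-Dirac with weights
#'   (0.1, 0.8, 0.1) and free shapes without.
#' @param f Normalization offset (already estimated; it is not refit here).
#' @param ccn Reference copy-number state; with a `cn` column the per-bin
#'   multiplier is `f * cn / ccn`, otherwise `f`.
#' @param mask_quantile Passed to [mask_high_counts()].
#' @param min_class_bins Minimum unmasked bins per class before merging.
#' @param ab_shared In SssI-free mode, share the fitted Beta shapes across
#'   classes (block-coordinate ascent); per-class otherwise. `NULL` picks the
#'   mode default (shared only for SssI-free).
#' @param restarts Random restarts around the initializer.
#' @param reltol Relative convergence tolerance of the optimizer.
#' @return An object of class `meth_eb_fit`: per-class tibble `classes`
#'   (alpha, beta, a, b, w0, w1, n_bins, n_masked, converged, loglik,
#'   merged_into), the resolved `prior`, `mode`, `f` and `ccn`.
#' @export
fit_meth_model <- function(counts, prior = NULL, f = 1, ccn = NULL,
                           mask_quantile = 0.999, min_class_bins = 50,
                           ab_shared = NULL, restarts = 3, reltol = 1e-8) {
  stopifnot(all(c("y_s", "cpg_class") %in% names(counts)))
  sssi <- "y_c" %in% names(counts)
  if (is.null(prior)) {
    prior <- if (sssi) meth_prior("uniform") else
      meth_prior("dbd", w0 = 0.1, w1 = 0.1)
  }
  if (is.null(ab_shared)) ab_shared <- !sssi && .prior_has_free_ab(prior)
  e <- if ("cn" %in% names(counts) && !is.null(ccn)) {
    combined_offsets(f, ccn, counts$cn)
  } else rep(f, nrow(counts))

  masked <- mask_high_counts(counts, mask_quantile)
  dat <- tibble::tibble(y_s = counts$y_s,
                        y_c = if (sssi) counts$y_c else NA_real_,
                        e = e, cpg_class = counts$cpg_class)[!masked, ]

  # merge small classes toward the nearest density neighbor
  sizes <- table(factor(dat$cpg_class))
  classes <- sort(unique(counts$cpg_class))
  merged_into <- stats::setNames(classes, classes)
  eff <- stats::setNames(as.numeric(sizes[as.character(classes)]), classes)
  eff[is.na(eff)] <- 0
  repeat {
    small <- names(eff)[eff < min_class_bins]
    if (length(small) == 0 || length(eff) == 1) break
    k <- small[1]
    others <- setdiff(names(eff), k)
    nb <- others[which.min(abs(as.numeric(others) - as.numeric(k)))]
    eff[nb] <- eff[nb] + eff[k]
    eff <- eff[names(eff) != k]
    merged_into[merged_into == as.numeric(k)] <- as.numeric(nb)
  }
  fit_class_of <- merged_into[as.character(dat$cpg_class)]

  fit_groups <- sort(unique(as.numeric(merged_into)))
  fit_one_group <- function(k, prior_k) {
    d <- dplyr::count(dat[fit_class_of == k, ], .data$y_s, .data$y_c, .data$e)
    .fit_class(d, prior_k, sssi, restarts, reltol)
  }

  if (ab_shared && .prior_has_free_ab(prior) && length(fit_groups) > 1) {
    # block-coordinate ascent: per-class (alpha, beta) given shared (a, b),
    # then shared (a, b) given all class parameters
    ab <- c(1, 1)
    fits <- NULL
    for (round in 1:3) {
      prior_ab <- .prior_fill_ab(prior, ab[1], ab[2])
      fits <- purrr::map(fit_groups, fit_one_group, prior_k = prior_ab)
      names(fits) <- fit_groups
      obj_ab <- function(lab) {
        -sum(purrr::map_dbl(seq_along(fit_groups), function(i) {
          k <- fit_groups[i]
          d <- dplyr::count(dat[fit_class_of == k, ],
                            .data$y_s, .data$y_c, .data$e)
          pr <- .prior_fill_ab(prior, exp(lab[1]), exp(lab[2]))
          .class_loglik(d, fits[[i]]$alpha, fits[[i]]$beta, pr, sssi)
        }))
      }
      op <- stats::optim(log(ab), obj_ab, method = "Nelder-Mead",
                         control = list(reltol = reltol, maxit = 500))
      ab <- exp(op$par)
    }
    prior <- .prior_fill_ab(prior, ab[1], ab[2])
    fits <- purrr::map(fit_groups, fit_one_group, prior_k = prior)
    names(fits) <- fit_groups
    for (i in seq_along(fits)) { fits[[i]]$a <- ab[1]; fits[[i]]$b <- ab[2] }
  } else {
    fits <- purrr::map(fit_groups, fit_one_group, prior_k = prior)
    names(fits) <- fit_groups
  }

  n_bins <- table(factor(counts$cpg_class, levels = classes))
  n_masked <- table(factor(counts$cpg_class[masked], levels = classes))
  cls <- tibble::tibble(
    cpg_class = classes,
    fit_class = as.numeric(merged_into[as.character(classes)]),
    alpha = unname(purrr::map_dbl(.data_chr(fits, classes, merged_into),
                                  "alpha")),
    beta = unname(purrr::map_dbl(.data_chr(fits, classes, merged_into),
                                 "beta")),
    a = unname(purrr::map_dbl(.data_chr(fits, classes, merged_into),
                              ~ .x$a %||% NA_real_)),
    b = unname(purrr::map_dbl(.data_chr(fits, classes, merged_into),
                              ~ .x$b %||% NA_real_)),
    w0 = prior$w0, w1 = prior$w1,
    n_bins = as.integer(n_bins),
    n_masked = as.integer(n_masked),
    converged = unname(purrr::map_lgl(.data_chr(fits, classes, merged_into),
                                      "converged")),
    loglik = unname(purrr::map_dbl(.data_chr(fits, classes, merged_into),
                                   "loglik"))
  )
  structure(list(classes = cls, prior = prior,
                 mode = if (sssi) "sssi" else "sssi_free",
                 f = f, ccn = ccn, mask_quantile = mask_quantile,
                 masked = masked),
            class = "meth_eb_fit")
}

.data_chr <- function(fits, classes, merged_into) {
  fits[as.character(merged_into[as.character(classes)])]
}

# deduplicated class log-likelihood; d has columns y_s, y_c, e, n
.class_loglik <- function(d, alpha, beta, prior, sssi) {
  ll <- log_marginal_likelihood(d$y_s, if (sssi) d$y_c else NULL,
                                alpha = alpha, beta = beta, e = d$e,
                                prior = prior)
  sum(d$n * ll)
}

.fit_class <- function(d, prior, sssi, restarts, reltol) {
  fit_ab <- .prior_has_free_ab(prior)
  # method-of-moments initializer
  ref <- if (sssi) rep(d$y_s * 0 + d$y_c, d$n) else rep(d$y_s / pmax(d$e, 1e-12) * 2, d$n)
  m <- mean(ref); v <- stats::var(ref)
  if (!is.finite(v) || v <= m) v <- m * 1.5 + 1e-6
  if (m <= 0) m <- 0.1
  beta0 <- m / max(v - m, 1e-6)
  alpha0 <- m * beta0
  p0 <- log(c(alpha0, beta0))
  if (fit_ab) p0 <- c(p0, 0, 0)   # a = b = 1

  obj <- function(p) {
    pr <- if (fit_ab) .prior_fill_ab(prior, exp(p[3]), exp(p[4])) else prior
    ll <- tryCatch(.class_loglik(d, exp(p[1]), exp(p[2]), pr, sssi),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  best <- NULL
  # restart perturbations from a private RNG stream so that fitting is
  # deterministic and does not disturb the caller's RNG state
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(140700)
  perturb <- purrr::map(seq_len(restarts),
                        ~ stats::rnorm(length(p0), 0, 0.5))
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old_seed, envir = globalenv())
  starts <- c(list(p0), purrr::map(perturb, ~ p0 + .x))
  for (s in starts) {
    op <- tryCatch(
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = 800)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) {
    return(list(alpha = alpha0, beta = beta0, a = NA_real_, b = NA_real_,
                converged = FALSE, loglik = -obj(p0)))
  }
  list(alpha = exp(best$par[1]), beta = exp(best$par[2]),
       a = if (fit_ab) exp(best$par[3]) else
         (prior$components$a[1] %||% NA_real_),
       b = if (fit_ab) exp(best$par[4]) else
         (prior$components$b[1] %||% NA_real_),
       converged = best$convergence == 0, loglik = -best$value)
}

#' Prior predictive distribution of the control counts
#'
#' Integrating the gamma read-density prior out of the Poisson model for the
#' fully methylated control yields a negative binomial distribution per CpG
#' class: size \eqn{\alpha}, success probability \eqn{\beta/(\beta+1)}, mean
#' \eqn{\alpha/\beta}, variance \eqn{\alpha(\beta+1)/\beta^2}. Useful for
#' checking the fitted priors against the observed control counts.
#'
#' @param alpha,beta Gamma prior shape and rate.
#' @return List with `size`, `prob`, `mean`, `variance` and `quantile` (a
#'   function of probabilities).
#' @examples
#' pp <- prior_predictive_sssi(5, 2)
#' pp$mean       # 2.5
#' pp$variance   # 3.75
#' pp$quantile(c(0.025, 0.975))
#' @export
prior_predictive_sssi <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  list(size = alpha, prob = beta / (beta + 1),
       mean = alpha / beta,
       variance = alpha * (beta + 1) / beta^2,
       quantile = function(p) stats::qnbinom(p, size = alpha,
                                             prob = beta / (beta + 1)))
}

#' Serialize / restore a fitted class model
#'
#' The fit is written as a plain TSV (one row per CpG class plus the run
#' metadata in extra columns), so a SssI-based fit can be reused across
#' samples captured under the same protocol.
#'
#' @param fit A `meth_eb_fit`.
#' @param path File path.
#' @return `write_meth_fit()`: `path` invisibly; `read_meth_fit()`: the
#'   restored `meth_eb_fit`.
#' @export
write_meth_fit <- function(fit, path) {
  stopifnot(inherits(fit, "meth_eb_fit"))
  tab <- dplyr::mutate(fit$classes,
                       mode = fit$mode, prior_kind = fit$prior$kind,
                       f = fit$f, ccn = fit$ccn %||% NA_integer_,
                       mask_quantile = fit$mask_quantile)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_meth_fit
#' @export
read_meth_fit <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- tab[1, c("mode", "prior_kind", "f", "ccn", "mask_quantile")]
  cls <- dplyr::select(tab, -dplyr::all_of(c("mode", "prior_kind", "f", "ccn",
                                             "mask_quantile")))
  prior <- switch(meta$prior_kind,
    uniform = meth_prior("uniform"),
    dbd = meth_prior("dbd", a = cls$a[1], b = cls$b[1],
                     w0 = cls$w0[1], w1 = cls$w1[1]),
    beta_mixture = meth_prior("beta_mixture", a = cls$a[1], b = cls$b[1]))
  structure(list(classes = cls, prior = prior, mode = meta$mode,
                 f = meta$f, ccn = if (is.na(meta$ccn)) NULL else meta$ccn,
                 mask_quantile = meta$mask_quantile, masked = NULL),
            class = "meth_eb_fit")
}

#' @export
print.meth_eb_fit <- function(x, ...) {
  cat(sprintf("<meth_eb_fit> mode: %s, prior: %s, f = %.4g, %d class(es)\n",
              x$mode, x$prior$kind, x$f, nrow(x$classes)))
  print(x$classes)
  invisible(x)
}
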
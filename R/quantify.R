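#' Quantify regional methylation from per-bin read counts
#'
#' End-to-end pipeline: filter bins by mappability, assign CpG-density
#' classes, estimate the normalization offset `f` (per mode and, when a `cn`
#' column is present, restricted to the reference copy-number state), fit or
#' reuse the per-class empirical Bayes hyperparameters, and compute the
#' closed-form posterior mean, variance and credible intervals of the
#' methylation level for every bin.
#'
#' Every input bin appears exactly once in the output with a `status`:
#' `"estimated"`, `"filtered_mappability"` (no estimate) or
#' `"masked_estimated"` (excluded from the hyperparameter fit but still
#' estimated). Bins with a control count of zero in SssI mode are estimated
#' — their wide posteriors carry the uncertainty — and flagged `no_capture`
#' rather than dropped: zero control reads mean the assay could not see the
#' bin, which the model distinguishes from low methylation.
#'
#' @param counts Tibble with `chrom`, `start`, `end`, `y_s`; optionally
#'   `y_c`, `cn`, `cpg_density`, `cpg_class`, `mappability`.
#' @param mode `"sssi"` (requires `y_c`) or `"sssi_free"` (ignores it).
#' @param prior A [meth_prior()]; defaults to uniform (sssi) or
#'   Dirac-Beta-Dirac with weights (0.1, 0.8, 0.1) and free shapes
#'   (sssi_free).
#' @param fit Optional precomputed [fit_meth_model()] result; when supplied
#'   the pipeline is restarted from it and `f`/hyperparameters are not
#'   re-estimated.
#' @param f Optional known normalization offset (estimated when `NULL`).
#' @param ccn Reference copy-number state (required with a `cn` column;
#'   default the most frequent state).
#' @param k_classes Number of CpG-density classes when `cpg_class` is absent.
#' @param map_threshold Minimum mappability (`>=`); bins below it are not
#'   estimated. Applied only when a `mappability` column exists.
#' @param mask_quantile High-count masking quantile for the fit.
#' @param ma_quantile,n_subsample,ma_min_bins,sssifree_quantile
#'   Offset-estimation settings (see [estimate_offset_f()]).
#' @param intervals Subset of `c("hpd", "quantile", "wald")`, or `NULL` for
#'   none.
#' @param level Credibility level.
#' @param grid_points Grid size for the numeric interval types.
#' @return A tibble: the input bin columns plus `status`, `mean`,
#'   `variance`, `atom0`, `atom1`, `no_capture`, and `<type>_lo`/`<type>_hi`
#'   per requested interval type. The fitted model is attached as attribute
#'   `fit` and the offset as attribute `f`.
#' @export
quantify_methylation <- function(counts, mode = c("sssi", "sssi_free"),
                                 prior = NULL, fit = NULL, f = NULL,
                                 ccn = NULL, k_classes = 100,
                                 map_threshold = 0.75, mask_quantile = 0.999,
                                 ma_quantile = 0.998, n_subsample = 50000,
                                 ma_min_bins = 100, sssifree_quantile = 0.99,
                                 intervals = c("hpd", "quantile", "wald"),
                                 level = 0.95, grid_points = 2048) {
  mode <- match.arg(mode)
  if (mode == "sssi" && !"y_c" %in% names(counts)) {
    stop("mode 'sssi' requires a y_c column", call. = FALSE)
  }
  work <- tibble::as_tibble(counts)
  if (mode == "sssi_free") work$y_c <- NULL

  status <- rep("estimated", nrow(work))
  if ("mappability" %in% names(work)) {
    status[work$mappability < map_threshold] <- "filtered_mappability"
  }
  usable <- status == "estimated"

  if (!"cpg_class" %in% names(work)) {
    if ("cpg_density" %in% names(work)) {
      work$cpg_class <- NA_integer_
      work$cpg_class[usable] <- assign_cpg_classes(work$cpg_density[usable],
                                                   k = k_classes)
    } else {
      work$cpg_class <- 1L
    }
  }

  has_cn <- "cn" %in% names(work)
  if (has_cn && is.null(ccn)) {
    if (!is.null(fit) && !is.null(fit$ccn)) ccn <- fit$ccn else {
      tab <- table(work$cn[usable])
      ccn <- as.integer(names(tab)[which.max(tab)])
    }
  }

  if (is.null(fit)) {
    if (is.null(f)) {
      f <- if (mode == "sssi") {
        as.numeric(estimate_offset_f(work[usable, ], q = ma_quantile,
                                     n_subsample = n_subsample,
                                     min_bins = ma_min_bins,
                                     ccn = if (has_cn) ccn else NULL))
      } else {
        estimate_offset_f_sssifree(work$y_s[usable],
                                   cn = if (has_cn) work$cn[usable] else NULL,
                                   ccn = ccn,
                                   sssifree_quantile = sssifree_quantile)
      }
    }
    message(sprintf("normalization offset f = %.4g", f))
    fit <- fit_meth_model(work[usable, ], prior = prior, f = f, ccn = ccn,
                          mask_quantile = mask_quantile)
    masked_usable <- fit$masked
    status[usable][masked_usable] <- "masked_estimated"
  } else {
    stopifnot(inherits(fit, "meth_eb_fit"))
    if (fit$mode != mode) stop("fit was made in mode ", fit$mode, call. = FALSE)
    f <- fit$f
  }

  e_bin <- if (has_cn) combined_offsets(fit$f, ccn %||% 1, work$cn) else
    rep(fit$f, nrow(work))

  out <- work
  out$status <- status
  out$mean <- NA_real_
  out$variance <- NA_real_
  out$atom0 <- NA_real_
  out$atom1 <- NA_real_
  out$no_capture <- FALSE
  if (mode == "sssi") out$no_capture <- !is.na(work$y_c) & work$y_c == 0
  for (type in intervals) {
    out[[paste0(type, "_lo")]] <- NA_real_
    out[[paste0(type, "_hi")]] <- NA_real_
  }

  est <- which(status != "filtered_mappability")
  cls_tab <- fit$classes
  for (k in unique(work$cpg_class[est])) {
    row <- cls_tab[cls_tab$cpg_class == k, ]
    if (nrow(row) == 0) row <- cls_tab[which.min(abs(cls_tab$cpg_class - k)), ]
    prior_k <- .fit_prior_for_class(fit, row)
    idx <- est[work$cpg_class[est] %in% k]
    ys <- work$y_s[idx]
    yc <- if (mode == "sssi") work$y_c[idx] else NULL
    ee <- e_bin[idx]
    mom <- posterior_moments(ys, yc, alpha = row$alpha, beta = row$beta,
                             e = ee, prior = prior_k)
    out$mean[idx] <- mom$mean
    out$variance[idx] <- mom$variance
    out$atom0[idx] <- mom$atom0
    out$atom1[idx] <- mom$atom1
    if (length(intervals)) {
      key <- paste(ys, if (is.null(yc)) "" else yc, ee)
      uni <- which(!duplicated(key))
      ints <- purrr::map(uni, function(i) {
        post <- meth_posterior(ys[i], if (is.null(yc)) NULL else yc[i],
                               alpha = row$alpha, beta = row$beta,
                               e = ee[i], prior = prior_k)
        credible_intervals(post, types = intervals, level = level,
                           grid_points = grid_points)
      })
      ints <- dplyr::bind_rows(ints)[match(key, key[uni]), ]
      for (col in names(ints)) out[[col]][idx] <- ints[[col]]
    }
  }
  attr(out, "fit") <- fit
  attr(out, "f") <- fit$f
  out
}

# resolve the concrete methylation prior for one fitted class row
.fit_prior_for_class <- function(fit, row) {
  prior <- fit$prior
  if (.prior_has_free_ab(prior)) {
    prior <- .prior_fill_ab(prior, row$a, row$b)
  }
  prior
}
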
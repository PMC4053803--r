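#' Normalization offset between sample and fully methylated control
#'
#' The scalar offset `f` converts the control library's read-rate scale to
#' the sample's (the effective relative sequencing depth, absorbing both
#' depth and library composition). It is estimated from an MA representation
#' of the per-bin counts: on a random subsample of bins with both counts
#' positive, `M = log2(y_s) - log2(y_c)` and `A = (log2(y_s) + log2(y_c))/2`,
#' and
#' \deqn{\hat f = 2^{\mathrm{median}(M \mid A > q_A)}}
#' where \eqn{q_A} is a high empirical quantile of `A` (default 0.998).
#' High-A bins are essentially fully methylated, so the log-ratio there
#' reflects the pure depth/composition offset. In samples with copy-number
#' variation, only bins at the most prominent state `ccn` should be used
#' (pass `ccn`).
#'
#' Zero-count bins are excluded rather than pseudocounted: only high-A bins
#' enter the median, where zeros do not occur.
#'
#' @param counts Tibble with `y_s` and `y_c` columns (and `cn` when `ccn` is
#'   given).
#' @param q High quantile of `A` (nearest-rank) above which bins enter the
#'   median.
#' @param n_subsample Number of bins sampled for the MA computation.
#' @param ccn If given, restrict to bins with `cn == ccn`.
#' @param min_bins Minimum number of bins above the A threshold.
#' @return A scalar `f`, with the MA diagnostic table (columns `m`, `a`,
#'   `selected`) in attribute `ma`.
#' @examples
#' cnt <- tibble::tibble(y_s = rpois(2000, 40), y_c = rpois(2000, 80))
#' estimate_offset_f(cnt, q = 0.9, min_bins = 20)   # about 0.5
#' @export
estimate_offset_f <- function(counts, q = 0.998, n_subsample = 50000,
                              ccn = NULL, min_bins = 100) {
  stopifnot(q > 0, q < 1, all(c("y_s", "y_c") %in% names(counts)))
  if (!is.null(ccn)) {
    stopifnot("cn" %in% names(counts))
    counts <- dplyr::filter(counts, .data$cn == ccn)
  }
  if (nrow(counts) > n_subsample) {
    counts <- counts[sample.int(nrow(counts), n_subsample), , drop = FALSE]
  }
  counts <- dplyr::filter(counts, .data$y_s > 0, .data$y_c > 0)
  m <- log2(counts$y_s) - log2(counts$y_c)
  a <- (log2(counts$y_s) + log2(counts$y_c)) / 2
  a_q <- .quantile_nearest_rank(a, q)
  sel <- a >= a_q   # the nearest-rank quantile is a data value; keep its ties
  if (sum(sel) < min_bins) {
    stop("only ", sum(sel), " bins above the A threshold; lower q",
         call. = FALSE)
  }
  f <- 2^stats::median(m[sel])
  attr(f, "ma") <- tibble::tibble(m = m, a = a, selected = sel)
  f
}

#' @rdname estimate_offset_f
#' @param y_s Sample-of-interest counts (SssI-free mode).
#' @param cn Optional per-bin copy-number states matching `y_s`.
#' @param sssifree_quantile Quantile of `y_s` at which `f` is fixed
#'   (nearest-rank; default 0.99). Without a control the offset is
#'   reinterpreted as the read level of bins "at risk" of full methylation.
#' @export
estimate_offset_f_sssifree <- function(y_s, cn = NULL, ccn = NULL,
                                       sssifree_quantile = 0.99) {
  stopifnot(sssifree_quantile > 0, sssifree_quantile < 1)
  if (!is.null(cn) && !is.null(ccn)) y_s <- y_s[cn == ccn]
  if (length(y_s) == 0 || all(y_s == 0)) {
    stop("no usable counts to fix the SssI-free offset", call. = FALSE)
  }
  .quantile_nearest_rank(y_s, sssifree_quantile)
}

# nearest-rank empirical quantile: the ceiling(q*n)-th order statistic
.quantile_nearest_rank <- function(x, q) {
  sort(x)[max(1, ceiling(q * length(x)))]
}

#' Copy-number-specific effective multipliers
#'
#' Combines the normalization offset with the copy-number ratio into the
#' per-bin multiplier \eqn{E = f \, cn / ccn} entering the Poisson mean of
#' the sample of interest. A state of 0 yields a multiplier of 0 (no capture
#' possible).
#'
#' @param f Positive normalization offset.
#' @param ccn Positive integer reference (most prominent) copy-number state.
#' @param cn Vector of per-bin integer states (>= 0).
#' @return Numeric vector `f * cn / ccn`.
#' @examples
#' combined_offsets(0.712, ccn = 4, cn = 1:8)
#' @export
combined_offsets <- function(f, ccn, cn) {
  stopifnot(length(f) == 1, f > 0, length(ccn) == 1)
  if (ccn <= 0) stop("ccn must be a positive integer", call. = FALSE)
  stopifnot(all(cn >= 0))
  f * cn / ccn
}

#' MA diagnostic plot for the normalization offset
#'
#' Mirrors the M-versus-A representation used to pick the offset: each point
#' is a bin; bins above the A quantile (used for the median) are highlighted,
#' and the fitted `log2(f)` is drawn.
#'
#' @param f Result of [estimate_offset_f()] (carries the MA table).
#' @return A ggplot object.
#' @export
plot_ma_offset <- function(f) {
  ma <- attr(f, "ma")
  if (is.null(ma)) stop("f carries no MA table", call. = FALSE)
  ggplot2::ggplot(ma, ggplot2::aes(x = .data$a, y = .data$m,
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_hline(yintercept = log2(as.numeric(f)), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "A (average log2 count)", y = "M (log2 ratio)",
                  colour = "used for f",
                  title = sprintf("Normalization offset f = %.3f",
                                  as.numeric(f)))
}
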
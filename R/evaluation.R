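#' Collapse base-resolution bisulfite truth to bins
#'
#' `collapse_wgbs()` aggregates per-CpG whole-genome bisulfite counts into
#' per-bin methylation levels
#' \deqn{\mu_B = \frac{\sum_j (m_j^+ + m_j^-)}{\sum_j (r_j^+ + r_j^-)}}
#' over the CpGs falling in a bin, with the summed read total termed the
#' depth. Bins without CpGs, or below `min_depth`, are returned with `NA`.
#'
#' @param records Tibble with `chrom`, `pos` (0-based position of the CpG
#'   C), methylated read counts `m_plus`, `m_minus` and totals `r_plus`,
#'   `r_minus` (single-strand data can set the minus columns to 0).
#' @param bins Tibble with `chrom`, `start`, `end` (sorted, non-overlapping
#'   per chromosome).
#' @param min_depth Minimum summed depth for a bin to be reported.
#' @return `bins` with `mu_true` and `depth` columns.
#' @export
collapse_wgbs <- function(records, bins, min_depth = 1) {
  req <- c("chrom", "pos", "m_plus", "m_minus", "r_plus", "r_minus")
  stopifnot(all(req %in% names(records)))
  if (any(records$m_plus > records$r_plus |
          records$m_minus > records$r_minus)) {
    stop("methylated counts exceed totals", call. = FALSE)
  }
  agg <- .sum_in_bins(records$chrom, records$pos,
                      cbind(m = records$m_plus + records$m_minus,
                            r = records$r_plus + records$r_minus), bins)
  mu <- ifelse(agg[, "r"] > 0, agg[, "m"] / agg[, "r"], NA_real_)
  mu[agg[, "r"] < min_depth] <- NA_real_
  dplyr::mutate(bins, mu_true = mu, depth = agg[, "r"])
}

#' Collapse methylation-array beta values to bins
#'
#' Averages (unweighted) the beta values of all array CpG sites within
#' `flank` bp of each bin center (total window `2 * flank`).
#'
#' @param sites Tibble with `chrom`, `pos` (0-based) and `beta` in \[0, 1\].
#' @param bins Tibble with `chrom`, `start`, `end`.
#' @param flank Half-window around the bin center (default 100 bp).
#' @return `bins` with `mu_true` (`NA` when no site in the window) and
#'   `n_sites`.
#' @export
collapse_array_betas <- function(sites, bins, flank = 100) {
  stopifnot(all(c("chrom", "pos", "beta") %in% names(sites)),
            all(sites$beta >= 0 & sites$beta <= 1))
  mu <- rep(NA_real_, nrow(bins))
  ns <- integer(nrow(bins))
  for (chrom in unique(bins$chrom)) {
    bidx <- which(bins$chrom == chrom)
    s <- sites[sites$chrom == chrom, , drop = FALSE]
    if (nrow(s) == 0) next
    center <- (bins$start[bidx] + bins$end[bidx]) / 2
    for (i in seq_along(bidx)) {
      inw <- abs(s$pos - center[i]) <= flank
      ns[bidx[i]] <- sum(inw)
      if (ns[bidx[i]] > 0) mu[bidx[i]] <- mean(s$beta[inw])
    }
  }
  dplyr::mutate(bins, mu_true = mu, n_sites = ns)
}

#' Collapse reduced-representation bisulfite data to overlapping bins
#'
#' Builds a sliding tiling (default 150-bp bins stepping by 50 bp, i.e.
#' overlapping by 100 bp) per chromosome and computes per-bin
#' \eqn{m_i = \sum M / \sum T} with depth \eqn{\sum T}; a CpG contributes to
#' every bin covering it.
#'
#' @param records Tibble with `chrom`, `pos` (0-based), `m` (methylated) and
#'   `t` (total reads); one strand per CpG.
#' @param bin_width,step Tiling geometry in bp.
#' @param chrom_lengths Optional named lengths; defaults to covering the
#'   observed positions.
#' @return Tibble `chrom`, `start`, `end`, `mu_true`, `depth` (bins with
#'   zero depth are `NA`).
#' @export
collapse_rrbs <- function(records, bin_width = 150, step = 50,
                          chrom_lengths = NULL) {
  stopifnot(all(c("chrom", "pos", "m", "t") %in% names(records)),
            all(records$m <= records$t))
  purrr::map_dfr(unique(records$chrom), function(chrom) {
    r <- records[records$chrom == chrom, , drop = FALSE]
    len <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      chrom_lengths[[chrom]]
    } else max(r$pos) + 1
    starts <- seq(0, max(len - bin_width, 0), by = step)
    tib <- tibble::tibble(chrom = chrom, start = starts,
                          end = starts + bin_width)
    msum <- tsum <- numeric(nrow(tib))
    for (i in seq_len(nrow(tib))) {
      inb <- r$pos >= tib$start[i] & r$pos < tib$end[i]
      msum[i] <- sum(r$m[inb]); tsum[i] <- sum(r$t[inb])
    }
    dplyr::mutate(tib, mu_true = ifelse(tsum > 0, msum / tsum, NA_real_),
                  depth = tsum)
  })
}

# sum value columns of positioned records into bins (0-based half-open)
.sum_in_bins <- function(chrom, pos, values, bins) {
  out <- matrix(0, nrow(bins), ncol(values),
                dimnames = list(NULL, colnames(values)))
  for (ch in unique(bins$chrom)) {
    bidx <- which(bins$chrom == ch)
    stopifnot(!is.unsorted(bins$start[bidx]))
    ridx <- which(chrom == ch)
    if (length(ridx) == 0) next
    p <- findInterval(pos[ridx], bins$start[bidx])
    ok <- p >= 1 & pos[ridx] < bins$end[bidx][pmax(p, 1)]
    for (j in seq_len(ncol(values))) {
      s <- tapply(values[ridx[ok], j], p[ok], sum)
      out[bidx[as.integer(names(s))], j] <- s
    }
  }
  out
}

#' Estimation performance against a truth set
#'
#' Computes, optionally per stratum, the mean bias
#' \eqn{\mathrm{mean}(\hat\mu - \mu)}, the mean squared error, the Spearman
#' correlation (average ranks for ties) and — for every interval type whose
#' `<type>_lo` / `<type>_hi` columns are present — the empirical coverage,
#' i.e. the fraction of bins whose true value lies inside the credible
#' interval.
#'
#' @param data Tibble pairing estimates and truth per bin (e.g. a
#'   [quantify_methylation()] result joined with a collapsed truth set).
#' @param estimate,truth Column names (tidy-select) of the estimated and true
#'   methylation levels.
#' @param strata Optional column name to stratify by.
#' @return Long tibble with `stratum`, `metric`, `value`, `n`.
#' @examples
#' d <- tibble::tibble(est = c(.1, .4, .9), tru = c(.2, .3, .8))
#' performance_metrics(d, est, tru)
#' @export
performance_metrics <- function(data, estimate = mean, truth = mu_true,
                                strata = NULL) {
  est <- dplyr::pull(data, {{ estimate }})
  tru <- dplyr::pull(data, {{ truth }})
  st <- if (rlang::quo_is_null(rlang::enquo(strata))) {
    rep("all", nrow(data))
  } else as.character(dplyr::pull(data, {{ strata }}))
  keep <- !is.na(est) & !is.na(tru)
  itypes <- sub("_lo$", "", grep("_lo$", names(data), value = TRUE))
  itypes <- itypes[paste0(itypes, "_hi") %in% names(data)]

  purrr::map_dfr(unique(st), function(s) {
    i <- keep & st == s
    n <- sum(i)
    if (n == 0) {
      warning("empty stratum ", s, " omitted")
      return(tibble::tibble())
    }
    rows <- tibble::tibble(
      stratum = s,
      metric = c("bias", "mse", "spearman"),
      value = c(mean(est[i] - tru[i]),
                mean((est[i] - tru[i])^2),
                if (length(unique(tru[i])) >= 2 &&
                    length(unique(est[i])) >= 2) {
                  stats::cor(est[i], tru[i], method = "spearman")
                } else NA_real_),
      n = n)
    for (ty in itypes) {
      lo <- data[[paste0(ty, "_lo")]]
      hi <- data[[paste0(ty, "_hi")]]
      cov_i <- i & !is.na(lo) & !is.na(hi)
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        stratum = s, metric = paste0("coverage_", ty),
        value = mean(lo[cov_i] <= tru[cov_i] & tru[cov_i] <= hi[cov_i]),
        n = sum(cov_i)))
    }
    rows
  })
}

#' Preset stratification helpers
#'
#' `stratify_depth()` cuts a depth vector at the capture-depth boundaries
#' used for performance tables (default `c(4, 7, 14, 27)`, a quintile-style
#' scheme for 100-bp MBD-seq control depth). `stratify_cpg_island()`
#' dichotomizes CpG density at 12.46, the density threshold separating CpG
#' islands from non-islands at a 700-bp window.
#'
#' @param depth,density Numeric vectors.
#' @param breaks Internal cut points for depth.
#' @param threshold CpG-island density threshold.
#' @return Factor of stratum labels.
#' @export
stratify_depth <- function(depth, breaks = c(4, 7, 14, 27)) {
  cut(depth, breaks = c(-Inf, breaks, Inf), include.lowest = TRUE)
}

#' @rdname stratify_depth
#' @export
stratify_cpg_island <- function(density, threshold = 12.46) {
  factor(ifelse(density >= threshold, "CpG island", "non-island"),
         levels = c("non-island", "CpG island"))
}
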
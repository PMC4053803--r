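#' Simulate a full affinity-capture methylation dataset
#'
#' Draws a complete synthetic dataset from the generative model: per bin,
#' a CpG class \eqn{k}, a read density at full methylation
#' \eqn{\lambda \sim \mathrm{Ga}(\alpha_k, \beta_k)}, a methylation level
#' \eqn{\mu} from the methylation prior, a copy-number state (in contiguous
#' segments), and counts
#' \eqn{y_C \sim \mathrm{Poisson}(\lambda)},
#' \eqn{y_S \sim \mathrm{Poisson}(f \cdot cn/ccn \cdot \mu \lambda)}.
#' Synthetic CpG densities are assigned monotonically in the class index, so
#' the annotation, empirical Bayes and quantification stages can be run
#' end-to-end on the output with known ground truth.
#'
#' The default class priors emulate the empirical pattern of capture data:
#' the control read depth grows with CpG density (class means rising from
#' about 2 to 40 reads per 100-bp bin) with moderate overdispersion. Random
#' streams are split per component (density, methylation, copy number,
#' counts), so changing one leaves the others untouched.
#'
#' @param n_classes Number of CpG-density classes (default 10; use 100 to
#'   mimic a genome-scale stratification).
#' @param bins_per_class Bins simulated per class.
#' @param alpha,beta Per-class gamma hyperparameters (recycled to
#'   `n_classes`).
#' @param prior A [meth_prior()] with concrete parameters for the true
#'   methylation levels.
#' @param f True normalization offset.
#' @param ccn Reference copy-number state.
#' @param cn_states Optional integer vector of states to draw from
#'   (`NULL` = constant `ccn`).
#' @param cn_probs Probabilities of `cn_states`.
#' @param segment_bins Length (in bins) of constant-copy-number segments.
#' @param with_sssi Include the control counts `y_c`.
#' @param bin_width Bin width in bp for the synthetic coordinates.
#' @param seed Integer seed; the output is reproducible given the seed.
#' @return A tibble with columns `chrom`, `start`, `end`, `cpg_density`,
#'   `cpg_class`, `mappability`, `cn`, `lambda`, `mu` (the latent truth),
#'   `e`, `y_s` and (optionally) `y_c`; the configuration is echoed in
#'   attribute `sim_config`.
#' @examples
#' sim <- simulate_methylation_dataset(n_classes = 3, bins_per_class = 50,
#'                                     seed = 1)
#' head(sim)
#' @export
simulate_methylation_dataset <- function(n_classes = 10, bins_per_class = 1000,
                                         alpha = seq(1.5, 8, length.out = n_classes),
                                         beta = alpha / seq(2, 40, length.out = n_classes),
                                         prior = meth_prior("uniform"),
                                         f = 1, ccn = 2,
                                         cn_states = NULL, cn_probs = NULL,
                                         segment_bins = 50,
                                         with_sssi = TRUE, bin_width = 100,
                                         seed = 1) {
  alpha <- rep_len(alpha, n_classes)
  beta <- rep_len(beta, n_classes)
  stopifnot(all(alpha > 0), all(beta > 0), f > 0, ccn >= 1)
  n <- n_classes * bins_per_class
  set.seed(seed)
  streams <- sample.int(.Machine$integer.max - 1, 4)

  cls <- rep(seq_len(n_classes), each = bins_per_class)

  set.seed(streams[1])                       # lambda stream
  lambda <- stats::rgamma(n, shape = alpha[cls], rate = beta[cls])

  set.seed(streams[2])                       # methylation stream
  mu <- rmeth_prior(n, prior)

  set.seed(streams[3])                       # copy-number stream
  if (is.null(cn_states)) {
    cn <- rep(ccn, n)
  } else {
    n_seg <- ceiling(n / segment_bins)
    seg_state <- sample(cn_states, n_seg, replace = TRUE, prob = cn_probs)
    cn <- rep(seg_state, each = segment_bins)[seq_len(n)]
  }
  e <- combined_offsets(f, ccn, cn)

  set.seed(streams[4])                       # count stream
  y_s <- stats::rpois(n, e * mu * lambda)
  y_c <- if (with_sssi) stats::rpois(n, lambda) else NULL

  # synthetic densities: class k occupies [k-1, k), jittered within
  dens <- cls - 1 + (seq_len(n) %% bins_per_class) / bins_per_class

  out <- tibble::tibble(
    chrom = "sim1",
    start = (seq_len(n) - 1) * bin_width,
    end = seq_len(n) * bin_width,
    cpg_density = dens,
    cpg_class = cls,
    mappability = 1,
    cn = cn,
    lambda = lambda,
    mu = mu,
    e = e,
    y_s = y_s
  )
  if (with_sssi) out$y_c <- y_c
  attr(out, "sim_config") <- list(n_classes = n_classes,
                                  bins_per_class = bins_per_class,
                                  alpha = alpha, beta = beta, prior = prior,
                                  f = f, ccn = ccn, cn_states = cn_states,
                                  segment_bins = segment_bins, seed = seed,
                                  bin_width = bin_width)
  out
}

#' Emit aligned-read records consistent with simulated per-bin counts
#'
#' For every bin, `y_s` (and `y_c`) reads are placed so that extending each
#' read to `fragment_length` from its 5' end puts the fragment midpoint
#' inside the bin; [count_reads_in_bins()] with the same
#' `read_extension = fragment_length` therefore reproduces the count table
#' exactly.
#'
#' @param sim Output of [simulate_methylation_dataset()].
#' @param read_length Sequenced read length in bp.
#' @param fragment_length Fragment length used by the midpoint rule.
#' @param seed Integer seed for the placement stream.
#' @param which Which count column to expand into reads.
#' @return Tibble with `chrom`, `start` (0-based), `width`, `strand`.
#' @export
simulate_reads <- function(sim, read_length = 36, fragment_length = 300,
                           seed = 1, which = c("y_s", "y_c")) {
  which <- match.arg(which)
  stopifnot(which %in% names(sim), read_length >= 1, fragment_length >= 1)
  set.seed(seed)
  cnt <- sim[[which]]
  idx <- rep.int(seq_len(nrow(sim)), cnt)
  if (length(idx) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          width = numeric(), strand = character()))
  }
  width <- sim$end[idx] - sim$start[idx]
  mid <- sim$start[idx] + floor(stats::runif(length(idx)) * width)
  strand <- sample(c("+", "-"), length(idx), replace = TRUE)
  # invert the midpoint rule of count_reads_in_bins for each strand
  start <- ifelse(strand == "+",
                  mid - floor(fragment_length / 2),
                  mid + ceiling(fragment_length / 2) - read_length)
  tibble::tibble(chrom = sim$chrom[idx], start = start,
                 width = read_length, strand = strand)
}
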
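#' Tile chromosomes into fixed-width bins
#'
#' Produces the non-overlapping genomic bins (default width 100 bp) on which
#' all downstream quantities are computed. Coordinates are 0-based half-open;
#' a trailing partial bin at the chromosome end is dropped.
#'
#' @param chrom_lengths Named numeric vector or list of chromosome lengths in
#'   bp.
#' @param bin_width Positive integer bin width.
#' @return A tibble with columns `chrom`, `start`, `end`, sorted by
#'   chromosome (input order) then start.
#' @examples
#' tile_genome(c(chr1 = 1000, chr2 = 250), bin_width = 100)
#' @export
tile_genome <- function(chrom_lengths, bin_width = 100) {
  chrom_lengths <- unlist(chrom_lengths)
  stopifnot(length(bin_width) == 1, bin_width >= 1,
            bin_width == floor(bin_width))
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be named by chromosome", call. = FALSE)
  }
  if (any(chrom_lengths < 0)) stop("negative chromosome length", call. = FALSE)
  purrr::map2_dfr(names(chrom_lengths), chrom_lengths, function(chrom, len) {
    n <- floor(len / bin_width)
    if (n == 0) return(tibble::tibble(chrom = character(), start = numeric(),
                                      end = numeric()))
    start <- (seq_len(n) - 1) * bin_width
    tibble::tibble(chrom = chrom, start = start, end = start + bin_width)
  })
}

#' Weighted CpG density of genomic bins
#'
#' Counts CpG dinucleotides in a window (default 700 bp) centered on each
#' bin, weighting each CpG by its distance to the bin center. With the
#' default linear kernel a CpG at distance `d` from the center contributes
#' `max(0, 1 - d / (window / 2))`; with `"uniform"` weighting every CpG in
#' the window contributes 1, i.e. the density is the plain CpG count. The
#' distance is measured to the C of the CpG; both strands are covered by
#' scanning the forward sequence only, since CpG is its own reverse
#' complement. Windows are clipped at chromosome ends.
#'
#' @param bins Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genome Named character vector of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param window Window size in bp (>= bin width).
#' @param weighting `"linear"` or `"uniform"`.
#' @return `bins` with an added `cpg_density` column.
#' @export
cpg_density <- function(bins, genome, window = 700,
                        weighting = c("linear", "uniform")) {
  weighting <- match.arg(weighting)
  seqs <- .as_genome(genome)
  stopifnot(window >= max(bins$end - bins$start))
  half <- window / 2
  missing_chrom <- setdiff(unique(bins$chrom), names(seqs))
  if (length(missing_chrom)) {
    stop("no sequence for chromosome(s): ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  dens <- numeric(nrow(bins))
  for (chrom in unique(bins$chrom)) {
    seq <- seqs[[chrom]]
    len <- nchar(seq)
    cg <- gregexpr("CG", seq, fixed = TRUE)[[1]]
    cg <- if (cg[1] == -1) numeric(0) else as.numeric(cg) - 1  # 0-based C pos
    idx <- which(bins$chrom == chrom)
    center <- (bins$start[idx] + bins$end[idx]) / 2
    for (k in seq_along(idx)) {
      d <- abs(cg - center[k])
      w <- if (weighting == "linear") pmax(0, 1 - d / half) else
        as.numeric(d <= half)
      dens[idx[k]] <- sum(w)
    }
    if (any(bins$end[idx] > len)) {
      stop("bin beyond end of sequence for ", chrom, call. = FALSE)
    }
  }
  dplyr::mutate(bins, cpg_density = dens)
}

.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && is.null(names(genome)) &&
      file.exists(genome)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA requires the Biostrings package", call. = FALSE)
    }
    ss <- Biostrings::readDNAStringSet(genome)
    genome <- stats::setNames(as.character(ss),
                              sub("\\s.*", "", names(ss)))
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome),
                              sub("\\s.*", "", names(genome)))
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  toupper(genome)
}

#' Mappability fraction of genomic bins
#'
#' Fraction of mappable bases in a window (default 500 bp, i.e. 250 bp up-
#' and downstream of the bin center). Bases not covered by the track are
#' treated as unmappable; windows are clipped at chromosome boundaries, in
#' which case the denominator is the clipped window size.
#'
#' @inheritParams cpg_density
#' @param track Mappable intervals: a tibble/data frame with `chrom`,
#'   `start`, `end` (0-based half-open), a `GRanges`, or a path to a BED (or
#'   any `rtracklayer`-readable) file.
#' @param window Window size in bp.
#' @param chrom_lengths Optional named vector used to clip windows at
#'   chromosome ends.
#' @return `bins` with an added `mappability` column in \[0, 1\].
#' @export
mappability_fraction <- function(bins, track, window = 500,
                                 chrom_lengths = NULL) {
  track <- .as_intervals(track)
  half <- window / 2
  mp <- numeric(nrow(bins))
  for (chrom in unique(bins$chrom)) {
    idx <- which(bins$chrom == chrom)
    tr <- track[track$chrom == chrom, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    center <- (bins$start[idx] + bins$end[idx]) / 2
    lo <- pmax(center - half, 0)
    hi <- center + half
    if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      hi <- pmin(hi, chrom_lengths[[chrom]])
    }
    mp[idx] <- purrr::map2_dbl(lo, hi, function(l, h) {
      if (h <= l) return(0)
      ov <- pmin(tr$end, h) - pmax(tr$start, l)
      sum(ov[ov > 0]) / (h - l)
    })
  }
  dplyr::mutate(bins, mappability = pmin(mp, 1))
}

.as_intervals <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading track files requires rtracklayer", call. = FALSE)
    }
    x <- rtracklayer::import(x)
  }
  if (inherits(x, "GRanges")) {
    x <- tibble::tibble(chrom = as.character(GenomicRanges::seqnames(x)),
                        start = GenomicRanges::start(x) - 1,  # to 0-based
                        end = GenomicRanges::end(x))
  }
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  tibble::as_tibble(x)
}

#' Partition bins into CpG-density classes
#'
#' Assigns every bin to one of `k` CpG-density classes using equal-count
#' (quantile) breakpoints with left-closed right-open intervals. The
#' hyperparameters of the read-density prior are later estimated separately
#' per class. Duplicate breakpoints (heavily tied densities) are merged, and
#' `k` is reduced with a warning when fewer distinct values are available.
#'
#' @param bins Tibble with a `cpg_density` column, or a bare numeric vector
#'   of densities.
#' @param k Target number of classes (default 100).
#' @return For a tibble input, `bins` with an added integer `cpg_class`
#'   column (1-based) and the partition stored in attribute `cpg_breaks`;
#'   for a vector input, an integer vector of class labels with the same
#'   attribute. [cpg_class_partition()] extracts the breakpoints as a tibble.
#' @export
assign_cpg_classes <- function(bins, k = 100) {
  vec <- is.numeric(bins)
  dens <- if (vec) bins else bins$cpg_density
  if (length(dens) == 0) stop("no densities to classify", call. = FALSE)
  stopifnot(k >= 1, all(dens >= 0))
  # equal-count split: class k holds sorted ranks ((k-1)n/K, kn/K]; the
  # left-closed breakpoint is the first value of the next class
  s <- sort(dens)
  n <- length(s)
  pos <- pmin(floor(seq_len(max(k - 1, 0)) * n / k) + 1, n)
  br <- sort(unique(s[pos]))
  br <- br[br > min(dens)]          # left-closed first interval must be nonempty
  if (length(br) + 1 < k && k > 1) {
    warning("reduced K from ", k, " to ", length(br) + 1,
            " (ties in CpG densities)")
  }
  labels <- findInterval(dens, br, left.open = FALSE) + 1L
  breaks <- tibble::tibble(
    cpg_class = seq_len(length(br) + 1),
    lower = c(-Inf, br),
    upper = c(br, Inf)
  )
  if (vec) {
    attr(labels, "cpg_breaks") <- breaks
    return(labels)
  }
  out <- dplyr::mutate(bins, cpg_class = labels)
  attr(out, "cpg_breaks") <- breaks
  out
}

#' @rdname assign_cpg_classes
#' @param x Output of [assign_cpg_classes()].
#' @export
cpg_class_partition <- function(x) {
  br <- attr(x, "cpg_breaks")
  if (is.null(br)) stop("no cpg_breaks attribute found", call. = FALSE)
  br
}

#' Filter bins by mappability
#'
#' Keeps bins whose mappability is at least `threshold` (default 0.75).
#'
#' @param bins Tibble with a `mappability` column.
#' @param threshold Minimum mappable fraction; comparison is `>=`.
#' @return Filtered tibble.
#' @export
filter_mappable <- function(bins, threshold = 0.75) {
  dplyr::filter(bins, .data$mappability >= threshold)
}
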
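#' Count extended reads in genomic bins
#'
#' Each read is extended to `read_extension` bp from its 5' end in strand
#' direction (capture fragments are longer than the sequenced read), and
#' increments the single bin containing the midpoint of the extended
#' fragment. The midpoint rule guarantees a read is never counted twice at
#' 100-bp resolution. Reads whose midpoint falls outside all bins, and reads
#' on chromosomes absent from `bins` (with a warning), are dropped.
#'
#' @param bins Tibble with `chrom`, `start`, `end`; per chromosome the bins
#'   must be sorted and non-overlapping.
#' @param reads A tibble/data frame with columns `chrom`, `start` (0-based
#'   leftmost aligned base), `width` and `strand` (`"+"`/`"-"`), or a path to
#'   an indexed BAM file (read via `Rsamtools`).
#' @param read_extension Fragment length to extend to (0 keeps the read as
#'   aligned).
#' @param count_col Name of the output count column (`"y_s"` or `"y_c"`).
#' @param min_mapq Minimum mapping quality when reading from BAM.
#' @return `bins` with the count column added.
#' @export
count_reads_in_bins <- function(bins, reads, read_extension = 300,
                                count_col = "y_s", min_mapq = 0) {
  stopifnot(read_extension >= 0)
  reads <- .as_reads(reads, min_mapq)
  unknown <- setdiff(unique(reads$chrom), unique(bins$chrom))
  if (length(unknown)) {
    warning("skipping reads on chromosome(s) without bins: ",
            paste(unknown, collapse = ", "))
    reads <- reads[!reads$chrom %in% unknown, , drop = FALSE]
  }
  ext <- pmax(read_extension, reads$width)
  # extended fragment interval [lo, hi) anchored at the 5' end
  lo <- ifelse(reads$strand == "-", reads$start + reads$width - ext,
               reads$start)
  mid <- floor((2 * lo + ext) / 2)

  counts <- rep(0L, nrow(bins))
  for (chrom in unique(bins$chrom)) {
    bidx <- which(bins$chrom == chrom)
    stopifnot(!is.unsorted(bins$start[bidx]))
    m <- mid[reads$chrom == chrom]
    pos <- findInterval(m, bins$start[bidx])
    ok <- pos >= 1 & pos <= length(bidx)
    pos <- pos[ok]
    inside <- m[ok] < bins$end[bidx][pos]
    tab <- tabulate(pos[inside], nbins = length(bidx))
    counts[bidx] <- tab
  }
  bins[[count_col]] <- counts
  bins
}

.as_reads <- function(reads, min_mapq = 0) {
  if (is.character(reads) && length(reads) == 1) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("reading BAM requires Rsamtools", call. = FALSE)
    }
    param <- Rsamtools::ScanBamParam(
      what = c("rname", "pos", "qwidth", "strand", "mapq"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    b <- Rsamtools::scanBam(reads, param = param)[[1]]
    keep <- is.na(b$mapq) | b$mapq >= min_mapq
    reads <- tibble::tibble(chrom = as.character(b$rname)[keep],
                            start = b$pos[keep] - 1,   # BAM pos is 1-based
                            width = b$qwidth[keep],
                            strand = as.character(b$strand)[keep])
  }
  stopifnot(is.data.frame(reads),
            all(c("chrom", "start", "width", "strand") %in% names(reads)))
  tibble::as_tibble(reads)
}

#' Read and write per-bin count tables
#'
#' The on-disk format is a tab-separated table with header columns `chrom`,
#' `start`, `end`, `y_s` and optionally `y_c` (SssI control), `cn`
#' (copy-number state) and any annotation columns (`cpg_density`,
#' `mappability`, `cpg_class`). Coordinates are 0-based half-open. A missing
#' `y_c` column marks the table as SssI-free. Reading and writing round-trip
#' losslessly.
#'
#' @param path File path.
#' @return `read_count_table()`: a tibble; `write_count_table()`: `path`,
#'   invisibly.
#' @export
read_count_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("chrom", "start", "end", "y_s")
  if (!all(req %in% names(tab))) {
    stop("count table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(c("y_s", "y_c", "cn"), names(tab))) {
    v <- tab[[col]]
    bad <- which(!is.na(v) & (v < 0 | v != floor(v)))
    if (length(bad)) {
      stop(sprintf("invalid %s at line %d: counts must be non-negative integers",
                   col, bad[1] + 1), call. = FALSE)
    }
  }
  tab
}

#' @rdname read_count_table
#' @param counts Tibble of per-bin counts.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Write methylation estimates
#'
#' Writes the posterior summary table produced by [quantify_methylation()]
#' as a full TSV (all columns), and optionally a bedGraph track of the
#' posterior means.
#'
#' @param estimates Posterior summary tibble.
#' @param path Output TSV path.
#' @param bedgraph Optional path for a bedGraph of posterior means.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path, bedgraph = NULL) {
  readr::write_tsv(estimates, path, progress = FALSE)
  if (!is.null(bedgraph)) {
    bg <- dplyr::filter(estimates, !is.na(.data$mean))
    readr::write_tsv(
      dplyr::transmute(bg, .data$chrom, .data$start, .data$end,
                       value = round(.data$mean, 6)),
      bedgraph, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}

#' Annotate bins with copy-number states
#'
#' Each bin takes the integer state of the copy-number segment containing its
#' midpoint (half-open segments: a midpoint on a boundary belongs to the
#' segment starting there). Bins covered by no segment receive the dataset's
#' most prominent state (`ccn`) and are flagged in `cn_imputed`.
#'
#' @param bins Tibble with `chrom`, `start`, `end`.
#' @param segments Tibble/data frame with `chrom`, `start`, `end`, `cn`
#'   (integer state), or a path to a BED4 file with the state in column 4;
#'   segments must not overlap within a chromosome.
#' @param ccn Reference state for uncovered bins; default the most frequent
#'   state among covered bins (ties broken toward the larger span).
#' @return `bins` with `cn` and `cn_imputed` columns.
#' @export
annotate_copy_number <- function(bins, segments, ccn = NULL) {
  segments <- .as_cn_segments(segments)
  for (chrom in unique(segments$chrom)) {
    s <- segments[segments$chrom == chrom, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stop("overlapping copy-number segments on ", chrom, call. = FALSE)
    }
  }
  mid <- floor((bins$start + bins$end) / 2)
  cn <- rep(NA_integer_, nrow(bins))
  for (chrom in unique(bins$chrom)) {
    bidx <- which(bins$chrom == chrom)
    s <- segments[segments$chrom == chrom, , drop = FALSE]
    if (nrow(s) == 0) next
    s <- s[order(s$start), , drop = FALSE]
    pos <- findInterval(mid[bidx], s$start)
    ok <- pos >= 1
    hit <- ok & mid[bidx] < s$end[pmax(pos, 1)]
    cn[bidx[hit]] <- s$cn[pos[hit]]
  }
  if (is.null(ccn)) {
    if (all(is.na(cn))) stop("no bin covered by any segment", call. = FALSE)
    tab <- table(cn[!is.na(cn)])
    ccn <- as.integer(names(tab)[which.max(tab)])
  }
  bins$cn_imputed <- is.na(cn)
  bins$cn <- ifelse(is.na(cn), ccn, cn)
  bins
}

.as_cn_segments <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    x <- readr::read_tsv(x, col_names = c("chrom", "start", "end", "cn"),
                         show_col_types = FALSE, progress = FALSE)
  }
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end", "cn") %in% names(x)))
  tibble::as_tibble(x)
}
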
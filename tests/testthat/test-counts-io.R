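make_bins <- function(n = 10, width = 100, chrom = "c1") {
  tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * width,
                 end = seq_len(n) * width)
}

test_that("read counting follows the extended-fragment midpoint rule", {
  bins <- make_bins(10)
  none <- count_reads_in_bins(bins, tibble::tibble(chrom = character(),
                                                   start = numeric(),
                                                   width = numeric(),
                                                   strand = character()))
  expect_true(all(none$y_s == 0))

  # one 36 bp plus-strand read starting at 150: fragment [150, 450),
  # midpoint 300 -> bin 4
  r <- tibble::tibble(chrom = "c1", start = 150, width = 36, strand = "+")
  cnt <- count_reads_in_bins(bins, r, read_extension = 300)
  expect_equal(which(cnt$y_s == 1), 4)
  expect_equal(sum(cnt$y_s), 1)

  # minus-strand read ending at 450: fragment [150, 450), same midpoint
  rm <- tibble::tibble(chrom = "c1", start = 414, width = 36, strand = "-")
  cntm <- count_reads_in_bins(bins, rm, read_extension = 300)
  expect_equal(which(cntm$y_s == 1), 4)

  # reads on unknown chromosomes are skipped with a warning
  bad <- tibble::tibble(chrom = c("c1", "cX"), start = c(10, 10),
                        width = 36, strand = "+")
  expect_warning(cnt2 <- count_reads_in_bins(bins, bad, read_extension = 0),
                 "cX")
  expect_equal(sum(cnt2$y_s), 1)
})

test_that("counting matches a brute-force tally of 1000 random reads", {
  set.seed(71)
  bins <- make_bins(50)
  reads <- tibble::tibble(chrom = "c1",
                          start = sample(0:4970, 1000, replace = TRUE),
                          width = 36,
                          strand = sample(c("+", "-"), 1000, replace = TRUE))
  ext <- 200
  got <- count_reads_in_bins(bins, reads, read_extension = ext)$y_s
  lo <- ifelse(reads$strand == "-", reads$start + reads$width - ext,
               reads$start)
  mid <- floor((2 * lo + ext) / 2)
  want <- vapply(seq_len(nrow(bins)), function(i) {
    sum(mid >= bins$start[i] & mid < bins$end[i])
  }, numeric(1))
  expect_equal(got, want)
  expect_lte(sum(got), nrow(reads))
})

test_that("counting from a BAM file agrees with the in-memory path", {
  skip_if_not_installed("Rsamtools")
  bins <- make_bins(20)
  set.seed(72)
  reads <- tibble::tibble(chrom = "c1",
                          start = sample(300:1600, 100, replace = TRUE),
                          width = 36,
                          strand = sample(c("+", "-"), 100, replace = TRUE))
  sam <- tempfile(fileext = ".sam")
  lines <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:c1\tLN:2000")
  ord <- order(reads$start)
  lines <- c(lines, sprintf("r%d\t%d\tc1\t%d\t60\t36M\t*\t0\t0\t%s\t*",
                            seq_len(nrow(reads)),
                            ifelse(reads$strand[ord] == "-", 16L, 0L),
                            reads$start[ord] + 1,
                            strrep("A", 36)))
  writeLines(lines, sam)
  bam <- suppressMessages(Rsamtools::asBam(sam, tempfile(), overwrite = TRUE))
  from_bam <- count_reads_in_bins(bins, bam, read_extension = 300)$y_s
  from_mem <- count_reads_in_bins(bins, reads, read_extension = 300)$y_s
  expect_equal(from_bam, from_mem)
})

test_that("count tables round-trip and enforce the count invariants", {
  tab <- make_bins(10)
  set.seed(73)
  tab$y_s <- rpois(10, 5)
  tab$y_c <- rpois(10, 8)
  tab$cn <- sample(2:4, 10, replace = TRUE)
  path <- tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  back <- read_count_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))

  # SssI-free tables simply lack y_c
  tab2 <- dplyr::select(tab, -"y_c")
  write_count_table(tab2, path)
  expect_false("y_c" %in% names(read_count_table(path)))

  bad <- tab; bad$y_s[3] <- -1
  write_count_table(bad, path)
  expect_error(read_count_table(bad_path <- path), "line 4")
})

test_that("estimate tables are written as TSV plus bedGraph", {
  est <- make_bins(3)
  est$mean <- c(0.1, NA, 0.9)
  est$variance <- c(0.01, NA, 0.02)
  tsv <- tempfile(fileext = ".tsv"); bg <- tempfile(fileext = ".bedgraph")
  write_estimates(est, tsv, bedgraph = bg)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 3)
  bg_tab <- readr::read_tsv(bg, col_names = FALSE, show_col_types = FALSE)
  expect_equal(nrow(bg_tab), 2)   # NA rows dropped from the track
  expect_equal(bg_tab$X4, c(0.1, 0.9))
})

test_that("copy-number annotation assigns segment states by bin midpoint", {
  bins <- make_bins(10)
  seg_all <- tibble::tibble(chrom = "c1", start = 0, end = 1000, cn = 4)
  ann <- annotate_copy_number(bins, seg_all)
  expect_true(all(ann$cn == 4))
  expect_false(any(ann$cn_imputed))

  # midpoint exactly on a segment boundary belongs to the right segment
  segs <- tibble::tibble(chrom = "c1", start = c(0, 150), end = c(150, 1000),
                         cn = c(2, 3))
  ann2 <- annotate_copy_number(bins, segs)
  expect_equal(ann2$cn[1:2], c(2, 3))   # bin 2 midpoint = 150

  # mixed segments equal a per-bin linear search
  set.seed(74)
  cuts <- sort(sample(100:900, 4))
  segs3 <- tibble::tibble(chrom = "c1",
                          start = c(0, cuts), end = c(cuts, 1000),
                          cn = sample(1:6, 5, replace = TRUE))
  ann3 <- annotate_copy_number(bins, segs3)
  mid <- (bins$start + bins$end) / 2
  want <- vapply(mid, function(m) {
    segs3$cn[which(segs3$start <= m & m < segs3$end)]
  }, numeric(1))
  expect_equal(ann3$cn, want)

  expect_error(annotate_copy_number(
    bins, tibble::tibble(chrom = "c1", start = c(0, 100), end = c(200, 300),
                         cn = c(2, 3))), "overlapping")

  # uncovered bins fall back to the most prominent state, flagged
  part <- tibble::tibble(chrom = "c1", start = 0, end = 500, cn = 3)
  ann4 <- annotate_copy_number(bins, part)
  expect_true(all(ann4$cn == 3))
  expect_equal(sum(ann4$cn_imputed), 5)
})

test_that("simulated reads round-trip through the counter exactly", {
  sim <- simulate_methylation_dataset(n_classes = 3, bins_per_class = 40,
                                      seed = 5)
  reads <- simulate_reads(sim, read_length = 36, fragment_length = 300,
                          seed = 6)
  expect_equal(nrow(reads), sum(sim$y_s))
  back <- count_reads_in_bins(sim[, c("chrom", "start", "end")], reads,
                              read_extension = 300)
  expect_equal(back$y_s, sim$y_s)
  # a bin with no reads emits none
  expect_false(any(reads$chrom[sim$y_s == 0] %in% NA))
})
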
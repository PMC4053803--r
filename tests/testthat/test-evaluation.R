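test_that("bisulfite truth collapses by summed methylated over total reads", {
  bins <- tibble::tibble(chrom = "c1", start = c(0, 100, 200),
                         end = c(100, 200, 300))
  rec <- tibble::tibble(chrom = "c1", pos = 50,
                        m_plus = 7, r_plus = 10, m_minus = 8, r_minus = 10)
  out <- collapse_wgbs(rec, bins)
  expect_equal(out$mu_true[1], 0.75)
  expect_equal(out$depth[1], 20)
  expect_true(is.na(out$mu_true[2]))   # no CpG in the bin
  expect_error(collapse_wgbs(dplyr::mutate(rec, m_plus = 12), bins), "exceed")

  # depth threshold marks shallow bins missing
  out2 <- collapse_wgbs(rec, bins, min_depth = 33)
  expect_true(is.na(out2$mu_true[1]))

  # 50 random CpGs across 5 bins equal a per-bin brute-force tally
  set.seed(101)
  bins5 <- tibble::tibble(chrom = "c1", start = 0:4 * 100, end = 1:5 * 100)
  rec50 <- tibble::tibble(chrom = "c1", pos = sample(0:499, 50),
                          r_plus = rpois(50, 20), r_minus = rpois(50, 20))
  rec50$m_plus <- rbinom(50, rec50$r_plus, 0.6)
  rec50$m_minus <- rbinom(50, rec50$r_minus, 0.6)
  got <- collapse_wgbs(rec50, bins5)
  for (i in 1:5) {
    inb <- rec50$pos >= bins5$start[i] & rec50$pos < bins5$end[i]
    expect_equal(got$depth[i], sum(rec50$r_plus[inb] + rec50$r_minus[inb]))
    expect_equal(got$mu_true[i],
                 sum(rec50$m_plus[inb] + rec50$m_minus[inb]) / got$depth[i])
  }

  # additivity: splitting records and re-merging leaves results unchanged
  split1 <- dplyr::mutate(rec50, r_plus = 0, m_plus = 0)
  split2 <- dplyr::mutate(rec50, r_minus = 0, m_minus = 0)
  merged <- collapse_wgbs(dplyr::bind_rows(split1, split2), bins5)
  expect_equal(merged$mu_true, got$mu_true)
  expect_equal(merged$depth, got$depth)
})

test_that("array betas average unweighted within the centered window", {
  bins <- tibble::tibble(chrom = "c1", start = 0, end = 100)  # center 50
  one <- tibble::tibble(chrom = "c1", pos = 60, beta = 0.9)
  expect_equal(collapse_array_betas(one, bins)$mu_true, 0.9)
  two <- tibble::tibble(chrom = "c1", pos = c(10, 140), beta = c(0.2, 0.6))
  expect_equal(collapse_array_betas(two, bins)$mu_true, 0.4)
  far <- tibble::tibble(chrom = "c1", pos = 151, beta = 1)
  expect_true(is.na(collapse_array_betas(far, bins)$mu_true))
  # randomized placement equals a brute-force window scan
  set.seed(102)
  bins3 <- tibble::tibble(chrom = "c1", start = c(0, 300, 600),
                          end = c(100, 400, 700))
  sites <- tibble::tibble(chrom = "c1", pos = sample(0:800, 60),
                          beta = runif(60))
  got <- collapse_array_betas(sites, bins3)
  for (i in 1:3) {
    ctr <- (bins3$start[i] + bins3$end[i]) / 2
    inw <- abs(sites$pos - ctr) <= 100
    want <- if (any(inw)) mean(sites$beta[inw]) else NA_real_
    expect_equal(got$mu_true[i], want)
  }
})

test_that("overlapping bisulfite tiling shares CpGs across covering bins", {
  rec <- tibble::tibble(chrom = "c1", pos = 120, m = 5, t = 10)
  out <- collapse_rrbs(rec, chrom_lengths = c(c1 = 400))
  covering <- out$start <= 120 & 120 < out$end
  expect_equal(sum(covering), 3)   # 150-bp bins stepping by 50
  expect_true(all(out$mu_true[covering] == 0.5))
  expect_true(all(is.na(out$mu_true[!covering])))
  # random records equal brute-force per-bin sums
  set.seed(103)
  rec2 <- tibble::tibble(chrom = "c1", pos = sample(0:390, 40, replace = TRUE),
                         t = rpois(40, 15))
  rec2$m <- rbinom(40, rec2$t, 0.3)
  got <- collapse_rrbs(rec2, chrom_lengths = c(c1 = 400))
  for (i in seq_len(nrow(got))) {
    inb <- rec2$pos >= got$start[i] & rec2$pos < got$end[i]
    if (sum(rec2$t[inb]) > 0) {
      expect_equal(got$mu_true[i], sum(rec2$m[inb]) / sum(rec2$t[inb]))
      expect_equal(got$depth[i], sum(rec2$t[inb]))
    }
  }
})

test_that("performance metrics match hand-computed values", {
  d <- tibble::tibble(mean = c(0.1, 0.4, 0.9), mu_true = c(0.2, 0.3, 0.8))
  pm <- performance_metrics(d)
  expect_equal(pm$value[pm$metric == "bias"], 1 / 30)
  expect_equal(pm$value[pm$metric == "mse"], 0.01)
  expect_equal(pm$value[pm$metric == "spearman"], 1)
  # perfect estimates
  d2 <- tibble::tibble(mean = c(0.2, 0.5, 0.7), mu_true = c(0.2, 0.5, 0.7),
                       hpd_lo = 0, hpd_hi = 1)
  pm2 <- performance_metrics(d2)
  expect_equal(pm2$value[pm2$metric == "bias"], 0)
  expect_equal(pm2$value[pm2$metric == "mse"], 0)
  expect_equal(pm2$value[pm2$metric == "coverage_hpd"], 1)
})

test_that("Spearman is invariant under monotone transforms and strata work", {
  set.seed(104)
  d <- tibble::tibble(mean = runif(200), mu_true = runif(200),
                      grp = rep(c("x", "y"), 100))
  pm <- performance_metrics(d, strata = grp)
  expect_setequal(unique(pm$stratum), c("x", "y"))
  rho <- pm$value[pm$metric == "spearman" & pm$stratum == "x"]
  d2 <- dplyr::mutate(d, mean = qlogis(mean / 1.0001 + 1e-5))
  pm2 <- performance_metrics(d2, strata = grp)
  expect_equal(pm2$value[pm2$metric == "spearman" & pm2$stratum == "x"], rho)
  # stratification presets
  expect_equal(levels(stratify_depth(c(1, 5, 10, 20, 100))),
               c("[-Inf,4]", "(4,7]", "(7,14]", "(14,27]", "(27, Inf]"))
  expect_equal(as.character(stratify_cpg_island(c(1, 13))),
               c("non-island", "CpG island"))
})
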
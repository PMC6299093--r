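# Binned enrichment profile: RPKM, log2 ratios, top-site selection, the
# minimum-overlap bin assignment rule, per-site window means and the
# signed-rank machinery.

test_that("RPKM normalization matches the per-bin formula", {
  tr <- bin_track("chr1", c(0, 50, 100), c(50, 100, 150), c(5, 0, 12))
  rn <- normalize_track(tr, total_reads = 1e6)
  expect_equal(rn$value, c(100, 0, 240))
  set.seed(1)
  tr2 <- bin_track("chr1", seq(0, 4950, 50), seq(50, 5000, 50), rpois(100, 30))
  total <- 3.7e6
  rn2 <- normalize_track(tr2, total)
  expect_equal(rn2$value, tr2$value / ((50 / 1000) * (total / 1e6)),
               tolerance = 1e-12)
  expect_error(normalize_track(tr, total_reads = 0), "total_reads")
})

test_that("log2 ratio track is exact, antisymmetric and grid-checked", {
  starts <- seq(0, 950, 50)
  cut <- bin_track("chr1", starts, starts + 50, rep(3, 20))
  uncut <- bin_track("chr1", starts, starts + 50, rep(1, 20))
  lr <- log2_ratio_track(cut, uncut, pseudocount = 1)
  expect_equal(lr$value, rep(1, 20)) # log2(4/2)
  expect_equal(log2_ratio_track(cut, cut)$value, rep(0, 20))

  set.seed(2)
  a <- bin_track("chr1", starts, starts + 50, rpois(20, 40))
  b <- bin_track("chr1", starts, starts + 50, rpois(20, 40))
  expect_equal(log2_ratio_track(a, b)$value, -log2_ratio_track(b, a)$value)
  expect_equal(log2_ratio_track(a, b)$value,
               log2((a$value + 1) / (b$value + 1)), tolerance = 1e-12)

  shifted <- bin_track("chr1", starts + 25, starts + 75, rep(1, 20))
  expect_error(log2_ratio_track(cut, shifted), "alignment error")
})

test_that("top-site selection is deterministic under ties", {
  sites <- cut_site_table(
    chrom = "chr1", position = seq(1000, 100000, length.out = 100),
    cleavage_score = 1:100, genic = rep(c(TRUE, FALSE), 50)
  )
  top <- select_top_sites(sites, 50)
  expect_setequal(top$cleavage_score, 51:100)
  expect_warning(allof <- select_top_sites(sites, 200), "exceeds")
  expect_equal(nrow(allof), 100L)

  # ties at the boundary: sort-then-slice oracle with (chrom, position) order
  set.seed(3)
  tied <- cut_site_table(
    chrom = sample(c("chr1", "chr2"), 30, TRUE),
    position = sample.int(1e6, 30),
    cleavage_score = sample(c(5, 7, 9), 30, TRUE),
    genic = FALSE
  )
  got <- select_top_sites(tied, 10)
  ord <- order(-tied$cleavage_score, tied$chrom, tied$position)
  expect_identical(got$site_id, tied$site_id[ord[1:10]])
})

test_that("bin assignment enforces the 90% rule exactly at the boundary", {
  iv <- distance_intervals()
  expect_identical(iv$interval, c("0-0.5", "0.5-1", "1-1.5", "1.5-2", "2-2.5"))
  site <- cut_site_table("chr1", 10000, 1, TRUE, site_id = "s1")

  # a bin wholly inside [pos+500, pos+1000) lands in 0.5-1
  tr <- bin_track("chr1", 10600, 10650, 2.5, bin_width = 50)
  a <- assign_bins(tr, site, iv)
  expect_equal(nrow(a), 1L)
  expect_identical(a$interval, "0.5-1")

  # overlap 45/50 bp (exactly 0.9): assigned; 44/50: not
  tr45 <- bin_track("chr1", 10455, 10505, 1, bin_width = 50)
  expect_equal(nrow(assign_bins(tr45, site, iv[1, ])), 1L)
  tr44 <- bin_track("chr1", 10456, 10506, 1, bin_width = 50)
  expect_equal(nrow(assign_bins(tr44, site, iv[1, ])), 0L)

  # a bin straddling two windows of one site never satisfies both
  strad <- bin_track("chr1", seq(9000, 10950, 50), seq(9050, 11000, 50), 1,
                     bin_width = 50)
  asg <- assign_bins(strad, site, iv)
  expect_false(any(duplicated(asg[, c("site_id", "start")])))
})

test_that("bin assignment equals the quadratic brute-force oracle", {
  set.seed(4)
  iv <- distance_intervals()
  starts <- sort(sample.int(2e5, 600))
  tr <- bin_track("chr1", starts * 50, starts * 50 + 50,
                  rnorm(600), bin_width = 50)
  sites <- cut_site_table("chr1", sort(sample.int(1e7, 10)),
                          runif(10), runif(10) < 0.5)
  got <- assign_bins(tr, sites, iv)
  want <- brute_assign(tr, sites, iv, 0.9)
  got <- got[order(got$site_id, got$interval, got$start), ]
  expect_equal(nrow(got), nrow(want))
  expect_identical(got$site_id, want$site_id)
  expect_identical(got$interval, want$interval)
  expect_equal(got$start, want$start)
  expect_equal(got$value, want$value)
})

test_that("per-site window means aggregate assigned bins", {
  asg <- data.frame(
    site_id = c("s1", "s1", "s2"),
    interval = c("0-0.5", "0-0.5", "1-1.5"),
    chrom = "chr1", start = c(0, 50, 100), end = c(50, 100, 150),
    value = c(1, 3, 2), stringsAsFactors = FALSE
  )
  m <- site_interval_means(asg)
  expect_equal(m$mean_log2[m$site_id == "s1"], 2)
  expect_equal(m$mean_log2[m$site_id == "s2"], 2)
  expect_equal(m$n_bins, c(2L, 1L))

  set.seed(5)
  big <- data.frame(
    site_id = sample(sprintf("s%d", 1:8), 200, TRUE),
    interval = sample(c("0-0.5", "0.5-1"), 200, TRUE),
    chrom = "chr1", start = seq_len(200) * 50, end = seq_len(200) * 50 + 50,
    value = rnorm(200), stringsAsFactors = FALSE
  )
  m2 <- site_interval_means(big)
  orc <- aggregate(value ~ site_id + interval, big, mean)
  key <- paste(m2$site_id, m2$interval)
  expect_equal(m2$mean_log2[match(paste(orc$site_id, orc$interval), key)],
               orc$value, tolerance = 1e-12)
})

test_that("signed-rank test pins the standard conventions", {
  # n = 5 all positive: one-sided 1/2^5, two-sided doubled
  expect_equal(signed_rank_test(c(1, 2, 3, 4, 5), alternative = "greater")$p.value,
               0.03125)
  expect_equal(signed_rank_test(c(1, 2, 3, 4, 5))$p.value, 0.0625)
  # zeros dropped; all-zero sample withholds the test
  z <- signed_rank_test(rep(0, 8))
  expect_true(is.na(z$p.value))
  expect_equal(z$n_zero, 8L)
  mix <- signed_rank_test(c(0, 0, 1, 2, 3, 4, 5))
  expect_equal(mix$n_used, 5L)
  expect_equal(mix$p.value, 0.0625)
  # tied magnitudes fall back to the corrected normal approximation
  expect_false(signed_rank_test(c(1, 1, 2, -2, 3))$exact)
})

test_that("exact branch equals full 2^n enumeration for n <= 10", {
  set.seed(6)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    x <- round(rnorm(n), 6)
    while (anyDuplicated(abs(x)) || any(x == 0)) x <- round(rnorm(n), 6)
    expect_equal(signed_rank_test(x)$p.value, enum_signed_rank_p(x),
                 tolerance = 1e-12)
  }
})

test_that("stratified testing withholds underpowered windows", {
  enr <- data.frame(
    site_id = sprintf("s%d", 1:8),
    interval = rep("0-0.5", 8),
    mean_log2 = c(rep(0.5, 6), -0.1, 0.2),
    n_bins = 10L, stringsAsFactors = FALSE
  )
  sites <- cut_site_table("chr1", seq(1e4, 8e4, 1e4), 1:8,
                          genic = c(rep(TRUE, 6), FALSE, FALSE),
                          site_id = sprintf("s%d", 1:8))
  expect_warning(
    out <- stratify_and_test(enr, sites, min_sites = 5),
    "withheld"
  )
  all_row <- out[out$stratum == "all", ]
  expect_equal(all_row$n, 8L)
  expect_false(is.na(all_row$p))
  expect_true(is.na(out$p[out$stratum == "nongenic"])) # only 2 sites
  # bonferroni multiplies by the number of windows (here 1, unchanged)
  out_b <- suppressWarnings(stratify_and_test(enr, sites, bonferroni = TRUE))
  expect_equal(out_b$p[out_b$stratum == "all"], all_row$p)
})
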
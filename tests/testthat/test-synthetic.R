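# Synthetic-data generators: ground truth bookkeeping, determinism,
# distributional behaviour and round trips through the readers.

test_that("SMLM ground truth matches the colocalization fraction dial", {
  s0 <- simulate_smlm_nucleus(smlm_sim_spec(coloc_fraction = 0), seed = 1)
  expect_equal(sum(s0$truth$b$coloc), 0L)

  s1 <- simulate_smlm_nucleus(
    smlm_sim_spec(coloc_fraction = 1, jitter_sd = 0, background_density = 0),
    seed = 2
  )
  expect_true(all(s1$truth$b$coloc))
  # every B centroid coincides with some A centroid
  match_dist <- vapply(seq_len(nrow(s1$truth$b)), function(i) {
    min(sqrt((s1$truth$a$x - s1$truth$b$x[i])^2 +
               (s1$truth$a$y - s1$truth$b$y[i])^2))
  }, numeric(1))
  expect_true(all(match_dist < 1e-9))
})

test_that("number of colocalized B clusters is Binomial(n_B, f) across seeds", {
  spec <- smlm_sim_spec(coloc_fraction = 0.5, n_clusters_a = 10,
                        n_clusters_b = 40, locs_per_cluster = 1,
                        background_density = 0)
  counts <- vapply(1:400, function(s) {
    sum(simulate_smlm_nucleus(spec, seed = s)$truth$b$coloc)
  }, numeric(1))
  # chi-square goodness of fit against Binomial(40, 0.5), pooled tails
  br <- c(-Inf, 16:24, Inf)
  obs <- table(cut(counts, br))
  p <- diff(pbinom(c(-Inf, 16:24, Inf), 40, 0.5))
  expect_gt(suppressWarnings(chisq.test(obs, p = p)$p.value), 0.01)
})

test_that("simulators are deterministic and round-trip their file dialects", {
  spec <- smlm_sim_spec(n_clusters_a = 10, n_clusters_b = 10)
  a <- simulate_smlm_nucleus(spec, seed = 9)
  b <- simulate_smlm_nucleus(spec, seed = 9)
  expect_identical(a, b)

  f <- withr::local_tempfile(fileext = ".csv")
  write_localizations(a$locs, f, loc_dialect(channel = "channel",
                                             nucleus = "nucleus_id"))
  back <- read_localizations(f, loc_dialect(channel = "channel",
                                            nucleus = "nucleus_id"))
  expect_equal(nrow(back), nrow(a$locs))
  expect_equal(back$x, a$locs$x, tolerance = 1e-6)
  expect_identical(back$channel, a$locs$channel)

  d1 <- simulate_drip_experiment(drip_sim_spec(chrom_length = 1e6, n_sites = 5),
                                 seed = 4)
  d2 <- simulate_drip_experiment(drip_sim_spec(chrom_length = 1e6, n_sites = 5),
                                 seed = 4)
  expect_identical(d1, d2)

  fb <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(d1$cut, fb)
  tb <- read_bedgraph(fb)
  expect_equal(tb$start, d1$cut$start)
  expect_equal(tb$value, d1$cut$value)

  fs <- withr::local_tempfile(fileext = ".bed")
  write_cut_sites(d1$sites, fs)
  sb <- read_cut_sites(fs)
  expect_equal(sb$position, d1$sites$position)
  expect_identical(sb$genic, d1$sites$genic)
  expect_identical(sb$site_id, d1$sites$site_id)
  expect_equal(sb$cleavage_score, d1$sites$cleavage_score, tolerance = 1e-6)
})

test_that("flat amplitude in the Poisson limit recovers its expectation", {
  spec <- drip_sim_spec(chrom_length = 1.5e6, n_sites = 10, baseline = 100,
                        peak_fold = 2, shape = "flat", dispersion = Inf)
  sim <- simulate_drip_experiment(spec, seed = 11)
  prof <- drip_profile(sim$cut, sim$uncut, sim$sites, top_k = 10,
                       total_reads_cut = sim$library_size_cut,
                       total_reads_uncut = sim$library_size_uncut)
  # expectation oracle: log2 of the pseudocounted RPKM ratio at the means
  scale <- (50 / 1000) * (sim$library_size_uncut / 1e6)
  want <- log2((200 / scale + 1) / (100 / scale + 1))
  per_int <- tapply(prof$per_site$mean_log2, prof$per_site$interval, mean)
  expect_true(all(abs(per_int - want) < 0.05))
  expect_true(all(abs(per_int - 1) < 0.1))
})

test_that("null amplitude gives flat profiles near zero", {
  sim <- simulate_drip_experiment(drip_sim_spec(peak_fold = 1), seed = 12)
  prof <- drip_profile(sim$cut, sim$uncut, sim$sites,
                       total_reads_cut = sim$library_size_cut,
                       total_reads_uncut = sim$library_size_uncut)
  med <- prof$summary$median[prof$summary$stratum == "all"]
  expect_true(all(abs(med) < 0.05))
  expect_true(all(sim$truth$expected_log2 == 0))
})

test_that("qPCR simulation recovers folds exactly at cv = 0", {
  tab <- simulate_qpcr_table(c(locus1 = 3, locus2 = 1.4), cv = 0,
                             n_replicates = 4, seed = 13)
  got <- fold_induction_table(tab)
  expect_equal(sort(got$summary$mean_fold), c(1.4, 3), tolerance = 1e-12)
  expect_equal(got$summary$sem, c(0, 0), tolerance = 1e-12)
})

test_that("cut sites respect separation and margins", {
  spec <- drip_sim_spec(chrom_length = 2e6, n_sites = 20)
  sim <- simulate_drip_experiment(spec, seed = 14)
  pos <- sort(sim$sites$position)
  expect_true(all(diff(pos) >= 2 * spec$max_distance))
  expect_true(min(pos) >= spec$max_distance)
  expect_true(max(pos) <= spec$chrom_length - spec$max_distance)
  scr <- scramble_sites(sim$sites, spec, seed = 15)
  dmin <- vapply(scr$position, function(p) min(abs(p - sim$sites$position)),
                 numeric(1))
  expect_true(all(dmin >= spec$max_distance))
})
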
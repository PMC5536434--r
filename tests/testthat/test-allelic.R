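site1 <- list(id = "s1", chrom = "chr1", pos = 5000, ref = "A", alt = "G")

test_that("count_alleles quantifies both alleles with quality filtering", {
  f <- tempfile(fileext = ".sam")
  simulate_allelic_sam(f, site1, n_ref = 5, n_alt = 5)
  ac <- count_alleles(f, site1)
  expect_equal(c(ac$count_a, ac$count_b, ac$n_other), c(5L, 5L, 0L))

  # 3 A reads at Q40 plus 1 G read below min_base_q -> (3, 0, 0)
  reads <- data.frame(
    qname = c("a", "b", "c", "d"), chrom = "chr1", pos1 = 4991, mapq = 60,
    cigar = "21M",
    seq = paste0("ACGTACGTAC", c("A", "A", "A", "G"), "ACGTACGTAC"),
    qual = c(rep(strrep("I", 21), 3), strrep("#", 21)),  # '#' = Q2
    stringsAsFactors = FALSE)
  ac2 <- count_alleles(sam_fixture(reads), site1, min_base_q = 20)
  expect_equal(c(ac2$count_a, ac2$count_b, ac2$n_other), c(3L, 0L, 0L))

  # low-MAPQ reads excluded
  reads$mapq <- c(60, 60, 5, 60)
  reads$qual <- strrep("I", 21)
  ac3 <- count_alleles(sam_fixture(reads), site1, min_map_q = 10)
  expect_equal(c(ac3$count_a, ac3$count_b), c(2L, 1L))

  # a read whose deletion spans the site contributes nothing there
  readsd <- data.frame(
    qname = c("a", "b"), chrom = "chr1", pos1 = c(4991, 4991), mapq = 60,
    cigar = c("21M", "10M5D11M"),
    seq = c(paste0("ACGTACGTAC", "A", "ACGTACGTAC"), strrep("ACGTACG", 3)),
    qual = strrep("I", 21), stringsAsFactors = FALSE)
  ac4 <- count_alleles(sam_fixture(readsd), site1)
  expect_equal(c(ac4$count_a, ac4$count_b, ac4$n_other), c(1L, 0L, 0L))

  # third-allele bases go to n_other; reads are conserved
  f5 <- tempfile(fileext = ".sam")
  simulate_allelic_sam(f5, site1, n_ref = 4, n_alt = 3, n_other = 2)
  ac5 <- count_alleles(f5, site1)
  expect_equal(c(ac5$count_a, ac5$count_b, ac5$n_other), c(4L, 3L, 2L))
  expect_equal(ac5$count_a + ac5$count_b + ac5$n_other, 9L)

  expect_error(count_alleles(f5, list(chrom = "chrZ", pos = 10, ref = "A", alt = "G")),
               "absent from alignment header")
})

test_that("calibrated_ratio divides assay ratios by the mean input ratio", {
  expect_equal(calibrated_ratio(2.0, ratio_calibration(c(1.1, 0.9, 1.0))), 2.0)
  expect_equal(calibrated_ratio(1.6, ratio_calibration(0.8)), 2.0)
  expect_equal(calibrated_ratio(1.0, ratio_calibration(c(1, 1))), 1.0)

  ac <- site_allele_count(site1, "chip", count_a = 100, count_b = 300)
  calib <- ratio_calibration(c(1.5, 1.5))
  expect_equal(calibrated_ratio(ac, calib), 2.0)
  # equivariance: scaling both counts leaves the ratio unchanged
  ac2 <- site_allele_count(site1, "chip", count_a = 700, count_b = 2100)
  expect_equal(calibrated_ratio(ac2, calib), calibrated_ratio(ac, calib))

  hom <- site_allele_count(site1, "chip", count_a = 0, count_b = 50)
  expect_error(calibrated_ratio(hom, calib), "undefined ratio")
  expect_error(ratio_calibration(c(1, -2)), "positive")
  # geometric option
  expect_equal(ratio_calibration(c(2, 0.5), "geometric")$mean_input_ratio, 1.0)
})

test_that("test_imbalance_counts is the exact two-sided binomial test", {
  p_sym <- test_imbalance_counts(list(count_a = 10, count_b = 10))
  expect_equal(p_sym$p_value, 1)

  p_ext <- test_imbalance_counts(list(count_a = 20, count_b = 0))
  expect_equal(p_ext$p_value, 2 * 0.5^20, tolerance = 1e-12)

  # (5, 15): two-sided sum over k <= 5 and k >= 15 at n = 20, p = 1/2
  p_two <- test_imbalance_counts(list(count_a = 5, count_b = 15))
  oracle <- sum(dbinom(c(0:5, 15:20), 20, 0.5))
  expect_equal(p_two$p_value, oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 4), 0.0414)

  # non-unit null ratio shifts the null success probability
  p_null2 <- test_imbalance_counts(list(count_a = 10, count_b = 20), null_ratio = 2)
  expect_equal(p_null2$p_value, 1)

  expect_error(test_imbalance_counts(list(count_a = 0, count_b = 0)), "at least one")
})

test_that("test_imbalance_ratios is the two-sided rank-sum test", {
  same <- c(1.0, 1.1, 0.9, 1.05)
  expect_gt(test_imbalance_ratios(same, same)$p_value, 0.99)

  # complete separation at 4 vs 4: exact p = 2/70
  r <- test_imbalance_ratios(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(r$p_value, 2 / 70, tolerance = 1e-12)
  expect_gt(r$ratio, 0)

  # shift recovery
  set.seed(17)
  detected <- mean(replicate(50, {
    ctrl <- rnorm(6, 1, 0.1)
    test_imbalance_ratios(ctrl + 2, ctrl)$p_value < 0.05
  }))
  expect_gt(detected, 0.95)

  expect_error(test_imbalance_ratios(rep(1, 4), rep(1, 4)), "degenerate")
  expect_error(test_imbalance_ratios(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("normalized_site_enrichment is a double ratio, scale-invariant", {
  expect_equal(normalized_site_enrichment(1, 1, 1, 1), 1.0)
  expect_equal(normalized_site_enrichment(4, 2, 3, 3), 2.0)
  expect_equal(normalized_site_enrichment(4 * 7, 2 * 7, 3 * 7, 3 * 7), 2.0)
  expect_error(normalized_site_enrichment(1, 0, 1, 1), "positive")
})

test_that("ddct_fold_change implements 2^-ddCt", {
  a <- qpcr_measurement(24, 20, "dmog")
  expect_equal(ddct_fold_change(a, a), 1.0)
  b <- qpcr_measurement(23, 20, "untreated")  # ddCt = -1 vs (24 - 20)
  expect_equal(ddct_fold_change(b, a), 2.0)
  c_ <- list(ct_target = 23.32, ct_housekeeping = 20)
  ref <- list(ct_target = 20, ct_housekeeping = 20)
  expect_equal(ddct_fold_change(c_, ref), 2^-3.32)
  expect_equal(round(2^-3.32, 3), 0.100)
  expect_error(qpcr_measurement(Inf, 20), "finite")
})

test_that("simulated allelic assays recover the true ratio and type-I rate", {
  # 50 sites, depth 1000, true calibrated ratio 2.0: mean within 5%
  set.seed(2024)
  sim <- simulate_allelic_reads(n_sites = 50, depth = 1000, true_ratio = 2.0,
                                input_depth = 1000)
  chip <- sim[sim$assay == "chip", ]
  inp <- sim[sim$assay == "input", ]
  ratios <- vapply(seq_len(nrow(chip)), function(i) {
    calibrated_ratio(chip$count_b[i] / chip$count_a[i],
                     ratio_calibration(inp$count_b[i] / inp$count_a[i]))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2.0) / 2.0, 0.05)

  # balanced sites: exact binomial rejects at ~alpha (module-scale check)
  sim0 <- simulate_allelic_reads(n_sites = 2000, depth = 1000, true_ratio = 1.0)
  chip0 <- sim0[sim0$assay == "chip", ]
  rej <- mean(vapply(seq_len(nrow(chip0)), function(i)
    test_imbalance_counts(list(count_a = chip0$count_a[i],
                               count_b = chip0$count_b[i]))$p_value < 0.05,
    logical(1)))
  expect_lt(abs(rej - 0.05), 0.025)

  # homozygous-control behaviour: count_a ~ 0, undefined-ratio error path
  simh <- simulate_allelic_reads(n_sites = 1, depth = 100, true_ratio = 1,
                                 n_homozygous = 1, seed = 3)
  hom <- simh[simh$site == "hom_site1" & simh$assay == "chip", ]
  expect_equal(hom$count_a, 0L)
  sac <- site_allele_count(site1, "chip", hom$count_a, hom$count_b)
  expect_error(calibrated_ratio(sac, ratio_calibration(1)), "undefined ratio")

  # degenerate depth
  expect_equal(nrow(simulate_allelic_reads(depth = 0)), 0L)
})
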
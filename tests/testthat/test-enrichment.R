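test_that("locus_structure reduces a block to rigid SNP offsets", {
  s1 <- locus_structure(data.frame(id = "b", chrom = "chr1", pos = 500))
  expect_equal(s1$offsets, 0)
  expect_equal(s1$width, 1)

  s <- locus_structure(data.frame(id = "b", chrom = "chr1", pos = c(400, 100, 150)))
  expect_equal(s$offsets, c(0, 50, 300))
  expect_equal(s$width, 301)

  # translation invariance
  s2 <- locus_structure(data.frame(id = "b", chrom = "chr1",
                                   pos = c(400, 100, 150) + 12345))
  expect_equal(s2$offsets, s$offsets)
})

test_that("empirical_p matches the tail-frequency definition", {
  null <- null_distribution(rep(0L, 1000), max_value = 5)
  expect_equal(empirical_p(0, null, "plug_in"), 1)          # every draw >= 0
  expect_equal(empirical_p(3, null, "plug_in"), 0)
  expect_equal(empirical_p(3, null, "add_one"), 1 / 1001)

  # histogram {3: 500, 4: 300, 5: 200}, observed 4 -> 0.5
  counts <- c(rep(3L, 500), rep(4L, 300), rep(5L, 200))
  null2 <- null_distribution(counts, max_value = 5)
  expect_equal(sum(null2$counts), null2$n_iter)
  expect_equal(empirical_p(4, null2, "plug_in"), 0.5)
})

test_that("shuffle_loci places structures proportionally to valid anchors", {
  g <- genome(c("chrA", "chrB"), c(1000, 3000))
  s <- locus_structure(data.frame(chrom = "chr1", pos = 0))
  set.seed(31)
  draws <- replicate(10000, shuffle_loci(list(s), g)[[1]]$chrom)
  frac_b <- mean(draws == "chrB")
  se <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(frac_b - 0.75), 3 * se)

  # internal offsets preserved exactly; determinism under seed
  s3 <- locus_structure(data.frame(chrom = "chr1", pos = c(0, 70, 200)))
  set.seed(5); a <- shuffle_loci(list(s3), g)
  set.seed(5); b <- shuffle_loci(list(s3), g)
  expect_identical(a, b)
  expect_equal(diff(a[[1]]$pos), c(70, 130))
  expect_true(all(a[[1]]$pos >= 0 & a[[1]]$pos < chrom_length(g, a[[1]]$chrom[1])))

  # structure wider than every chromosome
  wide <- locus_structure(data.frame(chrom = "chr1", pos = c(0, 5000)))
  expect_error(shuffle_loci(list(wide), g), "does not fit")

  # mask rejection: SNPs never land in the mask
  mask <- interval_set("chrB", 0, 2900)
  set.seed(8)
  for (i in 1:50) {
    pl <- shuffle_loci(list(s3), g, mask = mask)[[1]]
    if (pl$chrom[1] == "chrB") expect_true(all(pl$pos >= 2900))
  }
})

test_that("shuffle_peaks resamples the universe preserving widths", {
  g <- genome("chr1", 10000)
  uni <- interval_set("chr1", seq(0, 9000, 1000), seq(0, 9000, 1000) + 100)
  peaks <- interval_set("chr1", c(0, 200, 400), c(50, 280, 520))
  set.seed(2)
  sp <- shuffle_peaks(peaks, uni, g)
  expect_equal(nrow(sp), 3L)
  expect_setequal(sp$end - sp$start, peaks$end - peaks$start)

  # |peaks| == |universe|: every element used exactly once
  peaks10 <- interval_set("chr1", seq(0, 900, 100), seq(0, 900, 100) + 10)
  sp10 <- shuffle_peaks(peaks10, uni, g)
  mids <- floor((uni$start + uni$end) / 2)
  expect_setequal(floor((sp10$start + sp10$end) / 2), mids)

  # clipping at the chromosome tail shortens, never lengthens
  gshort <- genome("chr1", 1000)
  uni2 <- interval_set("chr1", c(0, 900), c(100, 1000))
  bigpeak <- interval_set("chr1", 0, 600)
  set.seed(3)
  for (i in 1:10) {
    spc <- shuffle_peaks(bigpeak, uni2, gshort)
    expect_lte(spc$end - spc$start, 600)
    expect_gte(spc$start, 0)
    expect_lte(spc$end, 1000)
  }

  expect_error(shuffle_peaks(uni, bigpeak, g), "smaller")
})

test_that("run_enrichment reproduces exhaustive-enumeration nulls on toy genomes", {
  # one chromosome [0,100), peak [0,50), 1-SNP block: p(hit) = 0.5 exactly
  g <- genome("chr1", 100)
  peaks <- interval_set("chr1", 0, 50)
  block <- list(data.frame(id = "b1", chrom = "chr1", pos = 10))
  p_oracle <- oracle_hit_prob(0, as.data.frame(g), peaks)
  expect_equal(p_oracle, 0.5)
  r <- run_enrichment(block, peaks, g, config = shuffle_config(n_iter = 20000, seed = 11))
  mc_mean <- sum(r$null$values * r$null$counts) / r$null$n_iter
  expect_lt(abs(mc_mean - 0.5), 3 * sqrt(0.25 / 20000))

  # two disjoint peaks [0,10) and [90,100): p(hit) = 0.20
  peaks2 <- interval_set(c("chr1", "chr1"), c(0, 90), c(10, 100))
  expect_equal(oracle_hit_prob(0, as.data.frame(g), peaks2), 0.2)
  r2 <- run_enrichment(block, peaks2, g, config = shuffle_config(n_iter = 20000, seed = 12))
  mc2 <- sum(r2$null$values * r2$null$counts) / r2$null$n_iter
  expect_lt(abs(mc2 - 0.2), 3 * sqrt(0.2 * 0.8 / 20000))

  # multi-SNP structures on a 10 kb genome vs the Poisson-binomial oracle
  g3 <- genome(c("chr1", "chr2"), c(6000, 4000))
  peaks3 <- interval_set(c("chr1", "chr2"), c(1000, 500), c(1400, 900))
  blocks3 <- list(
    data.frame(id = "a", chrom = "chr1", pos = c(100, 180)),
    data.frame(id = "b", chrom = "chr1", pos = c(2000, 2100, 2500)),
    data.frame(id = "c", chrom = "chr2", pos = 3000))
  ps <- vapply(blocks3, function(b)
    oracle_hit_prob(sort(b$pos) - min(b$pos), as.data.frame(g3), peaks3),
    numeric(1))
  pmf <- oracle_null_pmf(ps)
  r3 <- run_enrichment(blocks3, peaks3, g3,
                       config = shuffle_config(n_iter = 50000, seed = 13))
  expected <- pmf * r3$null$n_iter
  keep <- expected > 5
  chi <- sum((r3$null$counts[keep] - expected[keep])^2 / expected[keep])
  expect_gt(pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("run_enrichment is deterministic, order-invariant and bounded", {
  g <- genome(c("chr1", "chr2"), c(5000, 5000))
  peaks <- interval_set(c("chr1", "chr2"), c(100, 2000), c(600, 2600))
  blocks <- list(
    data.frame(id = "a", chrom = "chr1", pos = c(150, 350)),
    data.frame(id = "b", chrom = "chr2", pos = 4000),
    data.frame(id = "c", chrom = "chr1", pos = c(4500, 4600)))

  cfg <- shuffle_config(n_iter = 2000, seed = 99)
  r1 <- run_enrichment(blocks, peaks, g, config = cfg)
  r2 <- run_enrichment(blocks, peaks, g, config = cfg)
  expect_identical(r1$null$counts, r2$null$counts)   # bit-identical histogram
  expect_identical(r1$p_value, r2$p_value)

  # observed statistic does not depend on input ordering
  r3 <- run_enrichment(rev(blocks), sort_intervals(peaks)[c(2, 1), ], g, config = cfg)
  expect_equal(r3$observed, r1$observed)

  expect_gte(r1$observed, 0)
  expect_lte(r1$observed, length(blocks))
  expect_equal(sum(r1$null$counts), cfg$n_iter)

  # saturating peaks: observed = #blocks, p = 1
  sat <- interval_set(c("chr1", "chr2"), c(0, 0), c(5000, 5000))
  rs <- run_enrichment(blocks, sat, g,
                       config = shuffle_config(n_iter = 500, seed = 1))
  expect_equal(rs$observed, 3L)
  expect_equal(rs$p_value, 1)
})

test_that("peaks_shuffle direction counts peaks hitting blocks under the null", {
  g <- genome("chr1", 100000)
  uni <- interval_set("chr1", seq(0, 99000, 1000), seq(0, 99000, 1000) + 200)
  peaks <- uni[c(1, 5, 9), ]
  blocks <- list(data.frame(id = "b", chrom = "chr1", pos = c(100, 4100)))
  cfg <- shuffle_config(n_iter = 4000, seed = 21, direction = "peaks_shuffle")
  r <- run_enrichment(blocks, peaks, g, universe = uni, config = cfg)
  expect_equal(r$observed, 2L)  # peaks 1 and 5 contain the two SNPs
  # null mean: each surrogate peak covers an element containing a SNP with
  # prob 2/100 (2 of 100 universe elements contain block SNPs), 3 draws
  mc_mean <- sum(r$null$values * r$null$counts) / r$null$n_iter
  expect_lt(abs(mc_mean - 3 * 2 / 100), 4 * sqrt(0.06 / 4000) + 0.01)
  expect_error(run_enrichment(blocks, peaks, g, config = cfg), "universe")
})
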
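sim_counts <- function(n_genes, n_samples, mu = 200, disp = 0.2, seed = 1) {
  set.seed(seed)
  matrix(rnbinom(n_genes * n_samples, size = 1 / disp, mu = mu),
         nrow = n_genes,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

test_that("size_factors implements median-of-ratios with a depth fallback", {
  m <- sim_counts(200, 4)
  m2 <- cbind(m, m[, 1])
  sf <- size_factors(m2)
  expect_equal(sf[[1]], sf[[5]])                      # identical samples
  m3 <- cbind(m[, 1], m[, 1] * 2)
  sf3 <- size_factors(m3)
  expect_equal(sf3[[2]] / sf3[[1]], 2)                # doubled sample
  expect_equal(unname(size_factors(m[sample(nrow(m)), ])),
               unname(size_factors(m)))               # gene-order invariant
  # cross-check against the DESeq2 estimator
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
  # sparse matrix: fewer than 10 all-positive genes -> total-count scaling
  sp <- matrix(c(5, 0, 0, 10), 2, 2)
  expect_equal(unname(size_factors(sp)), c(sqrt(0.5), sqrt(2)))
})

test_that("metagene_score is a mean z of log2 normalized expression", {
  m <- sim_counts(50, 6)
  same <- matrix(rep(m[, 1], 6), ncol = 6,
                 dimnames = list(rownames(m), paste0("s", 1:6)))
  expect_true(all(abs(metagene_score(same, rownames(m)[1:10])) < 1e-12))

  # a sample with every set gene doubled scores strictly highest
  boosted <- m
  boosted[1:10, 3] <- boosted[1:10, 3] * 8
  sc <- metagene_score(boosted, rownames(m)[1:10], sf = rep(1, 6))
  expect_equal(unname(which.max(sc)), 3L)

  # invariant to genes outside the set (fixed size factors)
  sub <- metagene_score(m[1:20, ], rownames(m)[1:10], sf = rep(1, 6))
  full <- metagene_score(m, rownames(m)[1:10], sf = rep(1, 6))
  expect_equal(sub, full)

  expect_message(metagene_score(m, c(rownames(m)[1:5], "absent_gene"), sf = rep(1, 6)),
                 "absent")
  expect_error(metagene_score(m, c("nope1", "nope2")), "no metagene")
})

test_that("tertile_stratify balances groups and resists monotone transforms", {
  s9 <- tertile_stratify(c(5, 1, 9, 3, 7, 2, 8, 4, 6))
  expect_equal(as.integer(table(s9$tertile)), c(3L, 3L, 3L))
  expect_equal(as.character(s9$tertile[c(2, 6)]), c("low", "low"))

  s10 <- tertile_stratify(1:10)
  expect_equal(as.integer(table(s10$tertile)), c(4L, 3L, 3L))  # extra goes low

  x <- rnorm(31)
  expect_identical(tertile_stratify(x)$tertile, tertile_stratify(exp(x))$tertile)
  expect_error(tertile_stratify(c(1, 2)), "at least 3")
})

test_that("nb_glm_lrt: nesting, Poisson limit, flat data and error paths", {
  set.seed(42)
  n <- 120
  g <- sample(c("AA", "AB", "BB"), n, replace = TRUE, prob = c(.49, .42, .09))
  sf <- rep(1, n)

  # flat counts: LRT ~ 0, p ~ 1
  flat <- nb_glm_lrt(rep(7L, n), g, sf)
  expect_lt(flat$lrt_stat, 1e-6)
  expect_gt(flat$p_value, 0.999)

  # Poisson limit: with dispersion -> 0 the LRT matches a Poisson GLM LRT
  y <- rpois(n, 50 * exp(0.3 * (g == "BB")))
  r_nb <- nb_glm_lrt(y, g, sf, dispersion = 1e-9)
  gf <- factor(g)
  p1 <- glm(y ~ gf, family = poisson)
  p0 <- glm(y ~ 1, family = poisson)
  lrt_pois <- 2 * (logLik(p1) - logLik(p0))
  expect_lt(abs(r_nb$lrt_stat - as.numeric(lrt_pois)), 1e-3)
  expect_equal(r_nb$df, 2L)

  # nesting: the genotype model never has lower likelihood
  for (i in 1:10) {
    yy <- rnbinom(n, size = 5, mu = 100)
    expect_gte(nb_glm_lrt(yy, g, sf)$lrt_stat, 0)
  }

  # additive coding has df 1 and reports beta
  r_add <- nb_glm_lrt(y, g, sf, coding = "additive")
  expect_equal(r_add$df, 1L)
  expect_false(is.na(r_add$beta))

  # all-zero genotype group falls back to additive coding, flagged
  y0 <- rnbinom(n, size = 5, mu = 60)
  y0[g == "BB"] <- 0L
  r0 <- nb_glm_lrt(y0, g, sf)
  expect_equal(r0$coding, "additive")
  expect_match(r0$note, "all-zero")

  expect_error(nb_glm_lrt(rpois(4, 10), c("AA", "AA", "AA", "AB"), rep(1, 4)),
               "2 genotype groups")
})

test_that("nb_glm_lrt is calibrated under the null and recovers beta", {
  set.seed(77)
  n <- 150
  g <- sample(c("AA", "AB", "BB"), n, replace = TRUE, prob = c(.49, .42, .09))
  sf <- exp(rnorm(n, 0, 0.15))

  # null calibration (module-scale; the full 1,000-gene run is in the
  # acceptance suite)
  rej <- mean(replicate(300, {
    y <- rnbinom(n, size = 5, mu = 150 * sf)
    nb_glm_lrt(y, g, sf)$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.035)

  # beta recovery with additive coding
  beta <- log(1.5)
  dose <- c(AA = 0, AB = 1, BB = 2)[g]
  est <- replicate(60, {
    y <- rnbinom(n, size = 5, mu = 150 * sf * exp(beta * dose))
    nb_glm_lrt(y, g, sf, coding = "additive")$beta
  })
  expect_lt(abs(mean(est) - beta), 0.1)
})

test_that("size-factor rescaling of one sample barely moves the LRT", {
  set.seed(8)
  n <- 100
  g <- sample(c("AA", "AB", "BB"), n, replace = TRUE, prob = c(.5, .4, .1))
  sf <- rep(1, n)
  y <- rnbinom(n, size = 5, mu = 100)
  base <- nb_glm_lrt(y, g, sf, dispersion = 0.2)$lrt_stat
  y2 <- y; y2[1] <- y[1] * 2L
  sf2 <- sf; sf2[1] <- 2
  resc <- nb_glm_lrt(y2, g, sf2, dispersion = 0.2)$lrt_stat
  expect_lt(abs(resc - base), 0.05)
})

test_that("conditional_eqtl localizes the genotype effect to the high stratum", {
  sim <- simulate_expression(n_samples = 450, seed = 11)
  res <- conditional_eqtl(sim$counts, sim$genotype, sim$metagenes$HIF1, "TARGET")
  expect_equal(res$stratum, c("low", "mid", "high"))
  expect_equal(sum(res$n), 450L)
  expect_lt(res$p_value[res$stratum == "high"], 1e-3)
  expect_gt(res$p_value[res$stratum == "low"], 0.05)
  # group means rise with dose in the high stratum
  hi <- res[res$stratum == "high", ]
  expect_gt(hi$mean_BB, hi$mean_AA)

  # no effect anywhere: p-values stay unremarkable under the null
  sim0 <- simulate_expression(n_samples = 180, beta = 0, seed = 4)
  res0 <- conditional_eqtl(sim0$counts, sim0$genotype, sim0$metagenes$HIF1, "TARGET")
  expect_true(all(res0$p_value > 1e-4))

  expect_error(conditional_eqtl(sim$counts, sim$genotype[1:10],
                                sim$metagenes$HIF1, "TARGET"), "length")
  expect_error(conditional_eqtl(sim$counts, sim$genotype,
                                sim$metagenes$HIF1, "NOPE"), "target gene")
})

test_that("inducibility_by_genotype handles unbalanced designs", {
  set.seed(66)
  fc_same <- rnorm(12, 2, 0.3)
  r_same <- inducibility_by_genotype(c(fc_same, fc_same),
                                     rep(c("AA", "AG"), each = 12))
  expect_gt(r_same$carrier_test$p_value, 0.9)

  # the 18/12/3 design
  g <- c(rep("AA", 18), rep("AG", 12), rep("GG", 3))
  fc <- c(rnorm(18, 1.2, 0.2), rnorm(12, 2.5, 0.3), rnorm(3, 2.8, 0.3))
  r <- inducibility_by_genotype(fc, g)
  expect_equal(r$summary$n, c(18L, 12L, 3L))
  expect_lt(r$carrier_test$p_value, 0.05)
  expect_equal(nrow(r$pairwise), 3L)
  expect_lt(r$pairwise$p_value[r$pairwise$group1 == "AA" &
                                 r$pairwise$group2 == "AB"], 0.05)
})
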
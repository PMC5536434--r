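make_panel <- function(haps, pos = NULL, chrom = "chr1") {
  n <- ncol(haps)
  if (is.null(pos)) pos <- seq_len(n) * 100
  haplotype_panel(
    data.frame(id = paste0("rs", seq_len(n)), chrom = chrom, pos = pos,
               ref = "A", alt = "G", stringsAsFactors = FALSE),
    haps)
}

test_that("haplotype_panel enforces its invariants", {
  h <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_s3_class(make_panel(h), "haplotype_panel")
  expect_error(make_panel(matrix(0, 1, 2)), "at least 2")
  expect_error(make_panel(matrix(c(0, 1, NA, 0), 2, 2)), "0/1")
  expect_error(haplotype_panel(
    data.frame(id = c("a", "a"), chrom = "chr1", pos = 1:2, ref = "A", alt = "G"),
    h), "duplicate")
  expect_error(haplotype_panel(
    data.frame(id = c("a", "b"), chrom = "chr1", pos = 1:2, ref = "A", alt = "A"),
    h), "differ")
})

test_that("r_squared matches direct haplotype counting and the Pearson oracle", {
  # duplicated column: perfect LD
  x <- rbinom(60, 1, 0.4); x[1] <- 1; x[2] <- 0
  expect_equal(r_squared(make_panel(cbind(x, x)), 1, 2), 1.0)

  # counts AB=40, Ab=10, aB=10, ab=40: D = 0.40 - 0.25 = 0.15, r2 = 0.36
  haps <- rbind(
    matrix(1, 40, 2),
    cbind(rep(1, 10), rep(0, 10)),
    cbind(rep(0, 10), rep(1, 10)),
    matrix(0, 40, 2))
  expect_equal(r_squared(make_panel(haps), 1, 2), 0.36)

  # independence limit
  set.seed(101)
  n <- 20000
  ind <- cbind(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
  expect_lt(r_squared(make_panel(ind), 1, 2), (3 / sqrt(n))^2 + 3 / sqrt(n))

  # r2 == squared Pearson correlation of the 0/1 columns, to 1e-12
  set.seed(7)
  for (rep in 1:50) {
    m <- cbind(rbinom(80, 1, runif(1, 0.1, 0.9)), rbinom(80, 1, runif(1, 0.1, 0.9)))
    if (length(unique(m[, 1])) < 2 || length(unique(m[, 2])) < 2) next
    p <- make_panel(m)
    expect_equal(r_squared(p, 1, 2), cor(m[, 1], m[, 2])^2, tolerance = 1e-12)
    expect_equal(r_squared(p, 1, 2), r_squared(p, 2, 1))          # symmetric
    expect_equal(r_squared(make_panel(cbind(1 - m[, 1], m[, 2])), 1, 2),
                 r_squared(p, 1, 2), tolerance = 1e-12)           # allele relabeling
  }

  mono <- cbind(rep(1, 10), rbinom(10, 1, 0.5))
  mono[1, 2] <- 1; mono[2, 2] <- 0
  expect_error(r_squared(make_panel(mono), 1, 2), "monomorphic")
})

test_that("build_block applies a strict r2 threshold within the window", {
  set.seed(5)
  n <- 200
  x <- rbinom(n, 1, 0.5)
  # linked column: copy with a few flips -> high r2; unlinked: independent
  y_hi <- x; flip <- sample(n, 6); y_hi[flip] <- 1 - y_hi[flip]
  y_lo <- rbinom(n, 1, 0.5)
  p <- make_panel(cbind(x, y_hi, y_lo), pos = c(1000, 2000, 3000))
  r2_hi <- r_squared(p, 1, 2)
  expect_gt(r2_hi, 0.8)
  b <- build_block(p, "rs1", r2_threshold = 0.8, window = 1e6)
  expect_setequal(b$members$id, c("rs1", "rs2"))
  expect_equal(b$span$start, 1000)
  expect_equal(b$span$end, 2001)

  # strictness: a SNP at exactly the threshold is excluded
  b_eq <- build_block(p, "rs1", r2_threshold = r2_hi)
  expect_identical(b_eq$members$id, "rs1")
  b_in <- build_block(p, "rs1", r2_threshold = r2_hi - 1e-9)
  expect_true("rs2" %in% b_in$members$id)

  # lowering the threshold never removes members (monotone)
  prev <- build_block(p, "rs1", 0.95)$members$id
  for (thr in c(0.8, 0.5, 0.2, 0.0)) {
    cur <- build_block(p, "rs1", thr)$members$id
    expect_true(all(prev %in% cur))
    prev <- cur
  }

  # window restriction
  p_far <- make_panel(cbind(x, y_hi), pos = c(1000, 5e6))
  b_far <- build_block(p_far, "rs1", window = 1e6)
  expect_identical(b_far$members$id, "rs1")
  expect_equal(b_far$span$end - b_far$span$start, 1)  # 1-bp span

  expect_error(build_block(p, "rs99"), "not in panel")
})

test_that("load_index_snps reads the published risk-locus table layout", {
  f <- system.file("extdata", "rcc_index_snps_synthetic.tsv", package = "hifreg")
  idx <- load_index_snps(f)
  expect_equal(nrow(idx), 9L)
  expect_true("rs718314" %in% idx$id)
  expect_true(all(c("locus", "chrom", "pos", "id") %in% names(idx)))

  f2 <- tempfile()
  writeLines("locus\tchrom\tpos\tid", f2)
  expect_equal(nrow(load_index_snps(f2)), 0L)

  writeLines(c("locus\tchrom\tpos\tid", "l1\tchr1\tabc\trs1"), f2)
  expect_error(load_index_snps(f2), "non-numeric")

  writeLines(c("locus\tchrom\tpos\tid", "l1\tchr1\t10\trs1", "l2\tchr2\t20\trs1"), f2)
  expect_error(load_index_snps(f2), "duplicate")
})

test_that("haplotype TSV and VCF readers agree with the panel contract", {
  set.seed(9)
  p <- make_panel(matrix(rbinom(40, 1, 0.5), 10, 4), pos = c(100, 200, 300, 400))
  f <- tempfile(); fs <- tempfile()
  write_haplotypes_tsv(p, f, fs)
  q <- read_haplotypes_tsv(f, fs)
  expect_equal(unname(q$haplotypes), unname(p$haplotypes))
  expect_equal(q$snps$pos, p$snps$pos)  # 1-based round-trip

  # minimal phased VCF: 2 samples, 3 records (1 unphased record dropped)
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t101\trsA\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "chr1\t201\trsB\tC\tT\t.\tPASS\t.\tGT\t0|0\t0|1",
    "chr1\t301\trsC\tA\tT\t.\tPASS\t.\tGT\t0/1\t0|1"), vcf)
  pv <- read_haplotypes_vcf(vcf)
  expect_equal(pv$snps$id, c("rsA", "rsB"))
  expect_equal(pv$snps$pos, c(100, 200))      # converted to 0-based
  expect_equal(nrow(pv$haplotypes), 4L)       # 2 samples x 2 haplotypes
  expect_equal(sum(pv$haplotypes[, "rsA"]), 3L)
})
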
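# Independent oracles used to derive expected values, kept free of the
# package's own overlap/enrichment code paths.

# Exhaustive placement oracle: probability that a rigid SNP structure,
# anchored uniformly over all positions where it fits on one chromosome,
# lands with >= 1 SNP inside a peak. Direct enumeration of every anchor.
oracle_hit_prob <- function(offsets, genome_df, peaks_df) {
  w <- max(offsets) + 1
  hits <- 0; total <- 0
  for (ci in seq_len(nrow(genome_df))) {
    L <- genome_df$length[ci]
    if (L < w) next
    anchors <- 0:(L - w)
    total <- total + length(anchors)
    pk <- peaks_df[peaks_df$chrom == genome_df$chrom[ci], , drop = FALSE]
    if (nrow(pk) == 0) next
    for (a in anchors) {
      pos <- a + offsets
      if (any(vapply(pos, function(p) any(p >= pk$start & p < pk$end), logical(1))))
        hits <- hits + 1
    }
  }
  hits / total
}

# Poisson-binomial pmf: distribution of the number of independently placed
# structures that hit, given per-structure hit probabilities.
oracle_null_pmf <- function(ps) {
  pmf <- 1
  for (p in ps) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  pmf
}

# interval_set -> GRanges (0-based half-open -> 1-based closed)
gr_of <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1, x$end))
}

# Random interval set on a genome, for property tests.
rand_intervals <- function(n, genome_df, max_width = 50) {
  ci <- sample.int(nrow(genome_df), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  st <- vapply(seq_len(n), function(i)
    sample.int(genome_df$length[ci[i]] - w[i], 1) - 1, numeric(1))
  interval_set(genome_df$chrom[ci], st, st + w)
}

# SAM fixture with explicit per-read fields.
sam_fixture <- function(reads, chrom = "chr1", chrom_len = 1e6) {
  path <- tempfile(fileext = ".sam")
  write_sam(path, genome(chrom, chrom_len), reads)
  path
}
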
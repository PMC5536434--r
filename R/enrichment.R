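#' Extract the SNP-offset structure of a haplotype block
#'
#' The permutation null preserves the internal geometry of each GWAS
#' block: when a block is relocated, its member SNPs move as a rigid set.
#' This function reduces a block to that rigid structure - the sorted bp
#' offsets of its member SNPs relative to the first (left-most) SNP.
#'
#' @param block a [build_block()] result, or any list/data frame exposing
#'   member SNP positions via `$members$pos`, `$pos`, or a `pos` column.
#' @return A `locus_structure`: list with `id`, `offsets` (sorted, first
#'   element 0) and `width` (max offset + 1).
#' @export
locus_structure <- function(block) {
  if (inherits(block, "haplotype_block")) {
    pos <- block$members$pos
    id <- block$index$id
  } else if (is.data.frame(block)) {
    pos <- block$pos
    id <- if (!is.null(block$id)) block$id[1] else NA_character_
  } else if (is.list(block) && !is.null(block$pos)) {
    pos <- block$pos
    id <- if (!is.null(block$id)) block$id[1] else NA_character_
  } else stop("cannot extract SNP positions from block")
  if (length(pos) == 0L) stop("empty block")
  off <- sort(pos) - min(pos)
  structure(list(id = id, offsets = off, width = max(off) + 1), class = "locus_structure")
}

#' Configuration of a permutation enrichment run
#'
#' @param n_iter number of Monte-Carlo iterations (default 100,000, the
#'   scale at which empirical p-values resolve 1e-5 granularity).
#' @param seed integer RNG seed; with a fixed seed and `n_iter` the full
#'   null histogram is bit-identical across runs.
#' @param direction `"loci_shuffle"` relocates the GWAS block structures
#'   around the genome with peaks held fixed; `"peaks_shuffle"` relocates
#'   the peaks among the elements of an enhancer universe with blocks held
#'   fixed.
#' @param p_estimator `"plug_in"` (`#\{null >= obs\}/n_iter`, can return 0)
#'   or `"add_one"` (`(#\{null >= obs\}+1)/(n_iter+1)`, never 0;
#'   recommended).
#' @param overlap_rule `"snp_in_peak"` (a block overlaps a peak iff some
#'   member SNP lies within it; SNPs are 1-bp intervals) or
#'   `"span_overlap"` (the block's min..max span is intersected).
#' @param exclusion_mask optional [interval_set()]; shuffled placements
#'   with any SNP inside the mask are rejected and redrawn.
#' @return A `shuffle_config` list.
#' @export
shuffle_config <- function(n_iter = 100000L, seed = NULL,
                           direction = c("loci_shuffle", "peaks_shuffle"),
                           p_estimator = c("plug_in", "add_one"),
                           overlap_rule = c("snp_in_peak", "span_overlap"),
                           exclusion_mask = NULL) {
  n_iter <- as.integer(n_iter)
  if (is.na(n_iter) || n_iter < 1L) stop("n_iter must be >= 1")
  structure(list(
    n_iter = n_iter, seed = seed,
    direction = match.arg(direction),
    p_estimator = match.arg(p_estimator),
    overlap_rule = match.arg(overlap_rule),
    exclusion_mask = exclusion_mask
  ), class = "shuffle_config")
}

#' Null frequency distribution of an overlap statistic
#'
#' @param counts integer vector of per-iteration overlap statistics.
#' @param max_value largest attainable statistic (number of blocks or
#'   peaks); fixes the histogram support.
#' @return A `null_distribution`: list with `values` (0..max_value),
#'   `counts` (histogram, summing to `n_iter`) and `n_iter`.
#' @export
null_distribution <- function(counts, max_value = max(counts)) {
  h <- tabulate(counts + 1L, nbins = max_value + 1L)
  structure(list(values = 0:max_value, counts = h, n_iter = length(counts)),
            class = "null_distribution")
}

#' Empirical p-value from a permutation null
#'
#' Upper-tail probability of observing a statistic at least as large as
#' `observed` under the null histogram. The plug-in estimator
#' `#\{null >= observed\} / n_iter` matches the granularity of printed
#' permutation p-values at large iteration counts but can return 0; the
#' add-one estimator `(#\{null >= observed\} + 1) / (n_iter + 1)` is never
#' 0 and is a valid p-value.
#'
#' @param observed observed overlap statistic.
#' @param null a [null_distribution()].
#' @param estimator `"plug_in"` or `"add_one"`.
#' @return p-value in `[0, 1]`.
#' @export
empirical_p <- function(observed, null, estimator = c("plug_in", "add_one")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(null, "null_distribution"), null$n_iter >= 1L)
  tail <- sum(null$counts[null$values >= observed])
  switch(estimator,
         plug_in = tail / null$n_iter,
         add_one = (tail + 1) / (null$n_iter + 1))
}

# Normalize heterogeneous block inputs to list(id, chrom, pos sorted).
normalize_blocks <- function(blocks) {
  lapply(blocks, function(b) {
    if (inherits(b, "haplotype_block")) {
      list(id = b$index$id, chrom = b$index$chrom, pos = sort(b$members$pos))
    } else if (is.data.frame(b)) {
      list(id = if (!is.null(b$id)) b$id[1] else NA_character_,
           chrom = b$chrom[1], pos = sort(b$pos))
    } else if (is.list(b) && !is.null(b$pos)) {
      list(id = if (!is.null(b$id)) b$id[1] else NA_character_,
           chrom = b$chrom[1], pos = sort(b$pos))
    } else stop("blocks must be haplotype_block objects or (chrom, pos) tables")
  })
}

# Draw n anchor placements for one structure, uniform over all genome
# positions where the whole structure fits on one chromosome (chromosome
# probability proportional to its number of valid anchors). Placements with
# any SNP inside the mask are rejected and redrawn.
draw_anchors <- function(struct, genome, n, mask_lk = NULL, max_rounds = 1000L) {
  w <- struct$width
  valid <- pmax(genome$length - w + 1, 0)
  total <- sum(valid)
  if (total <= 0)
    stop("structure of width ", w, " does not fit on any chromosome")
  cum0 <- cumsum(c(0, valid[-length(valid)]))
  draw <- function(m) {
    g <- if (total <= .Machine$integer.max) sample.int(total, m, replace = TRUE) - 1
         else floor(stats::runif(m) * total)
    ci <- findInterval(g, cum0)
    list(chrom = ci, anchor = g - cum0[ci])
  }
  d <- draw(n)
  if (!is.null(mask_lk)) {
    for (round in seq_len(max_rounds)) {
      viol <- logical(n)
      for (ci in unique(d$chrom)) {
        i <- which(d$chrom == ci)
        pos <- rep(d$anchor[i], each = length(struct$offsets)) +
          rep(struct$offsets, times = length(i))
        inmask <- positions_in_lookup(mask_lk, genome$chrom[ci], pos)
        viol[i] <- colSums(matrix(inmask, nrow = length(struct$offsets))) > 0
      }
      if (!any(viol)) break
      rd <- draw(sum(viol))
      d$chrom[viol] <- rd$chrom
      d$anchor[viol] <- rd$anchor
      if (round == max_rounds)
        stop("could not place structure outside the exclusion mask")
    }
  }
  d
}

#' Shuffle locus structures around the genome (one draw)
#'
#' Places each structure independently and uniformly over every genome
#' position where it fits entirely on one chromosome, preserving internal
#' SNP offsets exactly. This is one draw of the `loci_shuffle` null.
#'
#' @param structures list of [locus_structure()]s.
#' @param genome a [genome()].
#' @param mask optional exclusion [interval_set()]; placements with any
#'   SNP inside it are rejected and redrawn.
#' @return List of placed SNP sets, each a data frame `(chrom, pos)`.
#' @export
shuffle_loci <- function(structures, genome, mask = NULL) {
  mask_lk <- if (!is.null(mask)) interval_lookup(merge_intervals(mask)) else NULL
  lapply(structures, function(s) {
    d <- draw_anchors(s, genome, 1L, mask_lk)
    data.frame(chrom = genome$chrom[d$chrom], pos = d$anchor + s$offsets,
               stringsAsFactors = FALSE)
  })
}

# One surrogate peak set: sample |peaks| universe elements without
# replacement; place each original peak width (in uniform random pairing)
# centered on the sampled element's midpoint, clipped to chromosome bounds.
draw_surrogate_peaks <- function(widths, universe, genome) {
  n <- length(widths)
  pick <- sample.int(nrow(universe), n)
  w <- widths[sample.int(n)]
  mid <- floor((universe$start[pick] + universe$end[pick]) / 2)
  st <- mid - floor(w / 2)
  en <- st + w
  L <- chrom_length(genome, universe$chrom[pick])
  st <- pmax(st, 0)
  en <- pmin(en, L)
  list(chrom = universe$chrom[pick], start = st, end = en)
}

#' Shuffle peaks among an enhancer universe (one draw)
#'
#' Samples `nrow(peaks)` universe elements uniformly without replacement
#' and places a surrogate peak of each original width (widths paired to
#' elements by a uniform random bijection) centered on the sampled
#' element's midpoint, clipped to chromosome bounds. The surrogate width
#' multiset equals the original width multiset (up to boundary clipping).
#'
#' @param peaks observed peak [interval_set()].
#' @param universe [interval_set()] of candidate elements; must have at
#'   least as many members as `peaks`.
#' @param genome a [genome()], used for boundary clipping.
#' @return A surrogate peak [interval_set()].
#' @export
shuffle_peaks <- function(peaks, universe, genome) {
  peaks <- as_interval_set(peaks); universe <- as_interval_set(universe)
  if (nrow(universe) < nrow(peaks))
    stop("universe (", nrow(universe), ") smaller than peak set (", nrow(peaks), ")")
  d <- draw_surrogate_peaks(peaks$end - peaks$start, universe, genome)
  interval_set(d$chrom, d$start, d$end)
}

# Observed statistic helpers -------------------------------------------------

# Number of blocks with >=1 member SNP inside >=1 peak (snp rule) or whose
# span intersects >=1 peak (span rule).
blocks_hit <- function(blocks, peak_lk, rule) {
  vapply(blocks, function(b) {
    if (rule == "snp_in_peak") any(positions_in_lookup(peak_lk, b$chrom, b$pos))
    else spans_in_lookup(peak_lk, b$chrom, min(b$pos), max(b$pos) + 1)
  }, logical(1))
}

# Number of peaks overlapping >=1 block, given per-chromosome sorted SNP
# positions (snp rule) or a lookup of merged block spans (span rule).
peaks_hit_count <- function(chrom, start, end, snp_pos_by_chrom = NULL, span_lk = NULL) {
  hit <- logical(length(start))
  for (cn in unique(chrom)) {
    i <- which(chrom == cn)
    if (!is.null(snp_pos_by_chrom)) {
      sp <- snp_pos_by_chrom[[cn]]
      if (is.null(sp)) next
      hit[i] <- findInterval(end[i] - 1, sp) > findInterval(start[i] - 1, sp)
    } else {
      hit[i] <- spans_in_lookup(span_lk, cn, start[i], end[i])
    }
  }
  sum(hit)
}

#' Monte-Carlo enrichment test of GWAS-block / peak overlap
#'
#' The central colocalization statistic. In the `loci_shuffle` direction
#' the observed statistic is the number of blocks with at least one member
#' SNP inside at least one peak (under the default `snp_in_peak` rule); a
#' null frequency distribution is built by relocating the rigid block
#' structures uniformly around the genome `n_iter` times with peaks held
#' fixed. In the `peaks_shuffle` direction the statistic is the number of
#' peaks overlapping at least one block, and the peaks are relocated among
#' the elements of a supplied enhancer universe. The empirical p-value is
#' the upper-tail frequency of the observed statistic under the null.
#'
#' Shuffled loci may overlap one another and real features other than the
#' exclusion mask: the null is the simplest uniform-placement model.
#'
#' @param blocks list of [build_block()] results (or `(chrom, pos)` member
#'   tables).
#' @param peaks peak [interval_set()] (e.g. consensus binding sites).
#' @param genome a [genome()].
#' @param universe enhancer universe [interval_set()]; required for
#'   `peaks_shuffle`.
#' @param config a [shuffle_config()].
#' @return An `enrichment_result`: list with `observed`, `null`
#'   (a [null_distribution()]), `p_value` and `config`.
#' @export
run_enrichment <- function(blocks, peaks, genome, universe = NULL,
                           config = shuffle_config()) {
  stopifnot(inherits(config, "shuffle_config"), inherits(genome, "genome"))
  peaks <- as_interval_set(peaks)
  validate_intervals(peaks, genome)
  bl <- normalize_blocks(blocks)
  if (length(bl) == 0L) stop("no blocks supplied")
  rule <- config$overlap_rule
  peak_lk <- interval_lookup(merge_intervals(peaks))
  if (!is.null(config$seed)) set.seed(config$seed)
  mask_lk <- if (!is.null(config$exclusion_mask))
    interval_lookup(merge_intervals(config$exclusion_mask)) else NULL

  if (config$direction == "loci_shuffle") {
    observed <- sum(blocks_hit(bl, peak_lk, rule))
    n <- config$n_iter
    counts <- integer(n)
    for (b in bl) {
      s <- locus_structure(b)
      d <- draw_anchors(s, genome, n, mask_lk)
      hit <- logical(n)
      for (ci in unique(d$chrom)) {
        i <- which(d$chrom == ci)
        cn <- genome$chrom[ci]
        if (rule == "snp_in_peak") {
          pos <- rep(d$anchor[i], each = length(s$offsets)) +
            rep(s$offsets, times = length(i))
          inpk <- positions_in_lookup(peak_lk, cn, pos)
          hit[i] <- colSums(matrix(inpk, nrow = length(s$offsets))) > 0
        } else {
          hit[i] <- spans_in_lookup(peak_lk, cn, d$anchor[i], d$anchor[i] + s$width)
        }
      }
      counts <- counts + hit
    }
    null <- null_distribution(counts, max_value = length(bl))
  } else {
    if (is.null(universe)) stop("peaks_shuffle requires an enhancer universe")
    universe <- as_interval_set(universe)
    validate_intervals(universe, genome)
    if (nrow(universe) < nrow(peaks))
      stop("universe (", nrow(universe), ") smaller than peak set (", nrow(peaks), ")")
    snp_by_chrom <- NULL; span_lk <- NULL
    if (rule == "snp_in_peak") {
      allsnps <- do.call(rbind, lapply(bl, function(b)
        data.frame(chrom = b$chrom, pos = b$pos)))
      snp_by_chrom <- lapply(split(allsnps$pos, allsnps$chrom), sort)
    } else {
      spans <- do.call(rbind, lapply(bl, function(b)
        data.frame(chrom = b$chrom, start = min(b$pos), end = max(b$pos) + 1)))
      span_lk <- interval_lookup(merge_intervals(as_interval_set(spans)))
    }
    observed <- peaks_hit_count(peaks$chrom, peaks$start, peaks$end,
                                snp_by_chrom, span_lk)
    widths <- peaks$end - peaks$start
    n <- config$n_iter
    counts <- integer(n)
    for (it in seq_len(n)) {
      d <- draw_surrogate_peaks(widths, universe, genome)
      counts[it] <- peaks_hit_count(d$chrom, d$start, d$end, snp_by_chrom, span_lk)
    }
    null <- null_distribution(counts, max_value = nrow(peaks))
  }

  structure(list(
    observed = observed,
    null = null,
    p_value = empirical_p(observed, null, config$p_estimator),
    config = config
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result (%s, %s rule)\n",
              x$config$direction, x$config$overlap_rule))
  cat(sprintf("  observed overlap: %d\n", x$observed))
  cat(sprintf("  empirical p (%s): %.3g  [%s iterations]\n",
              x$config$p_estimator, x$p_value,
              format(x$null$n_iter, big.mark = ",")))
  invisible(x)
}
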
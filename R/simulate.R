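#' Simulate a phased haplotype panel with controlled LD to an index SNP
#'
#' The index column is drawn Bernoulli(`maf_index`). Each linked SNP is a
#' two-locus haplotype-frequency construction: it copies the index allele
#' with probability `sqrt(target_r2)` and is otherwise drawn independently
#' at the same frequency, which preserves the allele frequency exactly and
#' gives expected r² equal to `target_r2` (the correlation of the two 0/1
#' columns is exactly the copy probability). The realized r² of every
#' linked SNP is recorded in the `ground_truth` attribute.
#'
#' @param n_hap number of haplotypes (>= 2).
#' @param maf_index index allele frequency, strictly in (0, 1).
#' @param target_r2 target r² per linked SNP, in `[0, 1]`; recycled to
#'   `n_snps`.
#' @param n_snps number of linked SNPs besides the index.
#' @param chrom chromosome name for all SNPs.
#' @param index_pos 0-based position of the index SNP.
#' @param spacing bp between consecutive SNP positions.
#' @param id_prefix prefix for generated SNP ids.
#' @param seed optional RNG seed (omit to use the ambient RNG stream).
#' @return A [haplotype_panel()]; attribute `"ground_truth"` holds the
#'   target and realized r² per linked SNP.
#' @export
simulate_haplotypes <- function(n_hap, maf_index, target_r2, n_snps,
                                chrom = "chr1", index_pos = 100000,
                                spacing = 500, id_prefix = "snp", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (maf_index <= 0 || maf_index >= 1)
    stop("maf_index must be strictly between 0 and 1")
  if (any(target_r2 < 0) || any(target_r2 > 1))
    stop("infeasible target_r2: attainable range is [0, 1]")
  target_r2 <- rep_len(target_r2, n_snps)
  x <- stats::rbinom(n_hap, 1, maf_index)
  # guard: LD is undefined for a monomorphic index draw
  if (sum(x) == 0) x[sample.int(n_hap, 1)] <- 1L
  if (sum(x) == n_hap) x[sample.int(n_hap, 1)] <- 0L
  cols <- matrix(0L, n_hap, n_snps + 1L)
  cols[, 1] <- x
  for (k in seq_len(n_snps)) {
    copy <- stats::rbinom(n_hap, 1, sqrt(target_r2[k])) == 1
    y <- ifelse(copy, x, stats::rbinom(n_hap, 1, maf_index))
    if (sum(y) == 0) y[sample.int(n_hap, 1)] <- 1L
    if (sum(y) == n_hap) y[sample.int(n_hap, 1)] <- 0L
    cols[, k + 1L] <- y
  }
  ids <- c(paste0(id_prefix, "_index"), paste0(id_prefix, "_", seq_len(n_snps)))
  snps <- data.frame(id = ids, chrom = chrom,
                     pos = index_pos + spacing * (0:n_snps),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  panel <- haplotype_panel(snps, cols)
  realized <- vapply(seq_len(n_snps) + 1L, function(j) r_squared(panel, 1L, j),
                     numeric(1))
  attr(panel, "ground_truth") <- data.frame(
    id = ids[-1], target_r2 = target_r2, realized_r2 = realized,
    stringsAsFactors = FALSE)
  panel
}

# Sample `n` intervals of the given widths, uniform over the genome,
# disjoint from each other and from `occupied` (list of chrom/start/end
# vectors), with at least `gap` bp separation. Simple rejection sampler.
place_disjoint <- function(genome, widths, occupied = NULL, gap = 1,
                           max_tries = 10000L) {
  oc <- if (is.null(occupied)) {
    list(chrom = character(), start = numeric(), end = numeric())
  } else occupied
  out_chrom <- character(length(widths))
  out_start <- numeric(length(widths))
  probs <- genome$length / sum(genome$length)
  for (i in seq_along(widths)) {
    w <- widths[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ci <- sample.int(nrow(genome), 1, prob = probs)
      L <- genome$length[ci]
      if (L < w) next
      st <- sample.int(L - w + 1, 1) - 1
      same <- oc$chrom == genome$chrom[ci]
      clash <- any(same & oc$start < st + w + gap & oc$end + gap > st)
      if (!clash) {
        out_chrom[i] <- genome$chrom[ci]; out_start[i] <- st
        oc$chrom <- c(oc$chrom, genome$chrom[ci])
        oc$start <- c(oc$start, st); oc$end <- c(oc$end, st + w)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place feature ", i, " disjointly; genome too crowded")
  }
  list(intervals = interval_set(out_chrom, out_start, out_start + widths),
       occupied = oc)
}

# Place one interval of width w near `center` on `chrom` (within maxdist),
# disjoint from occupied.
place_near <- function(genome, chrom, center, maxdist, w, occupied, gap = 1,
                       max_tries = 10000L) {
  L <- chrom_length(genome, chrom)
  for (try in seq_len(max_tries)) {
    st <- center + sample(c(-1, 1), 1) * sample.int(maxdist, 1)
    st <- max(0, min(st, L - w))
    same <- occupied$chrom == chrom
    clash <- any(same & occupied$start < st + w + gap & occupied$end + gap > st)
    if (!clash) {
      occupied$chrom <- c(occupied$chrom, chrom)
      occupied$start <- c(occupied$start, st)
      occupied$end <- c(occupied$end, st + w)
      return(list(start = st, occupied = occupied))
    }
  }
  stop("could not place a nearby feature disjointly")
}

#' Simulate a genome, enhancer universe, replicate peak sets and GWAS blocks
#'
#' Builds the complete region-level input of the colocalization analysis
#' with planted ground truth: a small multi-chromosome genome; a universe
#' of non-overlapping enhancers; a set of true binding sites, each placed
#' inside an enhancer and present (identically) in >= `min_support` of the
#' `n_datasets` replicate peak sets, plus per-dataset noise peaks present
#' in exactly one set; and GWAS haplotype-block SNP structures of which a
#' chosen number have at least one member SNP inside a true peak. Two
#' planted counts are dialed in: `n_overlapping` blocks hit a peak, and
#' `n_overlap_peaks` true peaks contain a block SNP (extra peak hits are
#' created by planting a second nearby peak for some overlapping blocks).
#'
#' @param n_chrom,chrom_length genome shape (default 3 x 2 Mb).
#' @param n_enhancers,enhancer_width enhancer universe (widths sampled
#'   uniformly from the given range).
#' @param n_true_peaks,peak_width true consensus binding sites.
#' @param n_datasets,min_support replicate structure of the peak sets.
#' @param n_noise_per_dataset single-dataset noise peaks.
#' @param n_blocks,n_overlapping,n_overlap_peaks planted block/peak
#'   overlap truth.
#' @param snps_per_block range of member-SNP counts per block.
#' @param block_span maximum bp span of a block's SNPs.
#' @param seed optional RNG seed.
#' @return List with `genome`, `enhancers`, `peak_sets` (list of
#'   [interval_set()]), `true_peaks`, `blocks` (list of `(id, chrom, pos)`
#'   member tables) and `ground_truth`.
#' @export
simulate_region_sets <- function(n_chrom = 3L, chrom_length = 2e6,
                                 n_enhancers = 400L, enhancer_width = c(300, 800),
                                 n_true_peaks = 30L, peak_width = c(200, 400),
                                 n_datasets = 5L, min_support = 2L,
                                 n_noise_per_dataset = 10L,
                                 n_blocks = 9L, n_overlapping = 4L,
                                 n_overlap_peaks = n_overlapping,
                                 snps_per_block = c(4L, 12L), block_span = 20000,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_overlapping <= n_blocks, n_true_peaks >= n_overlap_peaks,
            n_overlap_peaks >= n_overlapping, min_support <= n_datasets)
  g <- genome(paste0("chr", seq_len(n_chrom)), rep(chrom_length, n_chrom))

  enh_w <- sample(enhancer_width[1]:enhancer_width[2], n_enhancers, replace = TRUE)
  enh <- place_disjoint(g, enh_w, gap = 200)
  enhancers <- enh$intervals
  enhancers$name <- paste0("enh", seq_len(n_enhancers))

  # true peaks inside distinct enhancers
  pk_enh <- sample.int(n_enhancers, n_true_peaks)
  pk_w <- sample(peak_width[1]:peak_width[2], n_true_peaks, replace = TRUE)
  pk_w <- pmin(pk_w, enhancers$end[pk_enh] - enhancers$start[pk_enh])
  pk_start <- floor((enhancers$start[pk_enh] + enhancers$end[pk_enh] - pk_w) / 2)
  true_peaks <- interval_set(enhancers$chrom[pk_enh], pk_start, pk_start + pk_w,
                             name = paste0("peak", seq_len(n_true_peaks)))

  # extra peaks so that n_overlap_peaks peaks end up hit by blocks: for
  # `extra` of the overlapping blocks, plant a second peak (in its own new
  # enhancer) near the first one on the same chromosome
  occupied <- enh$occupied
  extra <- n_overlap_peaks - n_overlapping
  extra_partner <- integer(0)
  if (extra > 0) {
    for (k in seq_len(extra)) {
      anchor <- k  # partner of the k-th overlapping block's peak
      w_e <- sample(enhancer_width[1]:enhancer_width[2], 1)
      pl <- place_near(g, true_peaks$chrom[anchor],
                       true_peaks$start[anchor], maxdist = block_span %/% 2,
                       w = w_e, occupied = occupied, gap = 200)
      occupied <- pl$occupied
      enhancers <- as_interval_set(rbind(
        enhancers,
        interval_set(true_peaks$chrom[anchor], pl$start, pl$start + w_e,
                     name = paste0("enh", nrow(enhancers) + 1L))))
      w_p <- sample(peak_width[1]:peak_width[2], 1)
      w_p <- min(w_p, w_e)
      st_p <- floor(pl$start + (w_e - w_p) / 2)
      true_peaks <- as_interval_set(rbind(
        true_peaks,
        interval_set(true_peaks$chrom[anchor], st_p, st_p + w_p,
                     name = paste0("peak", nrow(true_peaks) + 1L))))
      extra_partner <- c(extra_partner, nrow(true_peaks))
    }
  }
  n_peaks_total <- nrow(true_peaks)

  # replicate peak sets: each true peak present identically in a random
  # choice of >= min_support datasets, plus per-dataset noise peaks that
  # are disjoint from everything (so consensus recovers the truth exactly)
  membership <- lapply(seq_len(n_peaks_total), function(i) {
    k <- sample(min_support:n_datasets, 1)
    sample.int(n_datasets, k)
  })
  noise <- place_disjoint(
    g, sample(peak_width[1]:peak_width[2], n_noise_per_dataset * n_datasets,
              replace = TRUE),
    occupied = occupied, gap = 200)
  occupied <- noise$occupied
  peak_sets <- lapply(seq_len(n_datasets), function(ds) {
    own <- which(vapply(membership, function(m) ds %in% m, logical(1)))
    nz <- seq_len(n_noise_per_dataset) + (ds - 1L) * n_noise_per_dataset
    as_interval_set(rbind(true_peaks[own, , drop = FALSE],
                          noise$intervals[nz, , drop = FALSE]))
  })

  # GWAS blocks: the first n_overlapping blocks get one SNP inside "their"
  # true peak (peak i for block i); blocks paired with an extra partner
  # peak get a SNP inside that partner too; all other SNPs avoid peaks
  peak_lk <- interval_lookup(merge_intervals(true_peaks))
  n_snps <- sample(snps_per_block[1]:snps_per_block[2], n_blocks, replace = TRUE)
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    if (b <= n_overlapping) {
      cn <- true_peaks$chrom[b]
      anchor <- sample(true_peaks$start[b]:(true_peaks$end[b] - 1), 1)
      pos <- anchor
      if (b <= extra) {
        j <- extra_partner[b]
        pos <- c(pos, sample(true_peaks$start[j]:(true_peaks$end[j] - 1), 1))
      }
      lo <- max(0, anchor - block_span %/% 2)
      hi <- min(chrom_length - 1, anchor + block_span %/% 2)
      while (length(pos) < n_snps[b]) {
        cand <- sample(lo:hi, 1)
        if (!positions_in_lookup(peak_lk, cn, cand) && !cand %in% pos)
          pos <- c(pos, cand)
      }
    } else {
      repeat {
        ci <- sample.int(n_chrom, 1)
        cn <- g$chrom[ci]
        anchor <- sample.int(chrom_length - block_span, 1) - 1
        cand <- sort(sample(anchor:(anchor + block_span), n_snps[b]))
        if (!any(positions_in_lookup(peak_lk, cn, cand))) { pos <- cand; break }
      }
    }
    blocks[[b]] <- data.frame(id = paste0("block", b), chrom = cn,
                              pos = sort(pos), stringsAsFactors = FALSE)
  }

  list(genome = g, enhancers = enhancers, peak_sets = peak_sets,
       true_peaks = true_peaks, blocks = blocks,
       ground_truth = list(
         n_blocks = n_blocks,
         planted_block_overlap = n_overlapping,
         planted_peak_hits = n_overlap_peaks,
         n_true_peaks = n_peaks_total,
         min_support = min_support,
         n_datasets = n_datasets))
}

#' Simulate allele-specific read counts at heterozygous sites
#'
#' For each site, assay minor-allele counts are Binomial(`depth`,
#' `rho / (1 + rho)`) where `rho` is the true calibrated B/A ratio, and
#' input-DNA counts are Binomial(`input_depth`, 1/2) (input carries the
#' two alleles 1:1). Optional homozygous control sites are emitted with
#' all reads on one allele (ground-truth ratio 0 or infinite).
#'
#' @param n_sites number of heterozygous sites.
#' @param depth assay reads per site.
#' @param true_ratio true calibrated B/A ratio `rho` (> 0).
#' @param input_depth input-DNA reads per site.
#' @param n_homozygous number of additional homozygous-B control sites.
#' @param seed optional RNG seed.
#' @return Data frame in the portable allele-count layout (`site`,
#'   `assay`, `count_a`, `count_b`, `n_other`), one `chip` and one `input`
#'   row per site; attribute `"ground_truth"` records the parameters.
#' @export
simulate_allelic_reads <- function(n_sites = 50L, depth = 1000L, true_ratio = 2.0,
                                   input_depth = 1000L, n_homozygous = 0L,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (true_ratio <= 0) stop("true_ratio must be > 0")
  if (depth < 1L) {
    out <- data.frame(site = character(), assay = character(),
                      count_a = integer(), count_b = integer(),
                      n_other = integer(), stringsAsFactors = FALSE)
    attr(out, "ground_truth") <- list(true_ratio = true_ratio, depth = depth)
    return(out)
  }
  p <- true_ratio / (1 + true_ratio)
  b <- stats::rbinom(n_sites, depth, p)
  bi <- stats::rbinom(n_sites, input_depth, 0.5)
  sites <- paste0("site", seq_len(n_sites))
  out <- rbind(
    data.frame(site = sites, assay = "chip", count_a = depth - b, count_b = b,
               n_other = 0L, stringsAsFactors = FALSE),
    data.frame(site = sites, assay = "input", count_a = input_depth - bi,
               count_b = bi, n_other = 0L, stringsAsFactors = FALSE))
  if (n_homozygous > 0L) {
    hs <- paste0("hom_site", seq_len(n_homozygous))
    out <- rbind(out,
                 data.frame(site = hs, assay = "chip", count_a = 0L,
                            count_b = depth, n_other = 0L, stringsAsFactors = FALSE),
                 data.frame(site = hs, assay = "input", count_a = 0L,
                            count_b = input_depth, n_other = 0L,
                            stringsAsFactors = FALSE))
  }
  attr(out, "ground_truth") <- list(true_ratio = true_ratio, depth = depth,
                                    input_depth = input_depth,
                                    n_sites = n_sites, n_homozygous = n_homozygous)
  out
}

#' Write a minimal SAM file
#'
#' Text-only alignment fixture writer used to exercise pileup-based allele
#' counting. Reads are written unpaired on the forward strand.
#'
#' @param path output SAM path.
#' @param genome a [genome()] (becomes the `@SQ` header).
#' @param reads data frame with columns `qname`, `chrom`, `pos1` (1-based
#'   leftmost), `mapq`, `cigar`, `seq`, `qual` (ASCII Phred+33 string of
#'   `nchar(seq)`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(path, genome, reads) {
  stopifnot(inherits(genome, "genome"),
            all(c("qname", "chrom", "pos1", "mapq", "cigar", "seq", "qual") %in% names(reads)))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", genome$chrom, as.integer(genome$length)))
  reads <- reads[order(match(reads$chrom, genome$chrom), reads$pos1), , drop = FALSE]
  body <- sprintf("%s\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$chrom, as.integer(reads$pos1),
                  as.integer(reads$mapq), reads$cigar, reads$seq, reads$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a SAM fixture with a chosen allele composition at one site
#'
#' Emits reads of length 21 centered on the site, carrying the requested
#' numbers of reference-allele, alternate-allele and third-allele bases.
#'
#' @param path output SAM path.
#' @param site list with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param chrom_len chromosome length for the header.
#' @param n_ref,n_alt,n_other read counts per base class.
#' @param mapq mapping quality for all reads.
#' @param base_qual single Phred+33 character for all bases (default `"I"`,
#'   Q40); per-read vectors are recycled.
#' @return `path`, invisibly.
#' @export
simulate_allelic_sam <- function(path, site, chrom_len = 1e6,
                                 n_ref = 10L, n_alt = 10L, n_other = 0L,
                                 mapq = 60L, base_qual = "I") {
  stopifnot(site$pos >= 10, site$pos + 10 < chrom_len)
  other_base <- setdiff(c("A", "C", "G", "T"), c(site$ref, site$alt))[1]
  bases <- c(rep(site$ref, n_ref), rep(site$alt, n_alt), rep(other_base, n_other))
  n <- length(bases)
  if (n == 0L) stop("no reads requested")
  bq <- rep_len(base_qual, n)
  flank <- "ACGTACGTAC"
  g <- genome(site$chrom, chrom_len)
  reads <- data.frame(
    qname = sprintf("r%04d", seq_len(n)),
    chrom = site$chrom,
    pos1 = site$pos + 1 - 10,      # 0-based site -> 1-based read start
    mapq = mapq,
    cigar = "21M",
    seq = paste0(flank, bases, flank),
    qual = vapply(bq, function(q) strrep(q, 21), character(1)),
    stringsAsFactors = FALSE
  )
  write_sam(path, g, reads)
}

#' Simulate an expression cohort with a pathway-conditional genotype effect
#'
#' Emulates a tumor RNA-seq cohort in which a genotype's effect on a
#' target gene exists only in samples with high latent pathway-1 activity.
#' Per sample, latent activities `a1, a2 ~ N(0, 1)` drive mean shifts of
#' the two metagene gene sets (`mean x exp(loading x a)`); genotype doses
#' follow Hardy-Weinberg at the given risk-allele frequency; the target
#' gene's mean is `baseline x exp(beta x dose)` in samples whose `a1` lies
#' in the top tertile (conditional mode) or in all samples (unconditional);
#' counts are negative binomial with the given dispersion around
#' `mean x size factor`.
#'
#' @param n_samples cohort size (default 450).
#' @param n_background non-metagene background genes.
#' @param metagene_size genes per metagene set.
#' @param dispersion NB dispersion (1/theta) shared by all genes.
#' @param beta log fold change per risk-allele dose (default `log(1.5)`).
#' @param maf risk-allele frequency (default 0.3).
#' @param activity_loading per-gene loading of latent activity on
#'   metagene-gene log-means (default 0.5, i.e. signal-to-noise about 2
#'   after averaging over the set).
#' @param conditional effect restricted to the high-`a1` tertile
#'   (default `TRUE`).
#' @param target_baseline baseline mean of the target gene.
#' @param seed optional RNG seed.
#' @return List with `counts` (genes x samples), `genotype`
#'   (`AA`/`AB`/`BB`), `metagenes` (`list(HIF1=, HIF2=)` gene ids),
#'   `target_gene`, and `truth` (latent activities, doses, conditional
#'   indicator, all parameters).
#' @export
simulate_expression <- function(n_samples = 450L, n_background = 100L,
                                metagene_size = 50L, dispersion = 0.2,
                                beta = log(1.5), maf = 0.3,
                                activity_loading = 0.5, conditional = TRUE,
                                target_baseline = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a1 <- stats::rnorm(n_samples); a2 <- stats::rnorm(n_samples)
  dose <- stats::rbinom(n_samples, 2, maf)
  sf_true <- exp(stats::rnorm(n_samples, 0, 0.2))
  top <- tertile_stratify(a1)$tertile == "high"
  ind <- if (conditional) as.numeric(top) else rep(1, n_samples)

  gene_sets <- list(
    bg = paste0("bg", seq_len(n_background)),
    hif1 = paste0("hif1_", seq_len(metagene_size)),
    hif2 = paste0("hif2_", seq_len(metagene_size))
  )
  ids <- c(gene_sets$bg, gene_sets$hif1, gene_sets$hif2, "TARGET")
  base_mu <- exp(stats::rnorm(length(ids), log(300), 0.8))
  names(base_mu) <- ids
  base_mu["TARGET"] <- target_baseline

  mu <- matrix(base_mu, nrow = length(ids), ncol = n_samples,
               dimnames = list(ids, paste0("s", seq_len(n_samples))))
  mu[gene_sets$hif1, ] <- mu[gene_sets$hif1, ] *
    matrix(exp(activity_loading * a1), metagene_size, n_samples, byrow = TRUE)
  mu[gene_sets$hif2, ] <- mu[gene_sets$hif2, ] *
    matrix(exp(activity_loading * a2), metagene_size, n_samples, byrow = TRUE)
  mu["TARGET", ] <- mu["TARGET", ] * exp(beta * dose * ind)
  mu <- sweep(mu, 2, sf_true, "*")
  theta <- if (dispersion == 0) Inf else 1 / dispersion
  counts <- matrix(stats::rnbinom(length(mu), size = theta, mu = mu),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  genotype <- c("AA", "AB", "BB")[dose + 1]
  list(counts = counts, genotype = genotype,
       metagenes = list(HIF1 = gene_sets$hif1, HIF2 = gene_sets$hif2),
       target_gene = "TARGET",
       truth = list(a1 = a1, a2 = a2, dose = dose, high_a1 = top,
                    conditional_indicator = ind, beta = beta, maf = maf,
                    dispersion = dispersion, sf_true = sf_true,
                    activity_loading = activity_loading))
}

#' Simulate a Capture-C viewpoint profile with distance decay
#'
#' Fragments tile both sides of a central viewpoint; expected counts
#' follow a power-law decay `near_count x (|d| / d_min)^-gamma` in
#' distance `d` from the viewpoint midpoint, observed counts are Poisson,
#' and listed spike fragments have their expectation multiplied by a fold
#' factor (the planted true interactions).
#'
#' @param n_fragments total fragments (split across the two sides).
#' @param fragment_width bp per fragment (default 500).
#' @param gamma decay exponent (default 1; 0 gives a flat background).
#' @param near_count expected count at the innermost fragment.
#' @param spikes data frame with columns `fragment` (index into the
#'   profile) and `fold` (> 1), or `NULL`.
#' @param chrom chromosome name.
#' @param seed optional RNG seed.
#' @return A [viewpoint_profile()]; attribute `"ground_truth"` carries the
#'   spiked fragment indices and the decay parameters.
#' @export
simulate_viewpoint <- function(n_fragments = 1000L, fragment_width = 500,
                               gamma = 1, near_count = 100, spikes = NULL,
                               chrom = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  half <- n_fragments %/% 2L
  # fragments tile [0, n*w); the viewpoint midpoint sits at the boundary
  # after fragment `half`, so distances are signed and never zero
  start <- (seq_len(n_fragments) - 1) * fragment_width
  dist <- (seq_len(n_fragments) - half - 0.5) * fragment_width
  expected <- near_count * (abs(dist) / (0.5 * fragment_width))^(-gamma)
  if (!is.null(spikes)) {
    stopifnot(all(c("fragment", "fold") %in% names(spikes)))
    expected[spikes$fragment] <- expected[spikes$fragment] * spikes$fold
  }
  counts <- stats::rpois(n_fragments, expected)
  prof <- viewpoint_profile(data.frame(
    chrom = chrom, start = start, end = start + fragment_width,
    distance = dist, count = counts, stringsAsFactors = FALSE))
  attr(prof, "ground_truth") <- list(
    spiked = if (is.null(spikes)) integer(0) else spikes$fragment,
    gamma = gamma, near_count = near_count, expected = expected)
  prof
}
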
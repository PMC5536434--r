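#' Per-site allele counts from an assay
#'
#' Container for the two allele read counts at one heterozygous site in
#' one assay. `count_a` is the major/reference allele, `count_b` the
#' minor/alternate allele (the fixed B/A orientation used throughout the
#' package, matching the minor/major reporter-dye convention of allele
#' discrimination assays). Reads covering the site with any other base are
#' tracked in `n_other`, never silently merged.
#'
#' @param site list or one-row data frame with `id`, `chrom`, `pos`
#'   (0-based), `ref`, `alt`.
#' @param assay one of `"chip"`, `"faire"`, `"input"`, `"cdna"`, `"gdna"`.
#' @param count_a,count_b,n_other non-negative read counts.
#' @return A `site_allele_count` object.
#' @export
site_allele_count <- function(site, assay = c("chip", "faire", "input", "cdna", "gdna"),
                              count_a, count_b, n_other = 0L) {
  assay <- match.arg(assay)
  if (any(c(count_a, count_b, n_other) < 0)) stop("counts must be >= 0")
  structure(list(site = site, assay = assay,
                 count_a = as.integer(count_a), count_b = as.integer(count_b),
                 n_other = as.integer(n_other)),
            class = "site_allele_count")
}

#' Count alleles at a SNP in aligned reads
#'
#' Pileup-based allele quantification: among reads covering the site that
#' pass the mapping- and base-quality filters, counts bases matching the
#' reference allele (`count_a`), the alternate allele (`count_b`), and any
#' other base (`n_other`). Reads with a deletion or reference skip at the
#' site contribute to none of the three. Counts are conserved:
#' `count_a + count_b + n_other` equals the number of quality-passing
#' covering reads with a base call at the site.
#'
#' @param alignments path to a BAM or SAM file (SAM is converted and
#'   indexed in a temporary directory).
#' @param site list with `id`, `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param min_base_q minimum base quality (Phred; default 20).
#' @param min_map_q minimum mapping quality (default 10).
#' @param assay assay label recorded in the result.
#' @return A [site_allele_count()].
#' @export
count_alleles <- function(alignments, site, min_base_q = 20L, min_map_q = 10L,
                          assay = "chip") {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(site)))
  bam <- alignments
  if (grepl("\\.sam$", alignments, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(alignments,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = TRUE)
  } else if (!file.exists(paste0(bam, ".bai"))) {
    Rsamtools::indexBam(bam)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!(site$chrom %in% names(hdr)))
    stop("site chromosome ", site$chrom, " absent from alignment header")
  pos1 <- site$pos + 1  # 0-based site -> 1-based pileup coordinates
  if (pos1 > hdr[[site$chrom]])
    stop("site position beyond end of ", site$chrom, " in alignment header")
  which <- GenomicRanges::GRanges(site$chrom, IRanges::IRanges(pos1, pos1))
  p <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(which = which, mapqFilter = min_map_q),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 1e6L, min_base_quality = as.integer(min_base_q),
      min_mapq = as.integer(min_map_q), min_nucleotide_depth = 0L,
      distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
      include_deletions = FALSE, include_insertions = FALSE
    )
  )
  p <- p[p$pos == pos1, , drop = FALSE]
  n_of <- function(base) sum(p$count[p$nucleotide == base])
  count_a <- n_of(site$ref)
  count_b <- n_of(site$alt)
  site_allele_count(site, assay,
                    count_a = count_a, count_b = count_b,
                    n_other = sum(p$count) - count_a - count_b)
}

#' Read a portable allele-count table
#'
#' Tab-delimited alternative to alignment input, with header columns
#' `site`, `assay`, `count_a`, `count_b`, `n_other`.
#'
#' @param path TSV path.
#' @return Data frame of per-site, per-assay allele counts.
#' @export
read_allele_counts <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("site", "assay", "count_a", "count_b", "n_other")
  if (!all(need %in% names(x)))
    stop("allele-count table must have columns: ", paste(need, collapse = ", "))
  x
}

#' Input-dilution ratio calibration
#'
#' Heterozygous input DNA carries both alleles 1:1, so its measured B/A
#' ratios (over serial dilutions) estimate the assay's allelic measurement
#' bias. The mean input ratio is arbitrarily set to 1 and assay ratios are
#' divided by it. The arithmetic mean of the dilution ratios is the
#' default; a geometric-mean option is provided since ratios are
#' multiplicative.
#'
#' @param input_ratios positive B/A ratios from input-DNA serial dilutions.
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @return A `ratio_calibration`: list with `input_ratios` and
#'   `mean_input_ratio`.
#' @export
ratio_calibration <- function(input_ratios, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  input_ratios <- as.numeric(input_ratios)
  if (length(input_ratios) < 1L || any(!is.finite(input_ratios)) || any(input_ratios <= 0))
    stop("input ratios must be positive and non-empty")
  m <- switch(method,
              arithmetic = mean(input_ratios),
              geometric = exp(mean(log(input_ratios))))
  structure(list(input_ratios = input_ratios, mean_input_ratio = m, method = method),
            class = "ratio_calibration")
}

#' Calibrated allelic ratio of an assay
#'
#' Divides the assay's B/A ratio by the mean input-DNA B/A ratio, so that
#' a perfectly balanced assay reads 1 regardless of platform bias.
#'
#' @param assay a [site_allele_count()] or a single positive B/A ratio.
#' @param calib a [ratio_calibration()].
#' @return Calibrated B/A ratio (> 0).
#' @export
calibrated_ratio <- function(assay, calib) {
  stopifnot(inherits(calib, "ratio_calibration"))
  if (inherits(assay, "site_allele_count")) {
    if (assay$count_a == 0)
      stop("undefined ratio: count_a is 0 (report one-sided enrichment instead)")
    ratio <- assay$count_b / assay$count_a
  } else {
    ratio <- as.numeric(assay)
    if (!is.finite(ratio) || ratio <= 0) stop("assay ratio must be positive")
  }
  ratio / calib$mean_input_ratio
}

#' Exact binomial test of allelic imbalance in read counts
#'
#' Two-sided exact binomial test of `count_b` out of `count_a + count_b`
#' against success probability `null_ratio / (1 + null_ratio)`.
#'
#' @param x a [site_allele_count()] (or list with `count_a`, `count_b`).
#' @param null_ratio B/A ratio under the null (default 1, i.e. balance).
#' @return An `imbalance_result`: list with `ratio` (raw B/A, `Inf` when
#'   `count_a` is 0), `test_name` and `p_value`.
#' @export
test_imbalance_counts <- function(x, null_ratio = 1.0) {
  n <- x$count_a + x$count_b
  if (n < 1L) stop("need at least one allele-informative read")
  p0 <- null_ratio / (1 + null_ratio)
  p <- stats::binom.test(x$count_b, n, p = p0, alternative = "two.sided")$p.value
  structure(list(ratio = if (x$count_a > 0) x$count_b / x$count_a else Inf,
                 test_name = "exact_binomial", p_value = p),
            class = "imbalance_result")
}

#' Rank-sum test of a shift in calibrated allelic ratios
#'
#' Two-sided Mann-Whitney-Wilcoxon test comparing calibrated ratios from a
#' treated condition (e.g. HIF-stabilized) against an untreated control.
#'
#' @param treated,control numeric vectors of calibrated ratios (>= 3 each).
#' @return An `imbalance_result` with the median ratio shift
#'   (`median(treated) - median(control)`) and the rank-sum p-value.
#' @export
test_imbalance_ratios <- function(treated, control) {
  if (length(treated) < 3L || length(control) < 3L)
    stop("need at least 3 ratios per group")
  if (length(unique(c(treated, control))) == 1L)
    stop("degenerate test: all ratios identical across both groups")
  w <- suppressWarnings(stats::wilcox.test(treated, control, alternative = "two.sided"))
  structure(list(ratio = stats::median(treated) - stats::median(control),
                 test_name = "mann_whitney", p_value = w$p.value),
            class = "imbalance_result")
}

#' @export
print.imbalance_result <- function(x, ...) {
  cat(sprintf("imbalance_result: %s, p = %.4g (ratio/shift %.4g)\n",
              x$test_name, x$p_value, x$ratio))
  invisible(x)
}

#' Input-normalized site enrichment against a control region
#'
#' Chromatin-accessibility style normalization: the site signal is first
#' normalized to its input DNA, then compared to the same quantity at a
#' non-enhancer control region. Invariant to rescaling all four inputs.
#'
#' @param faire_site,input_site signal and input quantities at the site.
#' @param faire_ctrl,input_ctrl signal and input at the control region.
#' @return `(faire_site/input_site) / (faire_ctrl/input_ctrl)`.
#' @export
normalized_site_enrichment <- function(faire_site, input_site, faire_ctrl, input_ctrl) {
  q <- c(faire_site, input_site, faire_ctrl, input_ctrl)
  if (any(!is.finite(q)) || any(q <= 0)) stop("all quantities must be positive")
  (faire_site / input_site) / (faire_ctrl / input_ctrl)
}

#' A qPCR measurement
#'
#' @param ct_target,ct_housekeeping finite positive cycle-threshold values.
#' @param condition `"untreated"` or `"dmog"`.
#' @return A `qpcr_measurement` list.
#' @export
qpcr_measurement <- function(ct_target, ct_housekeeping,
                             condition = c("untreated", "dmog")) {
  condition <- match.arg(condition)
  if (!is.finite(ct_target) || !is.finite(ct_housekeeping) ||
      ct_target <= 0 || ct_housekeeping <= 0)
    stop("cycle values must be finite and > 0")
  structure(list(ct_target = ct_target, ct_housekeeping = ct_housekeeping,
                 condition = condition), class = "qpcr_measurement")
}

#' Delta-delta-Ct relative fold change
#'
#' Computes `2^-ddCt` with `dCt = ct_target - ct_housekeeping` per
#' measurement and `ddCt = dCt_sample - dCt_reference`. Expression is thus
#' normalized to the housekeeping gene and to the reference (untreated)
#' condition. Amplification efficiency is assumed to be 2 per cycle.
#'
#' @param sample,reference [qpcr_measurement()]s (or lists with
#'   `ct_target`, `ct_housekeeping`).
#' @return Fold change (> 0).
#' @export
ddct_fold_change <- function(sample, reference) {
  dct_s <- sample$ct_target - sample$ct_housekeeping
  dct_r <- reference$ct_target - reference$ct_housekeeping
  2^-(dct_s - dct_r)
}
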
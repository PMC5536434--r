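#' Construct a phased haplotype panel
#'
#' A panel couples SNP metadata with a phased 0/1 haplotype matrix (one row
#' per haplotype, one column per SNP). Positions are stored 0-based; input
#' readers convert from the 1-based conventions of VCF and SNP tables.
#' Missingness is handled at load time by exclusion, so a constructed panel
#' has no missing entries.
#'
#' @param snps data frame with columns `id`, `chrom`, `pos` (0-based bp),
#'   `ref`, `alt`. `chrom`/`pos` may be `NA` when only LD (not block
#'   geometry) is needed.
#' @param haplotypes numeric/integer matrix of 0/1 with `ncol == nrow(snps)`;
#'   at least 2 rows.
#' @return A `haplotype_panel` object.
#' @export
haplotype_panel <- function(snps, haplotypes) {
  stopifnot(is.data.frame(snps), all(c("id", "chrom", "pos", "ref", "alt") %in% names(snps)))
  haplotypes <- as.matrix(haplotypes)
  if (nrow(haplotypes) < 2L) stop("a panel needs at least 2 haplotypes")
  if (ncol(haplotypes) != nrow(snps))
    stop("haplotype matrix has ", ncol(haplotypes), " columns but ", nrow(snps), " SNPs")
  if (anyNA(haplotypes) || !all(haplotypes %in% c(0, 1)))
    stop("haplotypes must be complete 0/1; exclude missing data at load time")
  if (anyDuplicated(snps$id)) stop("duplicate SNP id in panel")
  ok_allele <- function(a) is.na(a) | a %in% c("A", "C", "G", "T")
  if (!all(ok_allele(snps$ref)) || !all(ok_allele(snps$alt)))
    stop("alleles must be single nucleotides")
  same <- !is.na(snps$ref) & !is.na(snps$alt) & snps$ref == snps$alt
  if (any(same)) stop("ref and alt alleles must differ (SNP ", snps$id[which(same)[1]], ")")
  colnames(haplotypes) <- snps$id
  structure(list(snps = snps, haplotypes = haplotypes), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d SNPs\n",
              nrow(x$haplotypes), ncol(x$haplotypes)))
  invisible(x)
}

snp_index <- function(panel, id) {
  i <- match(id, panel$snps$id)
  if (is.na(i)) stop("SNP not in panel: ", id)
  i
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Computes r² between two biallelic SNPs by direct haplotype counting:
#' `D = p_AB - p_A p_B` and `r² = D² / (p_A (1-p_A) p_B (1-p_B))`.
#' This equals the squared Pearson correlation of the two 0/1 haplotype
#' columns. Both SNPs must be polymorphic in the panel; LD with a
#' monomorphic SNP is undefined (an error, not 0).
#'
#' @param panel a [haplotype_panel()].
#' @param i,j SNP ids (or column indices).
#' @return r² in `[0, 1]`.
#' @export
r_squared <- function(panel, i, j) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (is.character(i)) i <- snp_index(panel, i)
  if (is.character(j)) j <- snp_index(panel, j)
  x <- panel$haplotypes[, i]
  y <- panel$haplotypes[, j]
  pA <- mean(x); pB <- mean(y)
  if (pA <= 0 || pA >= 1)
    stop("LD undefined: SNP ", panel$snps$id[i], " is monomorphic in the panel")
  if (pB <= 0 || pB >= 1)
    stop("LD undefined: SNP ", panel$snps$id[j], " is monomorphic in the panel")
  D <- mean(x * y) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Expand an index SNP into its haplotype block
#'
#' A haplotype block is the index SNP plus every panel SNP on the same
#' chromosome, within `window` bp of it, whose LD with the index exceeds
#' `r2_threshold`. The threshold is strict (`r² > threshold`; a SNP at
#' exactly the threshold is excluded). Monomorphic panel SNPs cannot carry
#' LD information and are skipped.
#'
#' @param panel a [haplotype_panel()] with positions.
#' @param index id of the index SNP (must be present in the panel).
#' @param r2_threshold strict lower bound on r² (default 0.8).
#' @param window search window in bp either side of the index (default 1 Mb).
#' @return A `haplotype_block`: list with `index` (SNP row), `members`
#'   (data frame of member SNPs with an `r2` column; includes the index),
#'   and `span` (an [interval_set()] covering min..max member positions).
#' @export
build_block <- function(panel, index, r2_threshold = 0.8, window = 1e6) {
  stopifnot(inherits(panel, "haplotype_panel"))
  ii <- snp_index(panel, index)
  idx_snp <- panel$snps[ii, , drop = FALSE]
  if (is.na(idx_snp$chrom) || is.na(idx_snp$pos))
    stop("index SNP has no genomic position; block construction needs positions")
  cand <- which(panel$snps$chrom == idx_snp$chrom &
                  abs(panel$snps$pos - idx_snp$pos) <= window &
                  seq_len(nrow(panel$snps)) != ii)
  r2 <- rep(NA_real_, length(cand))
  for (k in seq_along(cand)) {
    p <- mean(panel$haplotypes[, cand[k]])
    if (p > 0 && p < 1) r2[k] <- r_squared(panel, ii, cand[k])
  }
  keep <- cand[!is.na(r2) & r2 > r2_threshold]
  members <- panel$snps[c(ii, keep), , drop = FALSE]
  members$r2 <- c(1, r2[!is.na(r2) & r2 > r2_threshold])
  members <- members[order(members$pos), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(
    index = idx_snp,
    members = members,
    span = interval_set(idx_snp$chrom, min(members$pos), max(members$pos) + 1,
                        name = idx_snp$id)
  ), class = "haplotype_block")
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat(sprintf("haplotype_block: index %s (%s:%d), %d member SNP(s), span %d bp\n",
              x$index$id, x$index$chrom, as.integer(x$index$pos),
              nrow(x$members), as.integer(x$span$end - x$span$start)))
  invisible(x)
}

#' Load a table of GWAS index SNPs
#'
#' Reads a tab-delimited table with header columns `locus`, `chrom`, `pos`
#' (1-based, converted to the package's 0-based convention) and `id`.
#'
#' @param path TSV path.
#' @return Data frame with columns `locus`, `chrom`, `pos` (0-based), `id`.
#' @export
load_index_snps <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("locus", "chrom", "pos", "id")
  if (!all(need %in% names(x)))
    stop("index-SNP table must have columns: ", paste(need, collapse = ", "))
  if (nrow(x) == 0L)
    return(data.frame(locus = character(), chrom = character(),
                      pos = numeric(), id = character(), stringsAsFactors = FALSE))
  pos <- suppressWarnings(as.numeric(x$pos))
  if (anyNA(pos))
    stop("non-numeric pos in index-SNP table at row ", which(is.na(pos))[1])
  if (anyDuplicated(x$id))
    stop("duplicate index SNP id: ", x$id[duplicated(x$id)][1])
  data.frame(locus = x$locus, chrom = x$chrom, pos = pos - 1, id = x$id,
             stringsAsFactors = FALSE)
}

#' Read a haplotype matrix TSV
#'
#' Rows are phased haplotypes, the header carries SNP ids, entries are 0/1.
#' SNP coordinates, when needed for block geometry, come from a separate
#' sites table (`id`, `chrom`, `pos` 1-based, `ref`, `alt`).
#'
#' @param path haplotype matrix TSV.
#' @param sites optional path to (or data frame of) the sites table.
#' @return A [haplotype_panel()].
#' @export
read_haplotypes_tsv <- function(path, sites = NULL) {
  m <- as.matrix(utils::read.delim(path, header = TRUE, check.names = FALSE))
  ids <- colnames(m)
  if (is.null(sites)) {
    snps <- data.frame(id = ids, chrom = NA_character_, pos = NA_real_,
                       ref = NA_character_, alt = NA_character_,
                       stringsAsFactors = FALSE)
  } else {
    if (is.character(sites)) {
      sites <- utils::read.delim(sites, header = TRUE, stringsAsFactors = FALSE)
    }
    need <- c("id", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(sites)))
      stop("sites table must have columns: ", paste(need, collapse = ", "))
    i <- match(ids, sites$id)
    if (anyNA(i)) stop("sites table missing SNP: ", ids[which(is.na(i))[1]])
    snps <- sites[i, need]
    snps$pos <- snps$pos - 1  # 1-based input -> 0-based internal
    rownames(snps) <- NULL
  }
  haplotype_panel(snps, m)
}

#' Write a haplotype panel as matrix + sites TSVs
#'
#' @param panel a [haplotype_panel()].
#' @param path haplotype matrix output path.
#' @param sites_path optional sites-table output path (1-based positions).
#' @return `path`, invisibly.
#' @export
write_haplotypes_tsv <- function(panel, path, sites_path = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  utils::write.table(panel$haplotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (!is.null(sites_path)) {
    s <- panel$snps
    s$pos <- s$pos + 1
    utils::write.table(s, sites_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read phased haplotypes from a VCF
#'
#' Restricted to biallelic SNVs with fully phased (`|`-separated) GT
#' fields. Sites with any missing or unphased genotype are dropped, as are
#' indels and multi-allelic records. Each sample contributes two haplotype
#' rows.
#'
#' @param path VCF path (v4.x, plain text or bgzipped).
#' @return A [haplotype_panel()].
#' @export
read_haplotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  snv <- fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  phased <- apply(gt, 1, function(g) all(!is.na(g)) && all(grepl("^[01]\\|[01]$", g)))
  keep <- which(snv & phased)
  if (length(keep) == 0L) stop("no phased biallelic SNVs in ", path)
  a1 <- apply(gt[keep, , drop = FALSE], c(1, 2), function(g) as.integer(substr(g, 1, 1)))
  a2 <- apply(gt[keep, , drop = FALSE], c(1, 2), function(g) as.integer(substr(g, 3, 3)))
  hap <- rbind(t(a1), t(a2))
  ids <- fix$ID[keep]
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM[keep], ":", fix$POS[keep])[is.na(ids) | ids == "."]
  snps <- data.frame(id = ids, chrom = fix$CHROM[keep],
                     pos = as.numeric(fix$POS[keep]) - 1,
                     ref = fix$REF[keep], alt = fix$ALT[keep],
                     stringsAsFactors = FALSE)
  haplotype_panel(snps, hap)
}
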
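#' Reverse complement of a DNA string
#'
#' @param x character DNA string over `A C G T N`.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# The HRE core is the exact 5-mer consensus RCGTG (R = A/G); no PWM.
HRE_PLUS <- c("ACGTG", "GCGTG")
HRE_MINUS <- c("CACGT", "CACGC")  # windows whose reverse complement is RCGTG

check_dna <- function(sequence) {
  s <- toupper(sequence)
  bad <- regmatches(s, regexpr("[^ACGTN]", s))
  if (length(bad) && nzchar(bad))
    stop("invalid character in DNA sequence: '", bad, "'")
  s
}

#' Scan a sequence for hypoxia response element (HRE) core motifs
#'
#' Finds every occurrence of the HRE consensus `RCGTG` (R = A or G) on the
#' plus strand and, by default, every position whose reverse complement
#' matches (reported on the minus strand). `N` never matches. The match
#' model is the exact 5-mer consensus; no position-weight scoring.
#'
#' @param sequence DNA string over `A C G T N`, length >= 5.
#' @param both_strands scan the minus strand too (default `TRUE`).
#' @return Data frame of motif hits with columns `offset` (0-based bp into
#'   the query), `strand` and `matched` (the RCGTG 5-mer as read on the
#'   reported strand). Zero rows when nothing matches.
#' @export
scan_hre <- function(sequence, both_strands = TRUE) {
  s <- check_dna(sequence)
  n <- nchar(s)
  if (n < 5L) stop("sequence must be at least 5 bp")
  starts <- seq_len(n - 4L)
  kmers <- substring(s, starts, starts + 4L)
  hits <- data.frame(offset = integer(), strand = character(),
                     matched = character(), stringsAsFactors = FALSE)
  plus <- which(kmers %in% HRE_PLUS)
  if (length(plus))
    hits <- rbind(hits, data.frame(offset = plus - 1L, strand = "+",
                                   matched = kmers[plus], stringsAsFactors = FALSE))
  if (both_strands) {
    minus <- which(kmers %in% HRE_MINUS)
    if (length(minus))
      hits <- rbind(hits, data.frame(offset = minus - 1L, strand = "-",
                                     matched = revcomp(kmers[minus]),
                                     stringsAsFactors = FALSE))
  }
  hits[order(hits$offset, hits$strand), , drop = FALSE]
}

#' Classify a SNP as HRE-creating, HRE-disrupting, or neutral
#'
#' Scans the window of all 5-mers containing the SNP position (up to 4 bp
#' each side) for both alleles and compares the hit sets. A hit present
#' only with the alternate allele means the variant creates an HRE
#' (`"gained"`); present only with the reference allele, it destroys one
#' (`"lost"`); `"both"` when each allele has a hit the other lacks;
#' `"none"` otherwise. Swapping ref and alt swaps gained and lost.
#'
#' @param context DNA string containing the SNP; should extend >= 4 bp
#'   each side of the SNP (shorter contexts are scanned as-is).
#' @param snp_offset 0-based offset of the SNP within `context`.
#' @param ref,alt the two alleles; `context` must carry `ref` at
#'   `snp_offset`.
#' @param both_strands scan both strands (default `TRUE`).
#' @return A `snp_motif_effect`: list with `effect` (one of `gained`,
#'   `lost`, `none`, `both`), `hits_ref` and `hits_alt` (hit tables in
#'   `context` coordinates).
#' @export
snp_motif_effect <- function(context, snp_offset, ref, alt, both_strands = TRUE) {
  s <- check_dna(context)
  ref <- toupper(ref); alt <- toupper(alt)
  if (snp_offset < 0 || snp_offset >= nchar(s)) stop("snp_offset outside context")
  if (substring(s, snp_offset + 1, snp_offset + 1) != ref)
    stop("context has '", substring(s, snp_offset + 1, snp_offset + 1),
         "' at snp_offset, not ref allele '", ref, "'")
  if (!alt %in% c("A", "C", "G", "T") || alt == ref)
    stop("alt must be a single nucleotide distinct from ref")
  w0 <- max(0L, snp_offset - 4L)
  w1 <- min(nchar(s), snp_offset + 5L)
  win_ref <- substring(s, w0 + 1, w1)
  win_alt <- win_ref
  substring(win_alt, snp_offset - w0 + 1, snp_offset - w0 + 1) <- alt
  shift_hits <- function(h) { if (nrow(h)) h$offset <- h$offset + w0; h }
  scan_win <- function(w) {
    if (nchar(w) < 5L)
      return(data.frame(offset = integer(), strand = character(),
                        matched = character(), stringsAsFactors = FALSE))
    scan_hre(w, both_strands = both_strands)
  }
  hits_ref <- shift_hits(scan_win(win_ref))
  hits_alt <- shift_hits(scan_win(win_alt))
  key <- function(h) paste(h$offset, h$strand)
  ref_only <- nrow(hits_ref) > 0 && any(!key(hits_ref) %in% key(hits_alt))
  alt_only <- nrow(hits_alt) > 0 && any(!key(hits_alt) %in% key(hits_ref))
  effect <- if (ref_only && alt_only) "both"
            else if (alt_only) "gained"
            else if (ref_only) "lost"
            else "none"
  structure(list(effect = effect, hits_ref = hits_ref, hits_alt = hits_alt,
                 snp_offset = snp_offset, ref = ref, alt = alt),
            class = "snp_motif_effect")
}

#' @export
print.snp_motif_effect <- function(x, ...) {
  cat(sprintf("snp_motif_effect: %s>%s at offset %d -> %s (%d ref hit(s), %d alt hit(s))\n",
              x$ref, x$alt, x$snp_offset, x$effect, nrow(x$hits_ref), nrow(x$hits_alt)))
  invisible(x)
}

#' Annotate SNP motif effects from FASTA context sequences
#'
#' Convenience wrapper: reads context sequences from a FASTA file (one
#' record per SNP) and classifies each SNP's effect on HRE motifs.
#'
#' @param fasta path to a FASTA of context sequences; record names must
#'   match `snps$id`.
#' @param snps data frame with columns `id`, `offset` (0-based SNP offset
#'   within its context), `ref`, `alt`.
#' @param both_strands scan both strands (default `TRUE`).
#' @return Data frame with one row per SNP: `id`, `effect`, and counts of
#'   ref/alt hits.
#' @export
annotate_snp_effects <- function(fasta, snps, both_strands = TRUE) {
  seqs <- read_fasta(fasta)
  stopifnot(all(c("id", "offset", "ref", "alt") %in% names(snps)))
  i <- match(snps$id, names(seqs))
  if (anyNA(i)) stop("FASTA missing context for SNP ", snps$id[which(is.na(i))[1]])
  out <- lapply(seq_len(nrow(snps)), function(k) {
    e <- snp_motif_effect(seqs[i[k]], snps$offset[k], snps$ref[k], snps$alt[k],
                          both_strands = both_strands)
    data.frame(id = snps$id[k], effect = e$effect,
               n_hits_ref = nrow(e$hits_ref), n_hits_alt = nrow(e$hits_alt),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Minimal FASTA reader for short context sequences.
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  idx <- cumsum(hdr)
  names_ <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  stats::setNames(seqs, names_)
}
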
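#' Construct an interval set
#'
#' The package's interval container: a data frame of 0-based half-open
#' regions `[start, end)` on named chromosomes, the BED convention. All
#' overlap logic in the package (peak consensus, block/peak colocalization,
#' the permutation null) runs on this representation; 1-based inputs (VCF
#' positions, SNP tables) are converted at I/O boundaries.
#'
#' @param chrom chromosome names.
#' @param start 0-based inclusive starts (bp).
#' @param end exclusive ends (bp); must satisfy `start < end`.
#' @param name optional feature names.
#' @param score optional numeric scores.
#' @param strand optional strand, `"+"`, `"-"` or `NA`.
#' @param genome optional [genome()]; if supplied, intervals are validated
#'   against chromosome names and lengths.
#' @return An `interval_set` data frame with columns
#'   `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @examples
#' interval_set("chr1", 0, 10)
#' @export
interval_set <- function(chrom = character(), start = numeric(), end = numeric(),
                         name = NA_character_, score = NA_real_, strand = NA_character_,
                         genome = NULL) {
  n <- length(chrom)
  x <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  class(x) <- c("interval_set", "data.frame")
  validate_intervals(x, genome)
  x
}

#' Validate an interval set, optionally against a genome
#'
#' Checks `0 <= start < end` and, when a genome is bound, that every
#' chromosome exists and no interval exceeds its length.
#'
#' @param x an `interval_set`.
#' @param genome optional [genome()].
#' @return `x`, invisibly; errors on violation.
#' @export
validate_intervals <- function(x, genome = NULL) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x)) {
    bad <- which(!is.finite(x$start) | !is.finite(x$end) |
                   x$start < 0 | x$start >= x$end)
    if (length(bad))
      stop(sprintf("invalid interval at row %d: need 0 <= start < end", bad[1]))
    if (!is.null(genome)) {
      i <- match(x$chrom, genome$chrom)
      if (anyNA(i))
        stop("interval on unknown chromosome: ", x$chrom[which(is.na(i))[1]])
      over <- which(x$end > genome$length[i])
      if (length(over))
        stop(sprintf("interval at row %d exceeds length of %s",
                     over[1], x$chrom[over[1]]))
    }
  }
  invisible(x)
}

as_interval_set <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  for (col in c("name", "strand"))
    if (is.null(x[[col]])) x[[col]] <- rep(NA_character_, nrow(x))
  if (is.null(x$score)) x$score <- rep(NA_real_, nrow(x))
  x <- x[, c("chrom", "start", "end", "name", "score", "strand")]
  class(x) <- c("interval_set", "data.frame")
  x
}

#' Read a BED3+ file
#'
#' Reads headerless tab-delimited BED text. The first three columns are
#' required; columns 4-6 are kept as name/score/strand when present.
#' Malformed lines are reported with their line number.
#'
#' @param path BED file path.
#' @param genome optional [genome()]; coordinates are validated against it.
#' @return An [interval_set()] in input order.
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")
  idx <- which(keep)
  if (length(idx) == 0L) return(interval_set())
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- vapply(parts, length, 0L)
  if (any(nf < 3L))
    stop(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                 idx[which(nf < 3L)[1]], path))
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("malformed BED line %d in %s: non-numeric coordinate",
                 idx[which(is.na(start) | is.na(end))[1]], path))
  getcol <- function(k, default) {
    out <- rep(default, length(parts))
    has <- nf >= k
    out[has] <- vapply(parts[has], `[[`, "", k)
    out
  }
  x <- interval_set(
    chrom = vapply(parts, `[[`, "", 1L),
    start = start, end = end,
    name = getcol(4L, NA_character_),
    score = suppressWarnings(as.numeric(getcol(5L, NA_character_))),
    strand = ifelse(getcol(6L, NA_character_) %in% c("+", "-"),
                    getcol(6L, NA_character_), NA_character_)
  )
  validate_intervals(x, genome)
  x
}

#' Write an interval set as BED
#'
#' Emits BED3 when no name is present, otherwise BED6 with `.`/`0`
#' placeholders, so that `read_bed(write_bed(x))` round-trips
#' `(chrom, start, end)` exactly.
#'
#' @param x an [interval_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as_interval_set(x)
  if (nrow(x) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (all(is.na(x$name)) && all(is.na(x$score)) && all(is.na(x$strand))) {
    out <- sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start), as.integer(x$end))
  } else {
    out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   x$chrom, as.integer(x$start), as.integer(x$end),
                   ifelse(is.na(x$name), ".", x$name),
                   ifelse(is.na(x$score), "0", format(x$score, trim = TRUE)),
                   ifelse(is.na(x$strand), ".", x$strand))
  }
  writeLines(out, path)
  invisible(path)
}

#' Do two intervals overlap?
#'
#' Half-open semantics: intervals overlap iff they are on the same
#' chromosome and `a$start < b$end && b$start < a$end`. Abutting intervals
#' (`a$end == b$start`) do not overlap.
#'
#' @param a,b `interval_set` rows (recycled to a common length).
#' @return Logical vector.
#' @export
intervals_overlap <- function(a, b) {
  a <- as_interval_set(a); b <- as_interval_set(b)
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ia] == b$chrom[ib] & a$start[ia] < b$end[ib] & b$start[ib] < a$end[ia]
}

#' Sort an interval set by (chrom, start, end)
#'
#' @param x an `interval_set`.
#' @return The sorted set.
#' @export
sort_intervals <- function(x) {
  x <- as_interval_set(x)
  x[order(x$chrom, x$start, x$end, method = "radix"), , drop = FALSE]
}

#' Merge overlapping intervals
#'
#' Produces the sorted, non-overlapping normal form. With `min_gap = 0`
#' only genuinely overlapping intervals merge (strict BED semantics:
#' half-open abutting intervals stay separate); `min_gap = g` additionally
#' merges intervals separated by a gap of fewer than `g` bp. The union of
#' covered bases is preserved and the operation is idempotent.
#'
#' @param x an `interval_set`.
#' @param min_gap non-negative bp; intervals with gap `< min_gap` merge.
#' @return A merged [interval_set()].
#' @export
merge_intervals <- function(x, min_gap = 0) {
  x <- sort_intervals(x)
  if (nrow(x) <= 1L) return(as_interval_set(x[, c("chrom", "start", "end")]))
  chrom <- x$chrom; start <- x$start; end <- x$end
  oc <- character(nrow(x)); os <- numeric(nrow(x)); oe <- numeric(nrow(x))
  k <- 1L; oc[1] <- chrom[1]; os[1] <- start[1]; oe[1] <- end[1]
  for (i in 2:nrow(x)) {
    if (chrom[i] == oc[k] && (start[i] - oe[k]) < min_gap) {
      oe[k] <- max(oe[k], end[i])
    } else {
      k <- k + 1L; oc[k] <- chrom[i]; os[k] <- start[i]; oe[k] <- end[i]
    }
  }
  interval_set(oc[1:k], os[1:k], oe[1:k])
}

# Per-chromosome lookup for fast membership / overlap queries against a
# merged (sorted, disjoint) interval set. Returns list(chrom -> list(s, e)).
interval_lookup <- function(merged) {
  merged <- as_interval_set(merged)
  split_idx <- split(seq_len(nrow(merged)), merged$chrom)
  lapply(split_idx, function(i) list(s = merged$start[i], e = merged$end[i]))
}

# Positions (0-based bp) inside any interval of the lookup for one chromosome.
positions_in_lookup <- function(lk, chrom, pos) {
  tab <- lk[[chrom]]
  if (is.null(tab)) return(rep(FALSE, length(pos)))
  j <- findInterval(pos, tab$s)
  j > 0L & pos < tab$e[pmax(j, 1L)]
}

# Half-open spans [start, end) overlapping any interval of the lookup.
spans_in_lookup <- function(lk, chrom, start, end) {
  tab <- lk[[chrom]]
  if (is.null(tab)) return(rep(FALSE, length(start)))
  j <- findInterval(end - 1, tab$s)  # rightmost interval with s <= end - 1
  j > 0L & tab$e[pmax(j, 1L)] > start
}

#' Count reciprocal overlap hits between two interval sets
#'
#' Counts how many members of `query` intersect at least one member of
#' `subject`, and symmetrically how many members of `subject` intersect at
#' least one member of `query`. Each member is counted at most once. This
#' is the observed statistic of the colocalization analysis (e.g. "how many
#' GWAS blocks hit a binding site / how many binding sites hit a block").
#'
#' @param query,subject `interval_set`s.
#' @return Named integer vector `c(n_query_hit, n_subject_hit)`.
#' @export
count_hits <- function(query, subject) {
  query <- as_interval_set(query); subject <- as_interval_set(subject)
  hit_count <- function(a, b) {
    if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
    lk <- interval_lookup(merge_intervals(b))
    hits <- logical(nrow(a))
    for (cn in unique(a$chrom)) {
      i <- which(a$chrom == cn)
      hits[i] <- spans_in_lookup(lk, cn, a$start[i], a$end[i])
    }
    sum(hits)
  }
  c(n_query_hit = hit_count(query, subject),
    n_subject_hit = hit_count(subject, query))
}

#' Consensus peak regions supported by several datasets
#'
#' Pools all peak sets, merges the pooled peaks into non-overlapping
#' regions, and keeps the regions to which at least `min_support` distinct
#' input datasets contribute one or more overlapping peaks. This is the
#' replicate-consensus rule used to define reproducible binding sites
#' (e.g. "present in a minimum of two out of five datasets").
#'
#' @param peak_sets list of `interval_set`s, one per dataset.
#' @param min_support integer in `[1, length(peak_sets)]`.
#' @return An [interval_set()] of consensus regions, with `score` set to
#'   the supporting-dataset count.
#' @export
consensus_peaks <- function(peak_sets, min_support = 2L) {
  if (!is.list(peak_sets) || length(peak_sets) < 1L)
    stop("peak_sets must be a non-empty list of interval sets")
  min_support <- as.integer(min_support)
  if (is.na(min_support) || min_support < 1L || min_support > length(peak_sets))
    stop("min_support must be between 1 and the number of peak sets")
  pooled <- do.call(rbind, lapply(peak_sets, function(s) as_interval_set(s)[, 1:3]))
  pooled <- as_interval_set(pooled)
  if (nrow(pooled) == 0L) return(interval_set())
  merged <- merge_intervals(pooled)
  lk <- interval_lookup(merged)
  support <- integer(nrow(merged))
  region_key <- paste(merged$chrom, merged$start)
  for (s in peak_sets) {
    s <- as_interval_set(s)
    if (nrow(s) == 0L) next
    seen <- character(0)
    for (cn in unique(s$chrom)) {
      tab <- lk[[cn]]
      if (is.null(tab)) next
      i <- which(s$chrom == cn)
      j <- findInterval(s$end[i] - 1, tab$s)
      ok <- j > 0L & tab$e[pmax(j, 1L)] > s$start[i]
      seen <- c(seen, paste(cn, tab$s[j[ok]]))
    }
    hit <- region_key %in% unique(seen)
    support[hit] <- support[hit] + 1L
  }
  out <- merged[support >= min_support, , drop = FALSE]
  out$score <- support[support >= min_support]
  as_interval_set(out)
}

#' Total bases covered by an interval set
#'
#' @param x an `interval_set`.
#' @return Numeric bp count of the union of covered bases.
#' @export
covered_bases <- function(x) {
  m <- merge_intervals(x)
  if (nrow(m) == 0L) return(0)
  sum(m$end - m$start)
}
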
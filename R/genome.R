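#' Define a genome as an ordered list of chromosomes
#'
#' A genome is the coordinate system every interval, SNP and shuffle in this
#' package is bound to: an ordered set of uniquely named chromosomes with
#' positive lengths in base pairs. Chromosome order is preserved exactly as
#' given and is stable for the lifetime of the object.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer-like vector of chromosome lengths in bp (> 0).
#' @return A `genome` object (a data frame with columns `chrom`, `length`).
#' @examples
#' g <- genome(c("chr1", "chr2"), c(1e6, 2e6))
#' chrom_length(g, "chr2")
#' @export
genome <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop("a genome needs at least one chromosome")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0) || any(length != floor(length)))
    stop("chromosome lengths must be positive integers")
  structure(
    data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
    class = c("genome", "data.frame")
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome: %d chromosome(s), %s bp total\n",
              nrow(x), format(sum(x$length), big.mark = ",")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Look up chromosome length(s)
#'
#' @param g a [genome()] object.
#' @param chrom chromosome name(s); unknown names are an error.
#' @return Numeric vector of lengths in bp.
#' @export
chrom_length <- function(g, chrom) {
  stopifnot(inherits(g, "genome"))
  i <- match(chrom, g$chrom)
  if (anyNA(i)) stop("unknown chromosome(s): ", paste(chrom[is.na(i)], collapse = ", "))
  g$length[i]
}

#' Read a two-column chromosome-sizes table
#'
#' Expects the conventional tab-delimited, headerless `name<TAB>length`
#' format (as produced by `samtools faidx` / UCSC fetchChromSizes).
#'
#' @param path path to the sizes TSV.
#' @return A [genome()] object with chromosomes in file order.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty chromosome-sizes file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad)) stop(sprintf("malformed chromosome-sizes line %d in %s", bad[1], path))
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(len)) stop(sprintf("non-numeric length on line %d in %s", which(is.na(len))[1], path))
  genome(vapply(parts, `[[`, "", 1L), len)
}

#' Write a chromosome-sizes table
#'
#' @param g a [genome()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(g, path) {
  stopifnot(inherits(g, "genome"))
  writeLines(sprintf("%s\t%d", g$chrom, as.integer(g$length)), path)
  invisible(path)
}
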
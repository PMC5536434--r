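#' A Capture-C viewpoint profile
#'
#' Read counts per restriction fragment around a capture viewpoint, with
#' each fragment's signed distance (bp) from the viewpoint midpoint.
#'
#' @param fragments data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `distance` (signed bp) and `count` (reads >= 0);
#'   fragments must be non-overlapping.
#' @param viewpoint optional one-row [interval_set()] for the capture
#'   fragment itself.
#' @return A `viewpoint_profile` object (fragments sorted by position).
#' @export
viewpoint_profile <- function(fragments, viewpoint = NULL) {
  need <- c("chrom", "start", "end", "distance", "count")
  stopifnot(is.data.frame(fragments), all(need %in% names(fragments)))
  if (any(fragments$count < 0)) stop("fragment counts must be >= 0")
  fragments <- fragments[order(fragments$chrom, fragments$start), , drop = FALSE]
  rownames(fragments) <- NULL
  structure(list(fragments = fragments, viewpoint = viewpoint),
            class = "viewpoint_profile")
}

#' Read a fragment-count table
#'
#' Tab-delimited with header `chrom`, `start`, `end`, `distance`, `count`.
#'
#' @param path TSV path.
#' @return A [viewpoint_profile()].
#' @export
read_viewpoint_tsv <- function(path) {
  viewpoint_profile(utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE))
}

# Weighted pool-adjacent-violators for a non-increasing fit.
pava_nonincreasing <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; size <- rep(1L, n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    val[k] <- y[i]; wt[k] <- w[i]; size[k] <- 1L
    while (k > 1L && val[k] > val[k - 1L]) {
      val[k - 1L] <- (val[k - 1L] * wt[k - 1L] + val[k] * wt[k]) / (wt[k - 1L] + wt[k])
      wt[k - 1L] <- wt[k - 1L] + wt[k]
      size[k - 1L] <- size[k - 1L] + size[k]
      k <- k - 1L
    }
  }
  rep(val[seq_len(k)], times = size[seq_len(k)])
}

#' Fit a distance-decay background to a viewpoint profile
#'
#' Contact frequency in chromosome-conformation data decays with genomic
#' distance from the viewpoint. The background expectation is estimated by
#' binning `|distance|` on a log scale, taking a trimmed mean per bin (the
#' top `trim` fraction of counts is excluded so genuine interaction spikes
#' do not inflate their own background), and enforcing monotone
#' non-increase with distance by pooling adjacent violating bins
#' (weighted PAVA). Empty bins inherit by interpolation.
#'
#' @param profile a [viewpoint_profile()] with >= 10 nonzero-distance
#'   fragments.
#' @param n_bins number of log-spaced distance bins (default 50).
#' @param trim fraction of largest counts excluded per bin (default 0.01).
#' @return A `background_curve`: list with `breaks` (log-scaled |distance|
#'   bin edges), `mid` (bin midpoints, bp), `expected` (monotone
#'   non-increasing expected count per bin) and `n` (fragments per bin).
#' @export
fit_background <- function(profile, n_bins = 50L, trim = 0.01) {
  stopifnot(inherits(profile, "viewpoint_profile"))
  fr <- profile$fragments
  d <- abs(fr$distance)
  keep <- d > 0
  if (sum(keep) < 10L) stop("need at least 10 fragments at nonzero distance")
  d <- d[keep]; cnt <- fr$count[keep]
  breaks <- exp(seq(log(min(d)), log(max(d)), length.out = n_bins + 1L))
  breaks[1] <- breaks[1] * (1 - 1e-9)  # include the minimum
  bin <- findInterval(d, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  trimmed_mean <- function(x) {
    # exclude the top `trim` fraction (at least one value when trim > 0)
    # so isolated interaction spikes do not inflate their own background
    drop <- if (trim > 0) min(ceiling(trim * length(x)), length(x) - 1L) else 0L
    if (drop > 0) x <- sort(x)[seq_len(length(x) - drop)]
    mean(x)
  }
  m <- rep(NA_real_, n_bins); nn <- integer(n_bins)
  for (b in unique(bin)) {
    m[b] <- trimmed_mean(cnt[bin == b])
    nn[b] <- sum(bin == b)
  }
  mid <- sqrt(breaks[-1] * breaks[-length(breaks)])
  ok <- !is.na(m)
  if (sum(ok) < 2L) stop("too few occupied distance bins to fit a background")
  m[!ok] <- stats::approx(log(mid[ok]), m[ok], xout = log(mid[!ok]), rule = 2)$y
  w <- pmax(nn, 1L)
  expected <- pava_nonincreasing(m, w)
  structure(list(breaks = breaks, mid = mid, expected = expected, n = nn),
            class = "background_curve")
}

# Expected count for fragments at |distance| d, interpolated on log
# distance between bin midpoints; outside the fitted range the nearest
# bin's expectation is used and the fragment flagged as extrapolated.
expected_at <- function(background, d) {
  d <- abs(d)
  br <- background$breaks
  extrapolated <- d < br[1] | d > br[length(br)]
  d_clip <- pmax(d, .Machine$double.eps)
  e <- stats::approx(log(background$mid), background$expected,
                     xout = log(d_clip), rule = 2)$y
  list(expected = e, extrapolated = extrapolated)
}

#' Call significant interactions against the decay background
#'
#' For each fragment, computes the upper-tail probability of its observed
#' count under a Poisson law whose mean is the background expectation at
#' the fragment's distance, applies Benjamini-Hochberg correction across
#' all tested fragments, and calls fragments with `q <= alpha_fdr`.
#' Fragments at zero distance (the viewpoint itself) are not tested.
#'
#' @param profile a [viewpoint_profile()].
#' @param background a [fit_background()] curve from the same or a matched
#'   profile.
#' @param alpha_fdr FDR threshold for calls (default 0.05).
#' @return Data frame of interaction calls: `chrom`, `start`, `end`,
#'   `distance`, `observed`, `expected`, `extrapolated`, `p_value`,
#'   `q_value`, `called`.
#' @export
call_interactions <- function(profile, background, alpha_fdr = 0.05) {
  stopifnot(inherits(profile, "viewpoint_profile"),
            inherits(background, "background_curve"))
  fr <- profile$fragments[abs(profile$fragments$distance) > 0, , drop = FALSE]
  ex <- expected_at(background, fr$distance)
  p <- stats::ppois(fr$count - 1, lambda = ex$expected, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(chrom = fr$chrom, start = fr$start, end = fr$end,
             distance = fr$distance, observed = fr$count,
             expected = ex$expected, extrapolated = ex$extrapolated,
             p_value = p, q_value = q, called = q <= alpha_fdr,
             stringsAsFactors = FALSE)
}

#' Export observed and expected tracks as bedGraph
#'
#' @param calls a [call_interactions()] result.
#' @param observed_path,expected_path output paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
write_interaction_tracks <- function(calls, observed_path = NULL, expected_path = NULL) {
  line <- function(v) sprintf("%s\t%d\t%d\t%s", calls$chrom,
                              as.integer(calls$start), as.integer(calls$end),
                              format(v, trim = TRUE))
  if (!is.null(observed_path)) writeLines(line(calls$observed), observed_path)
  if (!is.null(expected_path)) writeLines(line(calls$expected), expected_path)
  invisible(c(observed_path, expected_path))
}
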
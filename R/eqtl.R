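#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across genes of
#' the ratio of each sample's count to the geometric-mean reference,
#' restricted to genes with nonzero counts in every sample. When fewer
#' than 10 such genes exist the estimator is unstable and total-count
#' scaling (library size over its geometric mean) is used instead.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @return Positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0)) stop("every sample needs at least one nonzero count")
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (sum(allpos) >= 10L) {
    lc <- log(counts[allpos, , drop = FALSE])
    ref <- rowMeans(lc)
    sf <- apply(lc, 2, function(x) exp(stats::median(x - ref)))
  } else {
    ls <- colSums(counts)
    sf <- ls / exp(mean(log(ls)))
  }
  stats::setNames(sf, colnames(counts))
}

#' Metagene activity score
#'
#' Summarizes the activity of a pathway gene set per sample: each set
#' gene's `log2(normalized count + 1)` is z-scored across samples, and a
#' sample's score is the mean z over the set genes. Genes absent from the
#' matrix are reported and skipped; genes with zero variance contribute 0.
#' Scores are invariant to genes outside the set.
#'
#' @param counts genes x samples count matrix with gene ids as rownames.
#' @param genes character vector of set gene ids (non-empty after
#'   intersection with the matrix).
#' @param sf optional per-sample size factors; computed with
#'   [size_factors()] when `NULL`.
#' @return Numeric per-sample score vector; attribute `"missing"` lists
#'   set genes absent from the matrix.
#' @export
metagene_score <- function(counts, genes, sf = NULL) {
  counts <- as.matrix(counts)
  missing <- setdiff(genes, rownames(counts))
  genes <- intersect(genes, rownames(counts))
  if (length(genes) == 0L) stop("no metagene set gene present in the count matrix")
  if (length(missing))
    message(length(missing), " metagene gene(s) absent from matrix, skipped")
  if (is.null(sf)) sf <- size_factors(counts)
  l <- log2(sweep(counts[genes, , drop = FALSE], 2, sf, "/") + 1)
  z <- t(apply(l, 1, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  score <- colMeans(z)
  attr(score, "missing") <- missing
  score
}

#' Rank-based tertile stratification
#'
#' Splits samples into `low`, `mid` and `high` strata by score rank, with
#' sizes balanced to within one sample. When `n` is not divisible by 3 the
#' extra sample(s) go to the lower strata (first `low`, then `mid`). Ties
#' are broken by stable sample order, and the labels are invariant to any
#' monotone transform of the scores.
#'
#' @param scores numeric per-sample scores (length >= 3).
#' @return An `activity_strata`: list with `score` and `tertile` (factor
#'   `low`/`mid`/`high` in the original sample order).
#' @export
tertile_stratify <- function(scores) {
  n <- length(scores)
  if (n < 3L) stop("need at least 3 samples to stratify")
  base <- n %/% 3L; rem <- n %% 3L
  sizes <- c(low = base + (rem >= 1L), mid = base + (rem >= 2L), high = base)
  ord <- order(scores, method = "radix")  # stable: ties keep sample order
  lab <- rep(c("low", "mid", "high"), times = sizes)
  tertile <- character(n)
  tertile[ord] <- lab
  structure(list(score = scores,
                 tertile = factor(tertile, levels = c("low", "mid", "high"))),
            class = "activity_strata")
}

# Genotype input -> list(factor with observed levels, additive dose).
code_genotype <- function(genotype) {
  if (is.numeric(genotype)) {
    if (!all(stats::na.omit(genotype) %in% 0:2)) stop("numeric genotypes must be 0/1/2")
    dose <- genotype
    g <- factor(c("AA", "AB", "BB")[genotype + 1], levels = c("AA", "AB", "BB"))
  } else {
    g <- as.character(genotype)
    g[g %in% c("AG", "GA", "het")] <- "AB"
    g[g == "GG"] <- "BB"
    map <- c(AA = 0, AB = 1, BB = 2)
    if (!all(stats::na.omit(g) %in% names(map)))
      stop("genotypes must be AA/AB(or AG)/BB(or GG), or 0/1/2")
    dose <- unname(map[g])
    g <- factor(g, levels = c("AA", "AB", "BB"))
  }
  list(factor = droplevels(g), dose = dose)
}

nb_loglik <- function(y, mu, theta) sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))

#' Negative-binomial GLM likelihood-ratio eQTL test
#'
#' Fits a negative-binomial GLM with log link and log-size-factor offset
#' to one gene's counts under (a) an intercept-only model and (b) a model
#' including genotype (categorical by default, additive optional). The
#' dispersion is estimated by maximum likelihood profiled under the
#' alternative model and shared by both fits, so the likelihood-ratio
#' statistic `2 (ll_b - ll_a)` is referred to a chi-square distribution
#' with as many degrees of freedom as genotype parameters (number of
#' observed genotype groups minus 1 for categorical coding; 1 for
#' additive).
#'
#' A genotype group consisting entirely of zero counts separates the
#' categorical fit; such genes are flagged and refit with additive coding.
#' Non-convergence is reported in the result, not fatal.
#'
#' @param y integer counts for one gene across samples.
#' @param genotype per-sample genotypes (`AA`/`AB`(`AG`)/`BB`(`GG`) or
#'   0/1/2); `NA`s are excluded pairwise.
#' @param sf per-sample size factors (positive).
#' @param coding `"categorical"` (default) or `"additive"`.
#' @param dispersion optional fixed NB dispersion (1/theta); when `NULL`
#'   it is estimated from the data under the alternative model.
#' @return An `eqtl_result`: list with `lrt_stat`, `df`, `p_value`,
#'   `group_means` (normalized-count means per genotype group), `beta`
#'   (additive coding only), `dispersion`, `coding`, `converged`, `note`.
#' @export
nb_glm_lrt <- function(y, genotype, sf, coding = c("categorical", "additive"),
                       dispersion = NULL) {
  coding <- match.arg(coding)
  keep <- !is.na(genotype) & !is.na(y)
  y <- y[keep]; sf <- sf[keep]
  gcode <- code_genotype(genotype[keep])
  g <- gcode$factor; dose <- gcode$dose
  tab <- table(g)
  if (sum(tab >= 2L) < 2L)
    stop("need at least 2 genotype groups with at least 2 samples each")
  note <- character(0)
  if (coding == "categorical") {
    zero_group <- tapply(y, g, function(v) all(v == 0))
    if (any(zero_group)) {
      note <- c(note, "all-zero genotype group; refit with additive coding")
      coding <- "additive"
    }
  }
  off <- log(sf)
  x <- if (coding == "categorical") stats::model.matrix(~g) else cbind(1, dose)
  converged <- TRUE
  if (is.null(dispersion)) {
    fit_alt0 <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ x - 1 + offset(off))),
      error = function(e) NULL)
    if (is.null(fit_alt0)) {
      theta <- 1e8
      converged <- FALSE
      note <- c(note, "dispersion estimation failed; near-Poisson fallback")
    } else {
      theta <- fit_alt0$theta
      if (!isTRUE(fit_alt0$converged)) converged <- FALSE
    }
  } else {
    if (dispersion < 0) stop("dispersion must be >= 0")
    theta <- if (dispersion == 0) 1e8 else 1 / dispersion
  }
  fam <- MASS::negative.binomial(theta)
  fit_null <- suppressWarnings(stats::glm(y ~ 1 + offset(off), family = fam))
  fit_alt <- suppressWarnings(stats::glm(y ~ x - 1 + offset(off), family = fam))
  if (!fit_alt$converged || !fit_null$converged) converged <- FALSE
  ll_null <- nb_loglik(y, fitted(fit_null), theta)
  ll_alt <- nb_loglik(y, fitted(fit_alt), theta)
  lrt <- max(0, 2 * (ll_alt - ll_null))
  df <- if (coding == "categorical") nlevels(g) - 1L else 1L
  p <- stats::pchisq(lrt, df = df, lower.tail = FALSE)
  group_means <- tapply(y / sf, g, mean)
  beta <- if (coding == "additive") unname(stats::coef(fit_alt)[2]) else NA_real_
  structure(list(lrt_stat = lrt, df = df, p_value = p,
                 group_means = group_means, beta = beta,
                 dispersion = 1 / theta, coding = coding,
                 converged = converged,
                 note = if (length(note)) paste(note, collapse = "; ") else NA_character_),
            class = "eqtl_result")
}

#' @export
print.eqtl_result <- function(x, ...) {
  cat(sprintf("eqtl_result: LRT = %.3f (df %d), p = %.4g [%s coding]\n",
              x$lrt_stat, x$df, x$p_value, x$coding))
  invisible(x)
}

#' Genotype-expression test conditional on pathway activity
#'
#' Stratifies samples into tertiles of a metagene activity score and runs
#' the negative-binomial genotype LRT for the target gene separately in
#' each tertile. This is the analysis design that asks whether an eQTL is
#' conditional on high pathway (e.g. HIF-1) activity: an effect confined
#' to the high-activity tertile appears there and nowhere else.
#'
#' @param counts genes x samples count matrix (gene ids as rownames).
#' @param genotype per-sample genotypes at the candidate SNP.
#' @param metagene_genes gene ids of the activity metagene.
#' @param target_gene id of the gene whose expression is tested.
#' @param coding,dispersion passed to [nb_glm_lrt()].
#' @return Data frame with one row per stratum: `stratum`, `n`,
#'   `lrt_stat`, `df`, `p_value`, per-genotype normalized means, `note`.
#'   Strata failing the group-size precondition get `NA` statistics and an
#'   explanatory note. The per-sample strata are attached as attribute
#'   `"strata"`.
#' @export
conditional_eqtl <- function(counts, genotype, metagene_genes, target_gene,
                             coding = "categorical", dispersion = NULL) {
  counts <- as.matrix(counts)
  if (!target_gene %in% rownames(counts)) stop("target gene not in count matrix")
  if (length(genotype) != ncol(counts))
    stop("genotype length must match the number of samples")
  sf <- size_factors(counts)
  score <- metagene_score(counts, metagene_genes, sf = sf)
  strata <- tertile_stratify(score)
  y <- counts[target_gene, ]
  rows <- lapply(levels(strata$tertile), function(st) {
    i <- which(strata$tertile == st)
    res <- tryCatch(
      nb_glm_lrt(y[i], genotype[i], sf[i], coding = coding, dispersion = dispersion),
      error = function(e) e)
    gm <- c(mean_AA = NA_real_, mean_AB = NA_real_, mean_BB = NA_real_)
    if (!inherits(res, "error")) {
      got <- paste0("mean_", names(res$group_means))
      gm[got] <- as.numeric(res$group_means)
      data.frame(stratum = st, n = length(i), lrt_stat = res$lrt_stat,
                 df = res$df, p_value = res$p_value, t(gm),
                 note = res$note, stringsAsFactors = FALSE)
    } else {
      data.frame(stratum = st, n = length(i), lrt_stat = NA_real_,
                 df = NA_integer_, p_value = NA_real_, t(gm),
                 note = conditionMessage(res), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "strata") <- strata
  out
}

#' Genotype-stratified inducibility comparison
#'
#' Summarizes per-culture fold changes (stimulated vs untreated, where the
#' untreated value is 1) by genotype and tests whether risk-allele
#' carriers (`AB` + `BB`) respond differently from non-carriers (`AA`)
#' with a two-sided Welch t-test; pairwise Welch tests between genotype
#' groups with >= 2 cultures are also reported. Unbalanced group sizes
#' (e.g. 18/12/3) are accepted.
#'
#' @param fold_changes positive per-culture fold changes.
#' @param genotypes per-culture genotypes.
#' @return List with `summary` (n, mean, sd per genotype),
#'   `carrier_test` (carriers vs AA) and `pairwise` (data frame of group
#'   pairs and p-values).
#' @export
inducibility_by_genotype <- function(fold_changes, genotypes) {
  stopifnot(length(fold_changes) == length(genotypes))
  g <- code_genotype(genotypes)$factor
  smry <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- fold_changes[g == lv]
    data.frame(genotype = lv, n = length(v), mean = mean(v),
               sd = stats::sd(v), stringsAsFactors = FALSE)
  }))
  if (sum(table(g) >= 2L) < 2L) stop("need at least 2 groups with >= 2 cultures")
  carrier <- g %in% c("AB", "BB")
  carrier_test <- if (sum(carrier) >= 2L && sum(!carrier) >= 2L)
    stats::t.test(fold_changes[carrier], fold_changes[!carrier])$p.value
  else NA_real_
  pairs <- utils::combn(levels(g), 2)
  pw <- apply(pairs, 2, function(pr) {
    a <- fold_changes[g == pr[1]]; b <- fold_changes[g == pr[2]]
    if (length(a) >= 2L && length(b) >= 2L) stats::t.test(a, b)$p.value else NA_real_
  })
  list(summary = smry,
       carrier_test = list(comparison = "AB+BB vs AA", p_value = carrier_test),
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             p_value = pw, stringsAsFactors = FALSE))
}
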
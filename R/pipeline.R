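#' Write GWAS-block member SNPs as a TSV
#'
#' Layout: one row per member SNP with columns `block_id`, `chrom`, `pos`
#' (1-based on disk), `id`, `r2`.
#'
#' @param blocks list of [build_block()] results or `(id, chrom, pos)`
#'   member tables (0-based positions in memory).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_blocks_tsv <- function(blocks, path) {
  rows <- lapply(blocks, function(b) {
    if (inherits(b, "haplotype_block")) {
      data.frame(block_id = b$index$id, chrom = b$members$chrom,
                 pos = b$members$pos + 1, id = b$members$id,
                 r2 = b$members$r2, stringsAsFactors = FALSE)
    } else {
      data.frame(block_id = b$id[1], chrom = b$chrom, pos = b$pos + 1,
                 id = if (!is.null(b$snp_id)) b$snp_id else NA_character_,
                 r2 = NA_real_, stringsAsFactors = FALSE)
    }
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read GWAS-block member SNPs from a TSV
#'
#' @param path TSV written by [write_blocks_tsv()].
#' @return List of `(id, chrom, pos)` member tables (0-based positions),
#'   one per block, in first-appearance order.
#' @export
read_blocks_tsv <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("block_id", "chrom", "pos") %in% names(x)))
  ids <- unique(x$block_id)
  lapply(ids, function(b) {
    r <- x[x$block_id == b, , drop = FALSE]
    data.frame(id = b, chrom = r$chrom, pos = r$pos - 1, stringsAsFactors = FALSE)
  })
}

#' Default simulation configuration
#'
#' Bundles the parameters of every generator with defaults sized to the
#' shapes of the motivating study design: 9 GWAS blocks of which 4 overlap
#' a binding site (6 peaks hit), 5 replicate peak datasets with a
#' 2-of-5 consensus, a high-LD pair at r-squared 0.956 in a
#' 10,000-haplotype panel, 50 heterozygous sites at a true allelic ratio
#' of 2, a 450-sample expression cohort with a conditional genotype
#' effect of log(1.5), and a 1,000-fragment viewpoint with one 10-fold
#' spike.
#'
#' @param seed integer master seed for the whole bundle.
#' @param ... overrides for any top-level element (`region`, `ld`,
#'   `allelic`, `expression`, `capture`).
#' @return Nested configuration list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    region = list(n_chrom = 3L, chrom_length = 2e6, n_enhancers = 400L,
                  n_true_peaks = 30L, n_datasets = 5L, min_support = 2L,
                  n_noise_per_dataset = 10L, n_blocks = 9L,
                  n_overlapping = 4L, n_overlap_peaks = 6L),
    ld = list(n_hap = 10000L, maf_index = 0.3, target_r2 = 0.956, n_snps = 5L),
    allelic = list(n_sites = 50L, depth = 1000L, true_ratio = 2.0,
                   input_depth = 1000L, n_homozygous = 2L),
    expression = list(n_samples = 450L, dispersion = 0.2, beta = log(1.5),
                      maf = 0.3, conditional = TRUE),
    capture = list(n_fragments = 1000L, gamma = 1, near_count = 100,
                   spike_fragment = 510L, spike_fold = 10)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown sim_config element(s): ", paste(bad, collapse = ", "))
  for (nm in names(dots)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
  cfg
}

#' Generate the full synthetic input bundle on disk
#'
#' Runs every generator under one master seed and writes all pipeline
#' inputs as plain text, together with a `ground_truth.json` from which
#' every expected statistic can be recomputed, and a `run_config.yaml`
#' ready for [run_all()]. All outputs are pure functions of the
#' configuration and seed: rerunning with the same config yields
#' byte-identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the ground truth and the file paths.
#' @export
simulate_bundle <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  fp <- function(...) file.path(out_dir, ...)

  region <- do.call(simulate_region_sets, config$region)
  write_chrom_sizes(region$genome, fp("genome.tsv"))
  write_bed(region$enhancers, fp("enhancers.bed"))
  write_bed(region$true_peaks, fp("true_peaks.bed"))
  peak_files <- sprintf("peaks_ds%d.bed", seq_along(region$peak_sets))
  for (i in seq_along(region$peak_sets))
    write_bed(region$peak_sets[[i]], fp(peak_files[i]))
  write_blocks_tsv(region$blocks, fp("blocks.tsv"))

  panel <- do.call(simulate_haplotypes, config$ld)
  write_haplotypes_tsv(panel, fp("haplotypes.tsv"), fp("haplotype_sites.tsv"))
  idx <- panel$snps[1, , drop = FALSE]
  utils::write.table(
    data.frame(locus = "locus1", chrom = idx$chrom, pos = idx$pos + 1, id = idx$id),
    fp("index_snps.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  allelic <- do.call(simulate_allelic_reads, config$allelic)
  utils::write.table(allelic, fp("allele_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sam_site <- list(chrom = "chr1", pos = 5000, ref = "A", alt = "G")
  simulate_allelic_sam(fp("chip_reads.sam"), sam_site, chrom_len = 1e6,
                       n_ref = 5L, n_alt = 15L)

  expr <- do.call(simulate_expression, config$expression)
  utils::write.table(expr$counts, fp("counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  utils::write.table(
    data.frame(sample = colnames(expr$counts), snp = "risk_snp",
               genotype = expr$genotype),
    fp("genotypes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(expr$metagenes$HIF1, fp("metagene_hif1.txt"))
  writeLines(expr$metagenes$HIF2, fp("metagene_hif2.txt"))

  spikes <- data.frame(fragment = config$capture$spike_fragment,
                       fold = config$capture$spike_fold)
  vp <- simulate_viewpoint(n_fragments = config$capture$n_fragments,
                           gamma = config$capture$gamma,
                           near_count = config$capture$near_count,
                           spikes = spikes)
  utils::write.table(vp$fragments, fp("viewpoint.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  truth <- list(
    config = config,
    region = region$ground_truth,
    ld = attr(panel, "ground_truth"),
    allelic = attr(allelic, "ground_truth"),
    sam_fixture = list(site = sam_site, n_ref = 5, n_alt = 15),
    expression = list(beta = expr$truth$beta, maf = expr$truth$maf,
                      dispersion = expr$truth$dispersion,
                      conditional = config$expression$conditional,
                      target_gene = expr$target_gene),
    capture = list(spiked = config$capture$spike_fragment,
                   fold = config$capture$spike_fold,
                   gamma = config$capture$gamma)
  )
  jsonlite::write_json(truth, fp("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  run_cfg <- list(
    seed = config$seed,
    inputs = list(
      genome = "genome.tsv",
      haplotypes = "haplotypes.tsv",
      haplotype_sites = "haplotype_sites.tsv",
      index_snps = "index_snps.tsv",
      blocks = "blocks.tsv",
      peak_sets = as.list(peak_files),
      universe = "enhancers.bed",
      allele_counts = "allele_counts.tsv",
      counts = "counts.tsv",
      genotypes = "genotypes.tsv",
      metagene_hif1 = "metagene_hif1.txt",
      metagene_hif2 = "metagene_hif2.txt",
      target_gene = "TARGET",
      viewpoint = "viewpoint.tsv"
    ),
    stages = list(
      blocks = list(enabled = TRUE, r2_threshold = 0.8, window = 1e6),
      enrich = list(enabled = TRUE, n_iter = 10000L,
                    direction = "loci_shuffle", p_estimator = "add_one",
                    overlap_rule = "snp_in_peak", min_support = config$region$min_support),
      allelic = list(enabled = TRUE),
      motif = list(enabled = FALSE),
      eqtl = list(enabled = TRUE, coding = "categorical"),
      interactions = list(enabled = TRUE, n_bins = 50L, trim = 0.01,
                          alpha_fdr = 0.05)
    )
  )
  yaml::write_yaml(run_cfg, fp("run_config.yaml"))

  invisible(list(ground_truth = truth, dir = out_dir,
                 files = list.files(out_dir)))
}

run_config_defaults <- function() {
  list(
    blocks = list(enabled = FALSE, r2_threshold = 0.8, window = 1e6),
    enrich = list(enabled = FALSE, n_iter = 10000L, direction = "loci_shuffle",
                  p_estimator = "add_one", overlap_rule = "snp_in_peak",
                  min_support = 2L),
    allelic = list(enabled = FALSE),
    motif = list(enabled = FALSE),
    eqtl = list(enabled = FALSE, coding = "categorical"),
    interactions = list(enabled = FALSE, n_bins = 50L, trim = 0.01,
                        alpha_fdr = 0.05)
  )
}

#' Read and validate a pipeline run configuration
#'
#' YAML with top-level keys `seed`, `inputs`, `stages`; unknown top-level
#' keys, stage names or stage parameters are rejected so a typo cannot
#' silently disable or misconfigure a stage.
#'
#' @param path YAML path, or an equivalent list.
#' @return Validated configuration list with stage defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  bad <- setdiff(names(cfg), c("seed", "inputs", "stages", "out_dir"))
  if (length(bad)) stop("unknown run-config key(s): ", paste(bad, collapse = ", "))
  known_inputs <- c("genome", "haplotypes", "haplotype_sites", "index_snps",
                    "blocks", "peak_sets", "universe", "allele_counts",
                    "counts", "genotypes", "metagene_hif1", "metagene_hif2",
                    "target_gene", "snp_contexts", "snp_effects", "viewpoint")
  bad <- setdiff(names(cfg$inputs), known_inputs)
  if (length(bad)) stop("unknown input key(s): ", paste(bad, collapse = ", "))
  defaults <- run_config_defaults()
  bad <- setdiff(names(cfg$stages), names(defaults))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (st in names(cfg$stages)) {
    bad <- setdiff(names(cfg$stages[[st]]), names(defaults[[st]]))
    if (length(bad))
      stop("unknown parameter(s) for stage ", st, ": ", paste(bad, collapse = ", "))
    defaults[[st]] <- utils::modifyList(defaults[[st]], cfg$stages[[st]])
  }
  cfg$stages <- defaults
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in order (block building, overlap
#' enrichment, allelic quantification, motif annotation, conditional
#' eQTL, interaction calling) on the inputs named in the configuration,
#' writing per-stage outputs plus a machine-readable manifest
#' (`manifest.json`) that records the package version, the seed, every
#' stage's parameters and MD5 checksums of all inputs and outputs.
#' Rerunning with the same configuration and seed produces byte-identical
#' outputs. A stage failure aborts the run with the stage name and cause;
#' outputs written so far are retained alongside a `.partial` marker.
#'
#' @param config run configuration (YAML path or list; see
#'   [read_run_config()]).
#' @param out_dir output directory.
#' @param input_dir directory against which relative input paths are
#'   resolved (defaults to the config file's directory, or `.`).
#' @return The manifest, invisibly.
#' @export
run_all <- function(config, out_dir, input_dir = NULL) {
  if (is.character(config) && is.null(input_dir)) input_dir <- dirname(config)
  if (is.null(input_dir)) input_dir <- "."
  cfg <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, ".partial")
  file.create(marker)
  rp <- function(p) {
    q <- if (file.exists(p)) p else file.path(input_dir, p)
    if (!file.exists(q)) stop("input file not found: ", p, call. = FALSE)
    q
  }
  manifest <- list(package = "hifreg",
                   version = as.character(utils::packageVersion("hifreg")),
                   seed = cfg$seed, stages = list())
  inputs_used <- character(0)
  outputs <- character(0)
  set.seed(cfg$seed)

  run_stage <- function(name, fun) {
    prm <- cfg$stages[[name]]
    if (!isTRUE(prm$enabled)) return(invisible(NULL))
    res <- tryCatch(fun(prm), error = function(e) e)
    if (inherits(res, "error"))
      stop("stage '", name, "' failed: ", conditionMessage(res), call. = FALSE)
    manifest$stages[[name]] <<- c(list(status = "complete"),
                                  prm[setdiff(names(prm), "enabled")],
                                  list(outputs = basename(res)))
    outputs <<- c(outputs, res)
    invisible(NULL)
  }

  blocks_for_enrich <- NULL

  run_stage("blocks", function(prm) {
    hap <- rp(cfg$inputs$haplotypes); sites <- rp(cfg$inputs$haplotype_sites)
    idxf <- rp(cfg$inputs$index_snps)
    inputs_used <<- c(inputs_used, hap, sites, idxf)
    panel <- read_haplotypes_tsv(hap, sites)
    idx <- load_index_snps(idxf)
    bl <- lapply(idx$id[idx$id %in% panel$snps$id], function(id)
      build_block(panel, id, r2_threshold = prm$r2_threshold, window = prm$window))
    out <- file.path(out_dir, "ld_blocks.tsv")
    write_blocks_tsv(bl, out)
    out
  })

  run_stage("enrich", function(prm) {
    gf <- rp(cfg$inputs$genome)
    pf <- vapply(cfg$inputs$peak_sets, rp, character(1))
    bf <- rp(cfg$inputs$blocks)
    uf <- if (!is.null(cfg$inputs$universe)) rp(cfg$inputs$universe) else NULL
    inputs_used <<- c(inputs_used, gf, pf, bf, uf)
    g <- read_chrom_sizes(gf)
    peaks <- consensus_peaks(lapply(pf, read_bed), min_support = prm$min_support)
    blocks <- read_blocks_tsv(bf)
    blocks_for_enrich <<- blocks
    res <- run_enrichment(
      blocks, peaks, g,
      universe = if (!is.null(uf)) read_bed(uf) else NULL,
      config = shuffle_config(n_iter = prm$n_iter, seed = cfg$seed,
                              direction = prm$direction,
                              p_estimator = prm$p_estimator,
                              overlap_rule = prm$overlap_rule))
    out <- file.path(out_dir, "enrichment.json")
    jsonlite::write_json(list(
      observed = res$observed, p_value = res$p_value,
      histogram = list(values = res$null$values, counts = res$null$counts),
      n_iter = res$null$n_iter, direction = prm$direction,
      p_estimator = prm$p_estimator, overlap_rule = prm$overlap_rule,
      seed = cfg$seed
    ), out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out
  })

  run_stage("allelic", function(prm) {
    af <- rp(cfg$inputs$allele_counts)
    inputs_used <<- c(inputs_used, af)
    ac <- read_allele_counts(af)
    assays <- ac[ac$assay != "input", , drop = FALSE]
    inputs <- ac[ac$assay == "input", , drop = FALSE]
    rows <- lapply(seq_len(nrow(assays)), function(i) {
      s <- assays[i, ]
      inp <- inputs[inputs$site == s$site, , drop = FALSE]
      calibrated <- NA_real_
      if (nrow(inp) >= 1L && s$count_a > 0 && all(inp$count_a > 0)) {
        calib <- ratio_calibration(inp$count_b / inp$count_a)
        calibrated <- calibrated_ratio(s$count_b / s$count_a, calib)
      }
      tst <- test_imbalance_counts(list(count_a = s$count_a, count_b = s$count_b))
      data.frame(site = s$site, assay = s$assay, count_a = s$count_a,
                 count_b = s$count_b, calibrated_ratio = calibrated,
                 p_value = tst$p_value, stringsAsFactors = FALSE)
    })
    out <- file.path(out_dir, "allelic.tsv")
    utils::write.table(do.call(rbind, rows), out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out
  })

  run_stage("motif", function(prm) {
    cf <- rp(cfg$inputs$snp_contexts); ef <- rp(cfg$inputs$snp_effects)
    inputs_used <<- c(inputs_used, cf, ef)
    snps <- utils::read.delim(ef, header = TRUE, stringsAsFactors = FALSE)
    eff <- annotate_snp_effects(cf, snps)
    out <- file.path(out_dir, "motif_effects.tsv")
    utils::write.table(eff, out, sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  run_stage("eqtl", function(prm) {
    cfp <- rp(cfg$inputs$counts); gfp <- rp(cfg$inputs$genotypes)
    m1 <- rp(cfg$inputs$metagene_hif1); m2 <- rp(cfg$inputs$metagene_hif2)
    inputs_used <<- c(inputs_used, cfp, gfp, m1, m2)
    counts <- as.matrix(utils::read.delim(cfp, header = TRUE, row.names = 1,
                                          check.names = FALSE))
    geno <- utils::read.delim(gfp, header = TRUE, stringsAsFactors = FALSE)
    gv <- geno$genotype[match(colnames(counts), geno$sample)]
    res <- rbind(
      cbind(metagene = "HIF1",
            conditional_eqtl(counts, gv, readLines(m1), cfg$inputs$target_gene,
                             coding = prm$coding)),
      cbind(metagene = "HIF2",
            conditional_eqtl(counts, gv, readLines(m2), cfg$inputs$target_gene,
                             coding = prm$coding)))
    out <- file.path(out_dir, "eqtl.tsv")
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  run_stage("interactions", function(prm) {
    vf <- rp(cfg$inputs$viewpoint)
    inputs_used <<- c(inputs_used, vf)
    prof <- read_viewpoint_tsv(vf)
    bg <- fit_background(prof, n_bins = prm$n_bins, trim = prm$trim)
    calls <- call_interactions(prof, bg, alpha_fdr = prm$alpha_fdr)
    out <- file.path(out_dir, "interactions.tsv")
    utils::write.table(calls, out, sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  md5_by_name <- function(paths) {
    x <- tools::md5sum(unique(paths))
    stats::setNames(as.list(unname(x)), basename(names(x)))
  }
  manifest$input_checksums <- md5_by_name(inputs_used)
  manifest$output_checksums <- md5_by_name(outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(marker)
  invisible(manifest)
}
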
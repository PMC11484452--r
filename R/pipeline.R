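#' Load and validate a pipeline configuration
#'
#' A configuration is a named list (or path to a YAML file) with exactly one
#' of:
#' * `simulate`: a list of [sim_config()] overrides (possibly empty), or
#' * `inputs`: paths `counts`, `region_counts`, `annotation`, `samples`, and
#'   optionally `qpcr` and `gene_sets`;
#' plus `outdir`, optional `seed` (overrides the simulate seed) and optional
#' `thresholds` (`fpkm_filter` = 1, `meg_alpha` = 0.05, `meg_fold` = 2,
#' `ora_alpha` = 0.05, `pseudocount` = 1).
#'
#' @param config Named list or path to a YAML file.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp)
    stop("config must contain exactly one of 'simulate' or 'inputs'")
  if (is.null(config$outdir)) stop("config requires 'outdir'")
  if (has_inp) {
    need <- c("counts", "region_counts", "annotation", "samples")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss))
      stop("inputs missing: ", paste(miss, collapse = ", "))
    for (p in unlist(config$inputs))
      if (!file.exists(p)) stop("input file not found: ", p)
  }
  th <- list(fpkm_filter = 1, meg_alpha = 0.05, meg_fold = 2,
             ora_alpha = 0.05, pseudocount = 1)
  th[names(config$thresholds %||% list())] <- config$thresholds
  if (any(unlist(th) <= 0)) stop("thresholds must be positive")
  config$thresholds <- th
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the full muscle / M-EV cargo analysis pipeline
#'
#' Executes, in order: data simulation (or loading), FPKM quantification and
#' filtering, region distribution and full-length classification, divergence
#' statistics (correlation, PCA), rank-class enrichment with ANOVA + LSD,
#' the negative-binomial MEG test at both breed levels and globally with a
#' three-way catalog comparison, pathway over-representation (when gene sets
#' are available) and qPCR concordance (when a CT table is available). All
#' stage tables are written as TSV under `outdir`, together with
#' `manifest.json` (inputs, seed, thresholds) and `summary.json` (headline
#' statistics).
#'
#' @param config A [pipeline_config()] (or list / YAML path coercible to
#'   one).
#' @return Invisibly, a list with all stage results and the parsed summary.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  th <- cfg$thresholds
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  ## ---- stage: inputs -------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (!is.null(cfg$seed)) sim_args$seed <- cfg$seed
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_dataset(scfg)
    annotation <- sim$annotation; counts <- sim$counts
    regions <- sim$regions; samples <- sim$samples
    qpcr <- sim$qpcr; gene_sets <- sim$gene_sets
    seed_used <- scfg$seed
  } else {
    annotation <- read_annotation(cfg$inputs$annotation)
    counts <- read_count_matrix(cfg$inputs$counts)
    regions <- read_region_counts(cfg$inputs$region_counts)
    samples <- read_sample_sheet(cfg$inputs$samples)
    qpcr <- if (!is.null(cfg$inputs$qpcr)) read_qpcr(cfg$inputs$qpcr)
    gene_sets <- if (!is.null(cfg$inputs$gene_sets))
      read_gene_sets(cfg$inputs$gene_sets)
    sim <- NULL
    seed_used <- cfg$seed %||% NA
  }
  sdf <- as.data.frame(samples)
  muscle_s <- sdf$sample_id[sdf$compartment == "muscle"]
  mev_s <- sdf$sample_id[sdf$compartment == "MEV"]

  ## ---- stage: quantify -----------------------------------------------
  fpkm <- compute_fpkm(counts, annotation)
  filt <- filter_low_expression(fpkm, th$fpkm_filter)
  expr <- filt$expr
  write_count_matrix(round(expr, 6), file.path(outdir, "fpkm.tsv"))
  rdist <- region_distribution(regions)
  write.table(rdist, file.path(outdir, "region_distribution.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  fl <- classify_full_length(regions, samples)

  ## ---- stage: divergence ---------------------------------------------
  lg <- log_transform(expr, th$pseudocount)
  corr <- pearson_matrix(lg)
  write.table(data.frame(sample_id = rownames(corr$r), corr$r,
                         check.names = FALSE),
              file.path(outdir, "correlation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pca <- pca_samples(lg)
  write.table(data.frame(sample_id = rownames(pca$scores), pca$scores,
                         check.names = FALSE),
              file.path(outdir, "pca_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## ---- stage: rank enrichment ----------------------------------------
  classes <- assign_rank_classes(expr[, muscle_s, drop = FALSE])
  ranks <- maintained_fractions(expr[, muscle_s, drop = FALSE],
                                expr[, mev_s, drop = FALSE],
                                samples, classes)
  write.table(ranks, file.path(outdir, "rank_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  shares <- cumulative_share(expr, min(1000L, nrow(expr)), samples)
  write.table(data.frame(sample_id = names(shares), share = shares),
              file.path(outdir, "cumulative_share.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  lsd <- anova_lsd(ranks)

  ## ---- stage: MEG calling --------------------------------------------
  breeds <- unique(sdf$breed)
  levels_all <- c(breeds, "Global")
  de <- list(); catalogs <- list()
  for (lv in levels_all) {
    de[[lv]] <- meg_de(counts, samples, lv, genes = rownames(expr))
    catalogs[[lv]] <- call_megs(de[[lv]], lv, th$meg_alpha, th$meg_fold)
    write.table(as.data.frame(de[[lv]]),
                file.path(outdir, sprintf("de_%s.tsv", lv)), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(catalogs[[lv]]$genes,
               file.path(outdir, sprintf("megs_%s.tsv", lv)))
  }
  venn <- if (length(catalogs) == 3L)
    do.call(compare_catalogs, unname(catalogs))

  ## ---- stage: pathway ORA --------------------------------------------
  ora <- NULL; pathway_partition <- NULL
  if (!is.null(gene_sets) && length(breeds) >= 2L) {
    ora <- lapply(breeds, function(b)
      enrich_all(catalogs[[b]], gene_sets, de[[b]]$gene_id, th$ora_alpha))
    names(ora) <- breeds
    for (b in breeds)
      write.table(as.data.frame(ora[[b]]),
                  file.path(outdir, sprintf("ora_%s.tsv", b)), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    pathway_partition <- compare_pathway_sets(ora[[1L]], ora[[2L]],
                                              th$ora_alpha)
  }

  ## ---- stage: qPCR ---------------------------------------------------
  concordance <- NULL
  if (!is.null(qpcr)) {
    rel <- delta_delta_ct(qpcr)
    panel <- setdiff(unique(qpcr$gene_id), attr(qpcr, "reference_gene"))
    concordance <- lapply(c("muscle", "MEV"), function(cp)
      validate_concordance(rel, fpkm, panel, samples, cp, th$pseudocount))
    names(concordance) <- c("muscle", "MEV")
  }

  ## ---- summaries ------------------------------------------------------
  class_means <- tapply(ranks$fraction_maintained, ranks$class, mean)
  comp_means <- attr(shares, "compartment_means")
  summary <- list(
    n_genes_input = nrow(counts),
    n_genes_retained = nrow(expr),
    maintained_fraction_percent = as.list(class_means),
    top1000_share = list(muscle = unname(comp_means[["muscle"]]),
                         mev = unname(comp_means[["MEV"]])),
    anova = list(F = lsd$F, p = lsd$p_anova,
                 letters = as.list(lsd$letters)),
    meg_counts = lapply(catalogs, function(ct)
      list(n = length(ct$genes), n_tested = ct$n_tested,
           ratio = ct$ratio)),
    venn_counts = if (!is.null(venn)) as.list(venn$counts),
    pathway_partition = if (!is.null(pathway_partition))
      as.list(pathway_partition$counts),
    full_length = list(
      consensus_sizes = lapply(fl$consensus, length),
      shared = length(fl$shared_consensus)),
    qpcr_concordance = if (!is.null(concordance))
      lapply(concordance, function(x) list(r = x$r, p = x$p)))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "evcargo",
    version = as.character(utils::packageVersion("evcargo")),
    seed = seed_used,
    thresholds = th,
    mode = if (!is.null(cfg$simulate)) "simulate" else "inputs",
    inputs = cfg$inputs %||% NULL,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(annotation = annotation, counts = counts,
                 regions = regions, samples = samples, fpkm = fpkm,
                 expr = expr, dropped = filt$dropped,
                 region_distribution = rdist, full_length = fl,
                 correlation = corr, pca = pca, classes = classes,
                 rank_summary = ranks, shares = shares, anova_lsd = lsd,
                 de = de, catalogs = catalogs, venn = venn, ora = ora,
                 pathway_partition = pathway_partition,
                 concordance = concordance, sim = sim, summary = summary))
}
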
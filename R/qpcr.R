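#' 2^-ddCt relative quantification
#'
#' Per sample and target gene: dCT = CT_target - CT_reference(sample);
#' ddCT = dCT - dCT_calibrator(gene); relative expression = 2^-ddCT, which is
#' 1 for every gene in the calibrator sample by construction.
#'
#' @param qpcr A `qpcr_table` (columns `sample_id`, `gene_id`, `ct`).
#' @param reference_gene Reference transcript id (defaults to the table's
#'   `reference_gene` attribute); must be measured in every sample.
#' @param calibrator_sample Calibrator sample id (defaults to the table's
#'   attribute, else the first muscle-free choice is an error).
#' @return data.frame of class `relative_expression` with `sample_id`,
#'   `gene_id`, `dct`, `ddct`, `rel` (2^-ddCT).
#' @export
delta_delta_ct <- function(qpcr,
                           reference_gene = attr(qpcr, "reference_gene"),
                           calibrator_sample =
                             attr(qpcr, "calibrator_sample")) {
  if (is.null(reference_gene)) stop("reference_gene must be specified")
  if (is.null(calibrator_sample)) stop("calibrator_sample must be specified")
  df <- as.data.frame(qpcr)
  ref <- df[df$gene_id == reference_gene, ]
  ref_ct <- setNames(ref$ct, ref$sample_id)
  targets <- df[df$gene_id != reference_gene, ]
  miss <- setdiff(unique(targets$sample_id), names(ref_ct))
  if (length(miss))
    stop("missing reference CT for sample(s): ", paste(miss, collapse = ", "))
  if (!calibrator_sample %in% df$sample_id)
    stop("calibrator sample not in table: ", calibrator_sample)
  targets$dct <- targets$ct - ref_ct[targets$sample_id]
  calib <- targets[targets$sample_id == calibrator_sample, ]
  calib_dct <- setNames(calib$dct, calib$gene_id)
  miss_g <- setdiff(unique(targets$gene_id), names(calib_dct))
  if (length(miss_g))
    stop("gene(s) not measured in the calibrator sample: ",
         paste(miss_g, collapse = ", "))
  targets$ddct <- targets$dct - calib_dct[targets$gene_id]
  targets$rel <- 2^(-targets$ddct)
  out <- targets[, c("sample_id", "gene_id", "dct", "ddct", "rel")]
  rownames(out) <- NULL
  structure(out, reference_gene = reference_gene,
            calibrator_sample = calibrator_sample,
            class = c("relative_expression", "data.frame"))
}

#' Concordance of qPCR expression with RNA-seq FPKM
#'
#' Gene expression levels from qPCR are compared with RNA-seq across panel
#' genes x samples of one compartment on the reference-normalized scale:
#' -dCT = log2 expression relative to the reference gene, which is linear in
#' log2(FPKM) up to a constant, so perfectly concordant measurements give
#' r = 1. (The calibrator-normalized 2^-ddCt values are per-gene relative
#' quantities and carry no cross-gene scale, so they are not used for the
#' level comparison.) The report gives the Pearson correlation with
#' two-sided p over all (gene, sample) points, plus the per-gene correlation
#' of sample-averaged levels.
#'
#' @param rel A `relative_expression` from [delta_delta_ct()] (its `dct`
#'   column holds CT_target - CT_reference).
#' @param expr FPKM matrix containing the compartment's samples as columns.
#' @param genes Panel gene ids present in both inputs.
#' @param samples A [sample_sheet()].
#' @param compartment `"muscle"` or `"MEV"`.
#' @param pseudocount Added to FPKM before log2.
#' @return List of class `concordance_report` with `r`, `p`, `n_points`,
#'   `r_gene`, `p_gene`, `n_genes`, `compartment`.
#' @export
validate_concordance <- function(rel, expr, genes, samples, compartment,
                                 pseudocount = 1) {
  sdf <- as.data.frame(samples)
  comp_samples <- intersect(sdf$sample_id[sdf$compartment == compartment],
                            colnames(expr))
  genes <- intersect(genes, rownames(expr))
  sub <- rel[rel$gene_id %in% genes & rel$sample_id %in% comp_samples, ]
  if (nrow(sub) < 3L) stop("fewer than 3 (gene, sample) points")
  x <- -sub$dct
  y <- log2(expr[cbind(sub$gene_id, sub$sample_id)] + pseudocount)
  ct <- stats::cor.test(x, y, method = "pearson")
  gm_x <- tapply(x, sub$gene_id, mean)
  gm_y <- tapply(y, sub$gene_id, mean)
  if (length(gm_x) >= 3L) {
    ctg <- stats::cor.test(as.numeric(gm_x), as.numeric(gm_y[names(gm_x)]),
                           method = "pearson")
    r_gene <- unname(ctg$estimate); p_gene <- ctg$p.value
  } else {
    r_gene <- NA_real_; p_gene <- NA_real_
  }
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 n_points = nrow(sub), r_gene = r_gene, p_gene = p_gene,
                 n_genes = length(gm_x), compartment = compartment),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(paste0("qPCR/RNA-seq concordance [%s]: r = %.3f ",
                     "(p = %.3g, %d points); per-gene fold r = %.3f\n"),
              x$compartment, x$r, x$p, x$n_points, x$r_gene))
  invisible(x)
}
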
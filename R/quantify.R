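#' Compute FPKM from gene counts
#'
#' FPKM\[g, s\] = count\[g, s\] / ((gene_length\[g\] / 1e3) *
#' (library_size\[s\] / 1e6)), with library size taken as the column sum of
#' the count matrix (total assigned fragments).
#'
#' @param counts Genes x samples count matrix.
#' @param annotation A [gene_annotation()] covering all genes in `counts`.
#' @return Genes x samples FPKM matrix.
#' @export
compute_fpkm <- function(counts, annotation) {
  counts <- validate_count_matrix(counts)
  miss <- setdiff(rownames(counts), rownames(annotation$genes))
  if (length(miss))
    stop("gene(s) absent from annotation: ",
         paste(head(miss, 5L), collapse = ", "))
  len <- annotation$genes[rownames(counts), "gene_length"]
  if (any(len <= 0))
    stop("zero-length gene(s): ",
         paste(head(rownames(counts)[len <= 0], 5L), collapse = ", "))
  lib <- colSums(counts)
  if (any(lib <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  sweep(counts / (len / 1e3), 2L, lib / 1e6, "/")
}

#' Filter genes with low expression everywhere
#'
#' A gene is dropped iff its maximum FPKM over all samples (both
#' compartments) is below `threshold`; i.e. genes below the threshold in both
#' muscles and M-EVs are eliminated, while a gene expressed anywhere is kept.
#'
#' @param expr Genes x samples FPKM matrix.
#' @param threshold Non-negative FPKM cutoff (default 1).
#' @return List with `expr` (filtered matrix) and `dropped` (character vector
#'   of removed gene ids).
#' @export
filter_low_expression <- function(expr, threshold = 1) {
  if (threshold < 0) stop("threshold must be >= 0")
  keep <- apply(expr, 1L, max) >= threshold
  list(expr = expr[keep, , drop = FALSE],
       dropped = rownames(expr)[!keep])
}

#' Per-sample read distribution over mRNA regions
#'
#' For each sample, the fraction of assigned tags falling in the 5'UTR, CDS
#' and 3'UTR (tag count per region / total assigned tags).
#'
#' @param rc A [region_counts()] object.
#' @return data.frame with columns `sample_id`, `utr5`, `cds`, `utr3`;
#'   fractions sum to 1 per sample.
#' @export
region_distribution <- function(rc) {
  stopifnot(inherits(rc, "region_counts"))
  tot5 <- colSums(rc$utr5); totc <- colSums(rc$cds); tot3 <- colSums(rc$utr3)
  total <- tot5 + totc + tot3
  if (any(total == 0))
    stop("sample(s) with zero assigned tags: ",
         paste(names(total)[total == 0], collapse = ", "))
  data.frame(sample_id = colnames(rc$cds),
             utr5 = tot5 / total, cds = totc / total, utr3 = tot3 / total,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify full-length-potential transcripts
#'
#' A gene-sample has full-length potential iff reads are detected in all
#' three regions (5'UTR, CDS and 3'UTR counts all > 0). Genes with zero
#' region-derived counts in every sample of both compartments are removed
#' first. Per compartment, the consensus set contains genes called in every
#' sample of that compartment; pairwise per-sample overlap counts and the
#' cross-compartment shared consensus are also reported.
#'
#' @param rc A [region_counts()] object.
#' @param samples A [sample_sheet()] covering the columns of `rc`.
#' @return List with `calls` (logical genes x samples matrix), `consensus`
#'   (list of gene sets per compartment), `shared_consensus`, `overlaps`
#'   (per compartment, sample x sample matrices of called-set overlap
#'   counts) and `removed` (all-zero genes dropped up front).
#' @export
classify_full_length <- function(rc, samples) {
  stopifnot(inherits(rc, "region_counts"))
  sdf <- as.data.frame(samples)
  miss <- setdiff(sdf$sample_id, colnames(rc$cds))
  if (length(miss))
    stop("sample(s) absent from region counts: ", paste(miss, collapse = ", "))
  tot <- region_totals(rc)
  removed <- rownames(tot)[rowSums(tot) == 0]
  keep <- setdiff(rownames(tot), removed)
  calls <- (rc$utr5[keep, sdf$sample_id, drop = FALSE] > 0) &
    (rc$cds[keep, sdf$sample_id, drop = FALSE] > 0) &
    (rc$utr3[keep, sdf$sample_id, drop = FALSE] > 0)
  comps <- unique(sdf$compartment)
  consensus <- lapply(comps, function(cp) {
    s <- sdf$sample_id[sdf$compartment == cp]
    rownames(calls)[rowSums(calls[, s, drop = FALSE]) == length(s)]
  })
  names(consensus) <- comps
  overlaps <- lapply(comps, function(cp) {
    s <- sdf$sample_id[sdf$compartment == cp]
    m <- crossprod(calls[, s, drop = FALSE] * 1)
    dimnames(m) <- list(s, s)
    m
  })
  names(overlaps) <- comps
  shared <- if (length(comps) >= 2L) Reduce(intersect, consensus)
            else consensus[[1L]]
  list(calls = calls, consensus = consensus, shared_consensus = shared,
       overlaps = overlaps, removed = removed)
}
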
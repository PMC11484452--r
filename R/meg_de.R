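#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: for each gene with a positive
#' geometric mean across samples (the reference set), form the ratio of the
#' sample's count to that geometric mean; the size factor is the median of
#' these ratios.
#'
#' @param counts Genes x samples count matrix.
#' @return Named positive numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  counts <- validate_count_matrix(counts)
  loggeo <- rowMeans(log(counts))
  ref <- is.finite(loggeo)
  if (!any(ref))
    stop("empty reference set: no gene has positive counts in every sample; ",
         "consider a pseudo-reference on count + 1")
  sf <- apply(counts[ref, , drop = FALSE], 2L, function(col)
    median(exp(log(col) - loggeo[ref])))
  if (any(sf <= 0)) stop("non-positive size factor computed")
  sf
}

#' Method-of-moments dispersion with trend shrinkage
#'
#' Per gene, a raw negative-binomial dispersion is estimated from normalized
#' counts via the method of moments, alpha_raw = max(0, (s2 - mu) / mu^2),
#' using the pooled within-group variance s2 and the mean of the group means
#' mu. Raw estimates are then shrunk halfway toward a fitted mean-dispersion
#' trend alpha(mu) = a0 + a1/mu (ordinary least squares over genes), and
#' floored at 1e-8.
#'
#' @param counts Genes x samples count matrix.
#' @param sf Size factors from [size_factors()].
#' @param group Factor of length `ncol(counts)` with two levels; each group
#'   needs >= 2 samples.
#' @return Named numeric vector of per-gene dispersions (>= 1e-8).
#' @export
estimate_dispersion <- function(counts, sf, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("design must have exactly two groups")
  if (any(table(group) < 2L))
    stop("each group needs >= 2 samples for dispersion estimation")
  norm <- sweep(counts, 2L, sf, "/")
  lv <- levels(group)
  g1 <- group == lv[1L]; g2 <- group == lv[2L]
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  ss <- rowSums((norm[, g1, drop = FALSE] - m1)^2) +
    rowSums((norm[, g2, drop = FALSE] - m2)^2)
  s2 <- ss / (ncol(norm) - 2L)
  mu <- (m1 + m2) / 2
  raw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  # mean-dispersion trend alpha(mu) = a0 + a1/mu, least squares
  ok <- mu > 0 & is.finite(raw)
  if (sum(ok) >= 10L) {
    x <- 1 / mu[ok]
    co <- stats::lm.fit(cbind(1, x), raw[ok])$coefficients
    fitted <- pmax(0, co[1L] + co[2L] / mu)
  } else {
    fitted <- rep(mean(raw[ok]) %||% 0, length(raw))
  }
  alpha <- pmax(1e-8, 0.5 * raw + 0.5 * fitted)
  setNames(alpha, rownames(counts))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' padj for the i-th smallest p-value is min over j >= i of p_(j) * m / j,
#' capped at 1; the original order is restored.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

#' Two-group negative-binomial Wald test
#'
#' For each gene, group means of median-of-ratios-normalized counts are
#' formed (with a pseudo-fraction of 0.5 added to each group mean to avoid
#' infinite fold changes); log2FC = log2(mean_EV / mean_muscle). The
#' standard error comes from the delta method on the NB variance of each
#' group mean, Var(mean_k) = n_k^-2 * sum_j (m_k / sf_j + alpha * m_k^2),
#' giving a Wald z = log2FC / SE, two-sided normal p-values, and
#' Benjamini-Hochberg adjusted p-values over the tested genes. Genes with
#' zero counts in every sample are excluded and reported.
#'
#' @param counts Genes x samples count matrix.
#' @param sf Size factors from [size_factors()].
#' @param dispersions Per-gene dispersions from [estimate_dispersion()].
#' @param group Factor with levels `(muscle, MEV)` order: the first level is
#'   the denominator (muscle), the second the numerator (M-EV).
#' @return data.frame of class `de_result` with `gene_id`, `base_mean`,
#'   `log2fc`, `se_log2fc`, `wald_z`, `p`, `padj`; excluded all-zero genes
#'   in attribute `excluded`.
#' @export
wald_test <- function(counts, sf, dispersions, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("design must have exactly two groups")
  nonzero <- rowSums(counts) > 0
  excluded <- rownames(counts)[!nonzero]
  counts <- counts[nonzero, , drop = FALSE]
  alpha <- dispersions[rownames(counts)]
  norm <- sweep(counts, 2L, sf, "/")
  lv <- levels(group)
  g1 <- group == lv[1L]; g2 <- group == lv[2L]
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE]) + 0.5
  m2 <- rowMeans(norm[, g2, drop = FALSE]) + 0.5
  lfc <- log2(m2 / m1)
  v1 <- (outer(m1, 1 / sf[g1]) + alpha * m1^2) |> rowSums()
  v1 <- v1 / n1^2
  v2 <- (outer(m2, 1 / sf[g2]) + alpha * m2^2) |> rowSums()
  v2 <- v2 / n2^2
  se <- sqrt(v1 / m1^2 + v2 / m2^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pnorm(-abs(z))
  res <- data.frame(gene_id = rownames(counts),
                    base_mean = rowMeans(norm),
                    log2fc = lfc, se_log2fc = se, wald_z = z, p = p,
                    padj = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = rownames(counts))
  structure(res, excluded = excluded,
            class = c("de_result", "data.frame"))
}

#' Run the MEG differential test at one stratum
#'
#' Subsets samples to a breed (or keeps all for `"Global"`), orients the
#' design as muscle vs M-EV, and runs [size_factors()],
#' [estimate_dispersion()] and [wald_test()].
#'
#' @param counts Genes x samples count matrix (columns covering `samples`).
#' @param samples A [sample_sheet()].
#' @param level One of the breed labels or `"Global"`.
#' @param genes Optional gene subset to test (e.g. the FPKM-filtered set).
#' @return A `de_result` (see [wald_test()]) with attribute `level`.
#' @export
meg_de <- function(counts, samples, level = "Global", genes = NULL) {
  sdf <- as.data.frame(samples)
  if (level != "Global") {
    if (!level %in% sdf$breed) stop("unknown level: ", level)
    sdf <- sdf[sdf$breed == level, , drop = FALSE]
  }
  cc <- counts[, sdf$sample_id, drop = FALSE]
  if (!is.null(genes)) cc <- cc[intersect(rownames(cc), genes), ,
                                drop = FALSE]
  group <- factor(sdf$compartment, levels = c("muscle", "MEV"))
  sf <- size_factors(cc)
  disp <- estimate_dispersion(cc, sf, group)
  res <- wald_test(cc, sf, disp, group)
  attr(res, "level") <- level
  res
}

#' Call vesicle-enriched genes (MEGs) from a differential test
#'
#' A gene is a MEG iff its adjusted p-value is <= `alpha` and its EV/muscle
#' fold change is >= `min_fold` (log2FC >= log2(min_fold)).
#'
#' @param de A `de_result` from [wald_test()] / [meg_de()].
#' @param level Stratum label carried in the catalog.
#' @param alpha Adjusted-p threshold.
#' @param min_fold Minimum fold change.
#' @return List of class `meg_catalog` with `level`, `genes` (character
#'   vector), `n_tested` and `ratio` (= length(genes) / n_tested).
#' @export
call_megs <- function(de, level = attr(de, "level") %||% "Global",
                      alpha = 0.05, min_fold = 2) {
  sel <- de$padj <= alpha & de$log2fc >= log2(min_fold)
  genes <- de$gene_id[sel]
  structure(list(level = level, genes = genes, n_tested = nrow(de),
                 ratio = length(genes) / nrow(de)),
            class = "meg_catalog")
}

#' @export
print.meg_catalog <- function(x, ...) {
  cat(sprintf("meg_catalog [%s]: %d MEGs of %d tested genes (%.1f%%)\n",
              x$level, length(x$genes), x$n_tested, 100 * x$ratio))
  invisible(x)
}

#' Three-way Venn partition of MEG catalogs
#'
#' @param cat_a,cat_b,cat_c `meg_catalog` objects (e.g. the two breed-level
#'   and the global catalogs).
#' @return List of class `venn_partition` with `regions` (the 7 disjoint
#'   member sets, named by the catalogs they belong to), `counts`, and
#'   `percent_of` (each region's share of each catalog's size).
#' @export
compare_catalogs <- function(cat_a, cat_b, cat_c) {
  cats <- list(cat_a, cat_b, cat_c)
  labs <- vapply(cats, `[[`, "", "level")
  if (anyDuplicated(labs)) stop("catalog levels must be distinct")
  sets <- lapply(cats, `[[`, "genes")
  names(sets) <- labs
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L,
                                                dimnames = list(NULL, labs))
  key <- apply(member, 1L, function(row)
    paste(labs[row], collapse = "&"))
  regions <- split(all_genes, key)
  combos <- unlist(lapply(1:3, function(k)
    apply(combn(labs, k), 2L, paste, collapse = "&")))
  regions <- setNames(lapply(combos, function(cb)
    regions[[cb]] %||% character()), combos)
  counts <- vapply(regions, length, 1L)
  percent_of <- sapply(labs, function(l) {
    vapply(names(regions), function(cb) {
      if (l %in% strsplit(cb, "&", fixed = TRUE)[[1L]])
        100 * counts[[cb]] / max(1L, length(sets[[l]]))
      else 0
    }, 1)
  })
  structure(list(regions = regions, counts = counts,
                 percent_of = percent_of, levels = labs),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition over:", paste(x$levels, collapse = ", "), "\n")
  print(x$counts)
  invisible(x)
}
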
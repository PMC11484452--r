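#' Log10 transform an expression matrix
#'
#' @param expr FPKM matrix.
#' @param pseudocount Added before taking log10; must be > 0 unless all
#'   values are positive.
#' @return Matrix of log10(FPKM + pseudocount).
#' @export
log_transform <- function(expr, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(expr <= 0))
    stop("zero FPKM with pseudocount 0")
  log10(expr + pseudocount)
}

#' Pairwise Pearson correlation between samples
#'
#' Pearson r over genes for every sample pair, with two-sided p-values from
#' the t transform with n - 2 degrees of freedom.
#'
#' @param m Genes x samples matrix (>= 3 genes).
#' @return List of class `correlation_matrix` with `r` and `p` (sample x
#'   sample matrices) and `n` (genes used).
#' @export
pearson_matrix <- function(m) {
  if (nrow(m) < 3L) stop("need >= 3 genes for correlation")
  v <- apply(m, 2L, var)
  if (any(v == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(m)[v == 0], collapse = ", "))
  r <- cor(m)
  n <- nrow(m)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  structure(list(r = r, p = p, n = n), class = "correlation_matrix")
}

#' Principal component analysis of samples
#'
#' Samples are observations and genes variables; columns (genes) are centered
#' but not scaled, and scores come from the singular value decomposition
#' (via [stats::prcomp()]). For reproducibility each component's sign is
#' fixed so that its largest-magnitude gene loading is positive.
#'
#' @param m Genes x samples matrix (>= 2 samples).
#' @return List of class `pca_result` with `scores` (samples x components),
#'   `loadings`, and `variance_explained` (fraction per component,
#'   non-increasing).
#' @export
pca_samples <- function(m) {
  if (ncol(m) < 2L) stop("need >= 2 samples for PCA")
  fit <- prcomp(t(m), center = TRUE, scale. = FALSE)
  flip <- apply(fit$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(fit$x, 2L, flip, "*")
  loadings <- sweep(fit$rotation, 2L, flip, "*")
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve), class = "pca_result")
}
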
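#' Assign muscle abundance rank classes
#'
#' Per muscle sample, genes are ranked by descending FPKM; ranks 1-100 form
#' `Top100`, 101-1,000 `Mid`, and the remainder `Other`. Ties are broken by
#' lexicographic gene id so the partition is deterministic. With fewer than
#' 1,000 genes the classes truncate, with a warning.
#'
#' @param muscle_expr FPKM matrix of the muscle samples only.
#' @return Character matrix (genes x samples) with entries `Top100`, `Mid`,
#'   `Other`.
#' @export
assign_rank_classes <- function(muscle_expr) {
  n <- nrow(muscle_expr)
  if (n < 1000L)
    warning("fewer than 1,000 genes retained; rank classes truncate")
  ids <- rownames(muscle_expr)
  out <- matrix(NA_character_, n, ncol(muscle_expr),
                dimnames = dimnames(muscle_expr))
  for (j in seq_len(ncol(muscle_expr))) {
    ord <- order(-muscle_expr[, j], ids)
    cls <- rep("Other", n)
    cls[ord[seq_len(min(100L, n))]] <- "Top100"
    if (n > 100L) cls[ord[101:min(1000L, n)]] <- "Mid"
    out[, j] <- cls
  }
  out
}

#' Maintained-or-increased fractions per animal and rank class
#'
#' For each muscle/M-EV pair and abundance class, the percentage of class
#' genes whose EV FPKM is greater than or equal to the paired muscle FPKM
#' (a tie counts as maintained).
#'
#' @param muscle_expr,mev_expr FPKM matrices over the same (filtered) genes;
#'   columns are muscle and M-EV sample ids respectively.
#' @param samples A [sample_sheet()] defining the pairing.
#' @param classes Rank classes from [assign_rank_classes()] (columns =
#'   muscle samples).
#' @return data.frame with `animal_id`, `class`, `n_genes`, `n_maintained`
#'   and `fraction_maintained` (percent).
#' @export
maintained_fractions <- function(muscle_expr, mev_expr, samples, classes) {
  pairs <- sample_pairs(samples, complete_only = FALSE)
  if (any(!pairs$complete))
    stop("unpaired animal(s): ",
         paste(pairs$animal_id[!pairs$complete], collapse = ", "))
  if (!identical(rownames(muscle_expr), rownames(mev_expr)))
    stop("muscle and M-EV matrices must cover the same genes")
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    ms <- pairs$muscle[i]; es <- pairs$mev[i]
    kept <- mev_expr[, es] >= muscle_expr[, ms]
    cls <- classes[, ms]
    for (cl in c("Top100", "Mid", "Other")) {
      sel <- cls == cl
      if (!any(sel)) next
      out[[length(out) + 1L]] <- data.frame(
        animal_id = pairs$animal_id[i], class = cl,
        n_genes = sum(sel), n_maintained = sum(kept[sel]),
        fraction_maintained = 100 * mean(kept[sel]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Cumulative FPKM share of the most abundant genes
#'
#' Per sample, the fraction of total FPKM contributed by the `top_n` genes
#' with the largest FPKM in that sample.
#'
#' @param expr FPKM matrix.
#' @param top_n Number of top genes (1 <= top_n <= number of genes).
#' @param samples Optional [sample_sheet()]; if given, per-compartment mean
#'   shares are attached as attribute `compartment_means`.
#' @return Named numeric vector of per-sample shares in \[0, 1\].
#' @export
cumulative_share <- function(expr, top_n, samples = NULL) {
  if (top_n < 1L) stop("top_n must be >= 1")
  if (top_n > nrow(expr))
    stop("top_n exceeds the number of genes (", nrow(expr), ")")
  shares <- apply(expr, 2L, function(x)
    sum(sort(x, decreasing = TRUE)[seq_len(top_n)]) / sum(x))
  if (!is.null(samples)) {
    sdf <- as.data.frame(samples)
    cm <- tapply(shares[sdf$sample_id], sdf$compartment, mean)
    attr(shares, "compartment_means") <- cm
  }
  shares
}

# Compact letter display: classes sharing a letter are not significantly
# different. Maximal non-significant cliques (brute force; k is small),
# ordered by descending group mean.
compact_letters <- function(groups, means, sig_pairs) {
  k <- length(groups)
  if (k > 15L) stop("compact letter display supports at most 15 groups")
  nonsig <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$class_a[i]; b <- sig_pairs$class_b[i]
    if (sig_pairs$significant[i]) nonsig[a, b] <- nonsig[b, a] <- FALSE
  }
  cliques <- list()
  for (mask in seq_len(2^k - 1L)) {
    members <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0)
    if (all(nonsig[members, members])) cliques[[length(cliques) + 1L]] <- members
  }
  maximal <- Filter(function(cl) !any(vapply(cliques, function(o)
    length(o) > length(cl) && all(cl %in% o), TRUE)), cliques)
  first_rank <- vapply(maximal, function(cl) min(match(groups[cl],
    groups[order(-means)])), 1)
  maximal <- maximal[order(first_rank)]
  letters_out <- setNames(rep("", k), groups)
  for (i in seq_along(maximal))
    letters_out[maximal[[i]]] <- paste0(letters_out[maximal[[i]]],
                                        letters[i])
  letters_out
}

#' One-way ANOVA with LSD multiple comparison
#'
#' Fits a one-way ANOVA of the per-animal maintained fractions across rank
#' classes (via [stats::aov()]) and performs Fisher's least-significant-
#' difference pairwise t tests using the pooled within-class mean square with
#' N - k degrees of freedom and unadjusted p-values. A compact letter display
#' is attached: classes sharing no letter differ at level `alpha`.
#'
#' @param summary data.frame from [maintained_fractions()] (needs columns
#'   `class` and `fraction_maintained`), or any data.frame with those
#'   columns.
#' @param alpha Significance level for the letter display.
#' @return List of class `anova_lsd` with `F`, `p_anova`, `ms_within`,
#'   `df_within`, `pairwise` (class_a, class_b, mean_diff, t, p,
#'   significant), `letters`, `group_means` and `degenerate` (TRUE when the
#'   pooled within-class variance is zero but means differ).
#' @export
anova_lsd <- function(summary, alpha = 0.05) {
  stopifnot_names(summary, c("class", "fraction_maintained"), "summary")
  y <- summary$fraction_maintained
  g <- factor(summary$class)
  sizes <- table(g)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("need >= 2 classes with >= 2 observations each")
  fit <- aov(y ~ g)
  # a zero-residual fit is flagged as degenerate below; silence the
  # corresponding stats warning
  tab <- suppressWarnings(anova(fit))
  msw <- tab["Residuals", "Mean Sq"]
  dfw <- tab["Residuals", "Df"]
  means <- tapply(y, g, mean)
  degenerate <- msw <= 1e-12 && var(means) > 0
  Fstat <- if (degenerate) Inf else tab["g", "F value"]
  p_anova <- if (degenerate) 0 else tab["g", "Pr(>F)"]

  combs <- combn(levels(g), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1L, i]; b <- combs[2L, i]
    d <- means[[a]] - means[[b]]
    se <- sqrt(msw * (1 / sizes[[a]] + 1 / sizes[[b]]))
    tval <- if (se > 0) d / se else ifelse(d == 0, 0, Inf * sign(d))
    pval <- if (se > 0) 2 * pt(abs(tval), dfw, lower.tail = FALSE)
            else ifelse(d == 0, 1, 0)
    data.frame(class_a = a, class_b = b, mean_diff = d, t = tval, p = pval,
               stringsAsFactors = FALSE)
  }))
  pw$significant <- pw$p <= alpha
  lett <- compact_letters(levels(g), means[levels(g)], pw)
  structure(list(F = Fstat, p_anova = p_anova, ms_within = msw,
                 df_within = dfw, pairwise = pw, letters = lett,
                 group_means = means, degenerate = degenerate,
                 alpha = alpha),
            class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F = %.4g, p = %.3g%s\n", x$F, x$p_anova,
              if (x$degenerate) " (degenerate: zero within-class variance)"
              else ""))
  disp <- data.frame(mean = round(x$group_means, 3),
                     letter = x$letters[names(x$group_means)])
  print(disp)
  invisible(x)
}
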
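#' Hypergeometric over-representation test for one gene set
#'
#' Upper-tail hypergeometric probability of observing at least `k` query
#' genes in a pathway: p = P\[X >= k\] with X ~ Hypergeometric(N, K, n),
#' where N is the universe size, K the pathway size within the universe and
#' n the query size within the universe. Query genes outside the universe
#' are dropped with a warning; the pathway is intersected with the universe.
#'
#' @param query Character vector of query gene ids (e.g. a MEG catalog).
#' @param pathway Character vector of pathway member ids.
#' @param universe Character vector of background gene ids.
#' @return List with `k`, `K`, `n`, `N`, `p` and `enrich_ratio` (= k / K).
#' @export
ora_test <- function(query, pathway, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  out <- setdiff(query, universe)
  if (length(out)) {
    warning(length(out), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  pathway <- intersect(unique(pathway), universe)
  N <- length(universe); K <- length(pathway); n <- length(query)
  k <- length(intersect(query, pathway))
  p <- if (k == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = p,
       enrich_ratio = if (K > 0L) k / K else NA_real_)
}

#' Over-representation of a MEG catalog against a gene-set collection
#'
#' One hypergeometric test per pathway, sorted by p. Significance follows
#' the raw-p criterion (p <= `alpha`); BH-adjusted p-values are reported
#' alongside.
#'
#' @param catalog A `meg_catalog` (or plain character vector of genes).
#' @param sets A `gene_set_collection` from [read_gene_sets()].
#' @param universe Background gene ids (typically the genes tested in the
#'   corresponding differential analysis).
#' @param alpha Raw-p significance threshold.
#' @return data.frame of class `ora_result` with one row per pathway:
#'   `pathway_id`, `k`, `K`, `n`, `N`, `enrich_ratio`, `p`, `padj`,
#'   `significant`; sorted by `p`.
#' @export
enrich_all <- function(catalog, sets, universe, alpha = 0.05) {
  query <- if (inherits(catalog, "meg_catalog")) catalog$genes else catalog
  query <- intersect(unique(query), universe)
  rows <- lapply(names(sets), function(id) {
    t <- suppressWarnings(ora_test(query, sets[[id]], universe))
    data.frame(pathway_id = id, k = t$k, K = t$K, n = t$n, N = t$N,
               enrich_ratio = t$enrich_ratio, p = t$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$padj <- bh_adjust(res$p)
  res$significant <- res$p <= alpha
  res <- res[order(res$p, res$pathway_id), ]
  rownames(res) <- NULL
  structure(res, alpha = alpha, class = c("ora_result", "data.frame"))
}

#' Compare significant pathway sets across two strata
#'
#' @param res_a,res_b `ora_result` tables over the same gene-set collection.
#' @param alpha Raw-p significance threshold (defaults to the tables' own).
#' @return List with `unique_a`, `unique_b`, `shared` (pathway id vectors)
#'   and `counts`.
#' @export
compare_pathway_sets <- function(res_a, res_b,
                                 alpha = attr(res_a, "alpha") %||% 0.05) {
  if (!setequal(res_a$pathway_id, res_b$pathway_id))
    stop("results cover different gene-set collections")
  sig_a <- res_a$pathway_id[res_a$p <= alpha]
  sig_b <- res_b$pathway_id[res_b$p <= alpha]
  out <- list(unique_a = setdiff(sig_a, sig_b),
              unique_b = setdiff(sig_b, sig_a),
              shared = intersect(sig_a, sig_b))
  out$counts <- vapply(out, length, 1L)
  out
}
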
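#' Gene annotation with 5'UTR / CDS / 3'UTR region models
#'
#' Constructs a validated gene annotation from a feature table. Intervals are
#' 1-based and closed (GTF convention). Per gene and region the length is the
#' width of the union of that region's intervals; the gene length is the width
#' of the union of all intervals. Regions of a gene must not overlap each
#' other: an annotation whose region unions overlap is rejected as malformed.
#'
#' @param features data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `region` (one of `utr5`, `cds`, `utr3`), `start`, `end`.
#' @return An object of class `gene_annotation`: a list with `features` (the
#'   validated table) and `genes` (per-gene table with `utr5_length`,
#'   `cds_length`, `utr3_length` and `gene_length` in bp).
#' @export
gene_annotation <- function(features) {
  if (nrow(features) == 0L) {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), utr5_length = numeric(),
                        cds_length = numeric(), utr3_length = numeric(),
                        gene_length = numeric(), stringsAsFactors = FALSE)
    return(structure(list(features = features, genes = genes),
                     class = "gene_annotation"))
  }
  stopifnot_names(features, c("gene_id", "chrom", "strand", "region",
                              "start", "end"), "annotation feature table")
  bad <- which(features$start > features$end)
  if (length(bad))
    stop(sprintf("malformed coordinates (start > end) in feature row(s): %s",
                 paste(head(bad, 5L), collapse = ", ")))
  if (any(!features$region %in% REGIONS))
    stop("region must be one of: ", paste(REGIONS, collapse = ", "))

  meta <- unique(features[, c("gene_id", "chrom", "strand")])
  if (anyDuplicated(meta$gene_id))
    stop("duplicate conflicting gene records (same gene_id on different ",
         "chrom/strand): ",
         paste(unique(meta$gene_id[duplicated(meta$gene_id)]), collapse = ", "))

  gid <- factor(features$gene_id, levels = meta$gene_id)
  # union length per gene x region via IRanges::reduce
  region_len <- matrix(0, nrow = nrow(meta), ncol = 3L,
                       dimnames = list(meta$gene_id, REGIONS))
  for (r in REGIONS) {
    sel <- features$region == r
    if (!any(sel)) next
    ir <- IRanges::IRanges(start = features$start[sel], end = features$end[sel])
    byg <- S4Vectors::split(ir, gid[sel], drop = FALSE)
    region_len[, r] <- sum(IRanges::width(IRanges::reduce(byg)))
  }
  all_ir <- IRanges::IRanges(start = features$start, end = features$end)
  gene_len <- sum(IRanges::width(IRanges::reduce(S4Vectors::split(all_ir, gid,
                                                                  drop = FALSE))))
  over <- which(gene_len < rowSums(region_len) - 1e-9)
  if (length(over))
    stop("overlapping region unions (malformed annotation) for gene(s): ",
         paste(head(meta$gene_id[over], 5L), collapse = ", "))
  if (any(gene_len <= 0))
    stop("gene with non-positive total length: ",
         paste(head(meta$gene_id[gene_len <= 0], 5L), collapse = ", "))

  genes <- data.frame(meta,
                      utr5_length = region_len[, "utr5"],
                      cds_length = region_len[, "cds"],
                      utr3_length = region_len[, "utr3"],
                      gene_length = as.numeric(gene_len),
                      stringsAsFactors = FALSE, row.names = meta$gene_id)
  structure(list(features = features, genes = genes),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d region features\n",
              nrow(x$genes), nrow(x$features)))
  invisible(x)
}

default_feature_map <- c(utr5 = "five_prime_utr", cds = "CDS",
                         utr3 = "three_prime_utr")

#' Read a gene annotation from GTF
#'
#' Imports a GTF file (via \pkg{rtracklayer}) and keeps the three mRNA region
#' feature types. Feature-type names are configurable because GTF dialects
#' differ (`five_prime_utr` vs `5UTR` etc.). Genes lacking a region type keep
#' that region length at 0.
#'
#' @param path Path to a GTF file.
#' @param feature_map Named character vector mapping internal region names
#'   (`utr5`, `cds`, `utr3`) to the GTF `type` values that encode them.
#' @return A [gene_annotation()] object.
#' @export
read_annotation <- function(path, feature_map = default_feature_map) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(grepl("^#", lines) | !nzchar(lines))) {
    return(gene_annotation(data.frame(gene_id = character(),
                                      chrom = character(),
                                      strand = character(),
                                      region = character(),
                                      start = integer(), end = integer())))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e)
                   stop("GTF parse error in ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  type <- as.character(gr$type)
  keep <- type %in% feature_map
  gr <- gr[keep]
  type <- type[keep]
  inv <- setNames(names(feature_map), feature_map)
  if (is.null(gr$gene_id))
    stop("GTF has no gene_id attribute on region features")
  features <- data.frame(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    region = unname(inv[type]),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  gene_annotation(features)
}

#' Write a gene annotation to GTF
#'
#' @param ann A [gene_annotation()] object.
#' @param path Output GTF path.
#' @param feature_map As in [read_annotation()].
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(ann, path, feature_map = default_feature_map) {
  stopifnot(inherits(ann, "gene_annotation"))
  f <- ann$features
  if (nrow(f) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  # Deterministic plain GTF emission (attribute column: gene_id only).
  lines <- sprintf('%s\tevcargo\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   f$chrom, unname(feature_map[f$region]),
                   as.integer(f$start), as.integer(f$end), f$strand, f$gene_id)
  writeLines(lines, path)
  invisible(path)
}

validate_count_matrix <- function(m, what = "count matrix") {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must have gene and sample names")
  if (anyDuplicated(rownames(m)))
    stop("duplicated gene_id in ", what, ": ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (!is.numeric(m)) stop(what, " has non-numeric cells")
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("%s has non-integer or negative cell at gene '%s', sample '%s'",
                 what, rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  storage.mode(m) <- "double"
  m
}

#' Read a gene-level count matrix from TSV
#'
#' Expects a header row of sample ids, a first column `gene_id`, and
#' non-negative integer cells.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix (genes x samples) of integer-valued counts.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("count matrix file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(df) >= 2L || names(df)[1L] != "gene_id")
    stop("count matrix must have a first column 'gene_id' and >= 1 sample")
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (is.character(m)) {
    suppressWarnings(mn <- matrix(as.numeric(m), nrow = nrow(m),
                                  dimnames = dimnames(m)))
    if (anyNA(mn) && !anyNA(m)) {
      bad <- which(is.na(mn), arr.ind = TRUE)[1L, ]
      stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                   genes[bad[1L]], colnames(m)[bad[2L]]))
    }
    m <- mn
  }
  rownames(m) <- genes
  validate_count_matrix(m)
}

#' Write a gene-level count matrix to TSV
#'
#' @param counts Matrix (genes x samples).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Region-resolved count container
#'
#' Bundles three genes-x-samples count matrices, one per mRNA region
#' (5'UTR, CDS, 3'UTR), with identical dimnames.
#'
#' @param utr5,cds,utr3 Count matrices with identical dimnames.
#' @return Object of class `region_counts` (a named list of the three
#'   matrices).
#' @export
region_counts <- function(utr5, cds, utr3) {
  mats <- list(utr5 = utr5, cds = cds, utr3 = utr3)
  dn <- dimnames(utr5)
  for (r in REGIONS) {
    mats[[r]] <- validate_count_matrix(mats[[r]], paste0(r, " counts"))
    if (!identical(dimnames(mats[[r]]), dn))
      stop("region count matrices must share identical gene/sample names")
  }
  structure(mats, class = "region_counts")
}

#' @export
print.region_counts <- function(x, ...) {
  cat(sprintf("region_counts: %d genes x %d samples x 3 regions\n",
              nrow(x$cds), ncol(x$cds)))
  invisible(x)
}

#' Sum of the three region count matrices
#'
#' @param rc A [region_counts()] object.
#' @return Matrix of per-gene, per-sample totals over the three regions.
#' @export
region_totals <- function(rc) {
  stopifnot(inherits(rc, "region_counts"))
  rc$utr5 + rc$cds + rc$utr3
}

#' Read region-level counts from long-format TSV
#'
#' Columns: `gene_id`, `region` (`utr5`/`cds`/`utr3`), `sample_id`, `count`.
#' Missing (gene, region, sample) combinations are taken as 0.
#'
#' @param path Path to a TSV file.
#' @return A [region_counts()] object.
#' @export
read_region_counts <- function(path) {
  if (!file.exists(path)) stop("region counts file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot_names(df, c("gene_id", "region", "sample_id", "count"),
                  "region counts table")
  if (any(!df$region %in% REGIONS))
    stop("unknown region token(s): ",
         paste(unique(setdiff(df$region, REGIONS)), collapse = ", "))
  genes <- unique(df$gene_id)
  samples <- unique(df$sample_id)
  mats <- lapply(REGIONS, function(r) {
    m <- matrix(0, length(genes), length(samples),
                dimnames = list(genes, samples))
    sub <- df[df$region == r, ]
    m[cbind(match(sub$gene_id, genes), match(sub$sample_id, samples))] <-
      sub$count
    m
  })
  names(mats) <- REGIONS
  region_counts(mats$utr5, mats$cds, mats$utr3)
}

#' Write region-level counts to long-format TSV
#'
#' @param rc A [region_counts()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_region_counts <- function(rc, path) {
  stopifnot(inherits(rc, "region_counts"))
  genes <- rownames(rc$cds); samples <- colnames(rc$cds)
  df <- do.call(rbind, lapply(REGIONS, function(r) {
    data.frame(gene_id = rep(genes, times = length(samples)),
               region = r,
               sample_id = rep(samples, each = length(genes)),
               count = as.vector(rc[[r]]), stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Sample sheet for paired tissue / vesicle designs
#'
#' Validates sample metadata and derives the animal-level muscle/M-EV pairing.
#'
#' @param df data.frame with columns `sample_id`, `animal_id`, `breed`,
#'   `sex` (`M`/`F`), `compartment` (`muscle`/`MEV`).
#' @param breeds Allowed breed tokens.
#' @return `df` with class `sample_sheet` and an attribute `pairs`: a
#'   data.frame (`animal_id`, `muscle`, `mev`, `complete`). Incomplete pairs
#'   trigger a warning.
#' @export
sample_sheet <- function(df, breeds = c("LargeWhite", "WildBoar")) {
  stopifnot_names(df, c("sample_id", "animal_id", "breed", "sex",
                        "compartment"), "sample sheet")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (any(!df$compartment %in% c("muscle", "MEV")))
    stop("unknown compartment token(s): ",
         paste(unique(setdiff(df$compartment, c("muscle", "MEV"))),
               collapse = ", "))
  if (any(!df$breed %in% breeds))
    stop("unknown breed token(s): ",
         paste(unique(setdiff(df$breed, breeds)), collapse = ", "))
  if (any(!df$sex %in% c("M", "F")))
    stop("unknown sex token(s): ",
         paste(unique(setdiff(df$sex, c("M", "F"))), collapse = ", "))
  tab <- table(df$animal_id, df$compartment)
  if (any(tab > 1L)) {
    bad <- rownames(tab)[apply(tab > 1L, 1L, any)]
    stop("animal with more than one sample per compartment: ",
         paste(bad, collapse = ", "))
  }
  animals <- unique(df$animal_id)
  pick <- function(a, comp) {
    s <- df$sample_id[df$animal_id == a & df$compartment == comp]
    if (length(s)) s else NA_character_
  }
  pairs <- data.frame(animal_id = animals,
                      muscle = vapply(animals, pick, "", comp = "muscle"),
                      mev = vapply(animals, pick, "", comp = "MEV"),
                      stringsAsFactors = FALSE, row.names = NULL)
  pairs$complete <- !is.na(pairs$muscle) & !is.na(pairs$mev)
  if (any(!pairs$complete))
    warning("incomplete muscle/M-EV pair(s) for animal(s): ",
            paste(pairs$animal_id[!pairs$complete], collapse = ", "))
  structure(df, pairs = pairs, class = c("sample_sheet", "data.frame"))
}

#' Read a sample sheet from TSV
#'
#' @param path Path to a TSV file with columns `sample_id`, `animal_id`,
#'   `breed`, `sex`, `compartment`.
#' @inheritParams sample_sheet
#' @return A [sample_sheet()] object.
#' @export
read_sample_sheet <- function(path, breeds = c("LargeWhite", "WildBoar")) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sample_sheet(read.delim(path, stringsAsFactors = FALSE), breeds = breeds)
}

#' Write a sample sheet to TSV
#'
#' @param samples A [sample_sheet()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(as.data.frame(samples), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Muscle/M-EV pairing table of a sample sheet
#'
#' @param samples A [sample_sheet()] object.
#' @param complete_only Drop incomplete pairs?
#' @return data.frame with `animal_id`, `muscle`, `mev`, `complete`.
#' @export
sample_pairs <- function(samples, complete_only = TRUE) {
  p <- attr(samples, "pairs")
  if (is.null(p)) stop("not a sample_sheet object")
  if (complete_only) p[p$complete, , drop = FALSE] else p
}

#' Read gene sets from GMT
#'
#' Standard GMT dialect: one set per line — name, description, then member
#' gene ids, all tab-separated. Members are de-duplicated.
#'
#' @param path Path to a GMT file.
#' @return Object of class `gene_set_collection`: a named list of character
#'   vectors with a `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    id <- fields[1L]
    if (id %in% names(sets)) stop("duplicate pathway id: ", id)
    sets[[id]] <- unique(fields[-(1:2)])
    desc[id] <- fields[2L]
  }
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' Write gene sets to GMT
#'
#' @param sets A `gene_set_collection` (or plain named list of gene id
#'   vectors).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]] %||% id, sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a qPCR CT table from TSV
#'
#' Columns: `sample_id`, `gene_id`, `ct` (threshold cycles, finite reals).
#'
#' @param path Path to a TSV file.
#' @return data.frame of class `qpcr_table`.
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) stop("qPCR table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot_names(df, c("sample_id", "gene_id", "ct"), "qPCR table")
  if (!is.numeric(df$ct) || any(!is.finite(df$ct)))
    stop("qPCR CT values must be finite numbers")
  structure(df, class = c("qpcr_table", "data.frame"))
}

#' Write a qPCR CT table to TSV
#'
#' @param qpcr A `qpcr_table` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qpcr <- function(qpcr, path) {
  write.table(as.data.frame(qpcr), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
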
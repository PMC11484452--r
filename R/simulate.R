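#' Configuration for the paired muscle / M-EV simulator
#'
#' Builds a validated simulation configuration. The defaults are the
#' calibrated benchmark scenario (see [default_scenario()]): 2 breeds x 2
#' animals, 12,000 genes, heavy-tailed muscle expression in which the 1,000
#' most abundant genes carry 90.94% of total FPKM, rank-dependent
#' maintained-or-increased transfer into vesicles of 20% / 25% / 60% for the
#' Top100 / Mid (ranks 101-1,000) / Other abundance classes, an EV top-1,000
#' share of 73.99%, and planted vesicle-enriched gene (MEG) sets with shared
#' and breed-specific components drawn from the Other class.
#'
#' @param n_genes Number of genes (> 1,000).
#' @param n_animals_per_breed Animals per breed; each animal contributes one
#'   muscle and one M-EV sample.
#' @param breeds Breed labels.
#' @param seed Master seed; all generator stages derive their streams from it.
#' @param top1000_share_muscle Fraction of total muscle FPKM carried by the
#'   1,000 most abundant genes (exact in the base profile).
#' @param top1000_share_mev Target fraction of total EV FPKM carried by the
#'   EV top-1,000 genes; hit by calibrating the depletion depth of
#'   non-maintained high-abundance genes (tolerance 0.02).
#' @param maintain_prob Named probabilities (`Top100`, `Mid`, `Other`) that a
#'   gene of that muscle abundance class keeps or increases its expression in
#'   the paired EV sample.
#' @param muscle_library_size,mev_library_size Expected sequenced fragments
#'   per sample.
#' @param dispersion Negative-binomial dispersion alpha (variance =
#'   mu + alpha mu^2), shared across genes in the generator.
#' @param region_props_muscle,region_props_mev Baseline tag allocation over
#'   (`utr5`, `cds`, `utr3`); per gene these are re-weighted by region
#'   lengths.
#' @param n_meg_shared Planted MEGs enriched in both breeds.
#' @param n_meg_breed_specific Planted MEGs enriched in one breed only (per
#'   breed).
#' @param meg_log2fc_min Minimum true log2 EV/muscle ratio of an active
#'   planted MEG (>= 1).
#' @param fraction_missing_region_mev Probability that an EV gene-sample has
#'   one UTR region's reads forced to zero (truncated cargo).
#' @param qpcr_noise_sd Gaussian CT noise, cycles.
#' @param head_decay,tail_decay Geometric decay ratios of the top-1,000 block
#'   and the remainder of the base abundance profile. The absolute FPKM
#'   scale is fixed by the FPKM identity (sum of FPKM x gene length in kb
#'   equals 10^6), so planted values live on the same scale the pipeline
#'   recovers from counts.
#' @param jitter_sdlog Per-animal lognormal jitter (sd on the log scale) of
#'   muscle expression around the base profile.
#' @param breed_sdlog Per-gene lognormal breed effect (sd on the log scale)
#'   on muscle expression: the two breeds differ in their muscle
#'   transcriptomes, which gives validation panels cross-animal dynamic
#'   range; the effect is inherited by the vesicle profile and so cancels in
#'   EV/muscle transfer ratios.
#' @param maintained_log2_min,maintained_log2_max Maintained genes draw log2
#'   transfer factors uniformly from \[`maintained_log2_min`,
#'   `maintained_log2_max`\]; the lower bound keeps maintained genes
#'   detectably above the muscle level under count noise.
#' @param depleted_log2_other Non-maintained Other-class genes draw log2
#'   factors uniformly from \[-`depleted_log2_other`, 0).
#' @param utr5_meanlog,cds_meanlog,utr3_meanlog,region_sdlog,min_region_len
#'   Lognormal region-length parameters (bp) for the simulated annotation.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 12000L,
                       n_animals_per_breed = 2L,
                       breeds = c("LargeWhite", "WildBoar"),
                       seed = 20241003L,
                       top1000_share_muscle = 0.9094,
                       top1000_share_mev = 0.7399,
                       maintain_prob = c(Top100 = 0.20, Mid = 0.25,
                                         Other = 0.60),
                       muscle_library_size = 4e7,
                       mev_library_size = 5.2e7,
                       dispersion = 0.02,
                       region_props_muscle = c(utr5 = 0.20, cds = 0.45,
                                               utr3 = 0.35),
                       region_props_mev = c(utr5 = 0.35, cds = 0.20,
                                            utr3 = 0.45),
                       n_meg_shared = 1600L,
                       n_meg_breed_specific = 400L,
                       meg_log2fc_min = 2,
                       fraction_missing_region_mev = 0.3,
                       qpcr_noise_sd = 0.25,
                       head_decay = 0.997,
                       tail_decay = 0.99981,
                       jitter_sdlog = 0.1,
                       breed_sdlog = 0.4,
                       maintained_log2_min = 0.15,
                       maintained_log2_max = 1,
                       depleted_log2_other = 1,
                       utr5_meanlog = log(170),
                       cds_meanlog = log(1300),
                       utr3_meanlog = log(500),
                       region_sdlog = 0.45,
                       min_region_len = 30L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_animals_per_breed = as.integer(n_animals_per_breed),
              breeds = breeds, seed = as.integer(seed),
              top1000_share_muscle = top1000_share_muscle,
              top1000_share_mev = top1000_share_mev,
              maintain_prob = maintain_prob,
              muscle_library_size = muscle_library_size,
              mev_library_size = mev_library_size,
              dispersion = dispersion,
              region_props_muscle = region_props_muscle,
              region_props_mev = region_props_mev,
              n_meg_shared = as.integer(n_meg_shared),
              n_meg_breed_specific = as.integer(n_meg_breed_specific),
              meg_log2fc_min = meg_log2fc_min,
              fraction_missing_region_mev = fraction_missing_region_mev,
              qpcr_noise_sd = qpcr_noise_sd,
              head_decay = head_decay, tail_decay = tail_decay,
              jitter_sdlog = jitter_sdlog,
              breed_sdlog = breed_sdlog,
              maintained_log2_min = maintained_log2_min,
              maintained_log2_max = maintained_log2_max,
              depleted_log2_other = depleted_log2_other,
              utr5_meanlog = utr5_meanlog, cds_meanlog = cds_meanlog,
              utr3_meanlog = utr3_meanlog, region_sdlog = region_sdlog,
              min_region_len = as.integer(min_region_len))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes <= 1000L)
    stop("n_genes must exceed 1,000 (rank classes need a populated tail)")
  if (any(cfg$maintain_prob < 0 | cfg$maintain_prob > 1))
    stop("maintain_prob entries must lie in [0, 1]")
  if (!setequal(names(cfg$maintain_prob), c("Top100", "Mid", "Other")))
    stop("maintain_prob must be named Top100, Mid, Other")
  for (s in c("top1000_share_muscle", "top1000_share_mev"))
    if (cfg[[s]] <= 0 || cfg[[s]] >= 1) stop(s, " must lie in (0, 1)")
  for (p in c("region_props_muscle", "region_props_mev")) {
    v <- cfg[[p]]
    if (!setequal(names(v), REGIONS)) stop(p, " must be named utr5, cds, utr3")
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9) stop(p, " must sum to 1")
  }
  if (cfg$meg_log2fc_min < 1) stop("meg_log2fc_min must be >= 1")
  if (cfg$maintained_log2_min < 0 ||
      cfg$maintained_log2_min >= cfg$maintained_log2_max)
    stop("need 0 <= maintained_log2_min < maintained_log2_max")
  if (cfg$fraction_missing_region_mev < 0 ||
      cfg$fraction_missing_region_mev > 1)
    stop("fraction_missing_region_mev must lie in [0, 1]")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  invisible(cfg)
}

#' Default calibrated benchmark scenario
#'
#' Returns the simulator configuration used throughout the package's
#' benchmark and recovery studies: 2 breeds x 2 animals, 12,000 genes,
#' muscle top-1,000 FPKM share 90.94%, EV top-1,000 share 73.99%,
#' maintained-or-increased probabilities (20%, 25%, 60%) for the
#' (Top100, Mid, Other) abundance classes, and 2,400 planted MEGs
#' (1,600 shared + 400 per breed) with true EV/muscle fold >= 4.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config` object.
#' @export
default_scenario <- function(...) sim_config(...)

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: %d genes, %d breeds x %d animals, seed %d\n",
    "  top-1000 FPKM share: muscle %.4f, M-EV %.4f\n",
    "  maintain prob (Top100/Mid/Other): %.2f / %.2f / %.2f\n",
    "  planted MEGs: %d shared + %d per breed, log2FC >= %g\n"),
    x$n_genes, length(x$breeds), x$n_animals_per_breed, x$seed,
    x$top1000_share_muscle, x$top1000_share_mev,
    x$maintain_prob[["Top100"]], x$maintain_prob[["Mid"]],
    x$maintain_prob[["Other"]], x$n_meg_shared, x$n_meg_breed_specific,
    x$meg_log2fc_min))
  invisible(x)
}

sim_gene_ids <- function(n) sprintf("G%05d", seq_len(n))

breed_code <- function(breed) {
  known <- c(LargeWhite = "LW", WildBoar = "WB")
  ifelse(breed %in% names(known), known[breed],
         toupper(substr(breed, 1L, 2L)))
}

sim_animals <- function(cfg) {
  sexes <- rep_len(c("F", "M"), cfg$n_animals_per_breed)
  do.call(rbind, lapply(cfg$breeds, function(b) {
    idx <- seq_len(cfg$n_animals_per_breed)
    data.frame(animal_id = paste0(breed_code(b), sprintf("%02d", idx),
                                  sexes),
               breed = b, sex = sexes, stringsAsFactors = FALSE)
  }))
}

#' Simulate a gene annotation
#'
#' Draws one 5'UTR, CDS and 3'UTR interval per gene with lognormal lengths
#' and lays genes out consecutively along 18 autosomes. Deterministic given
#' the configuration seed.
#'
#' @param cfg A [sim_config()].
#' @return A [gene_annotation()] object with `n_genes` genes.
#' @export
simulate_annotation <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    ids <- sim_gene_ids(n)
    draw <- function(meanlog) pmax(cfg$min_region_len,
                                   round(rlnorm(n, meanlog, cfg$region_sdlog)))
    l5 <- draw(cfg$utr5_meanlog)
    lc <- draw(cfg$cds_meanlog)
    l3 <- draw(cfg$utr3_meanlog)
    chrom <- paste0("chr", 1L + (seq_len(n) - 1L) %% 18L)
    strand <- rep_len(c("+", "-"), n)
    # consecutive layout per chromosome with a fixed intergenic gap
    glen <- l5 + lc + l3
    start <- integer(n)
    offset <- integer(18L); names(offset) <- paste0("chr", 1:18)
    for (i in seq_len(n)) {
      start[i] <- offset[chrom[i]] + 1L
      offset[chrom[i]] <- offset[chrom[i]] + glen[i] + 1000L
    }
    features <- data.frame(
      gene_id = rep(ids, each = 3L),
      chrom = rep(chrom, each = 3L),
      strand = rep(strand, each = 3L),
      region = rep(c("utr5", "cds", "utr3"), times = n),
      start = as.integer(rbind(start, start + l5, start + l5 + lc)),
      end = as.integer(rbind(start + l5 - 1L, start + l5 + lc - 1L,
                             start + glen - 1L)),
      stringsAsFactors = FALSE)
    gene_annotation(features)
  })
}

#' Plant expression truth for a paired muscle / M-EV dataset
#'
#' Constructs the generator's ground truth in three steps. (1) A base muscle
#' abundance profile: two geometric-decay blocks scaled so the top-1,000
#' genes carry exactly `top1000_share_muscle` of total FPKM, then per-animal
#' lognormal jitter. (2) Per gene and animal a maintained-or-increased flag
#' drawn with the gene's abundance-class probability; maintained genes draw a
#' transfer factor (EV/muscle FPKM ratio) >= 1, others < 1. Planted MEGs are
#' drawn from the Other class and forced to factors >= `2^meg_log2fc_min` in
#' their active breed(s); the Bernoulli rate of the remaining Other genes is
#' adjusted so the class-wise maintained fraction still matches
#' `maintain_prob`. (3) The depletion depth of non-maintained Top100/Mid
#' genes is calibrated by bisection so the expected EV top-1,000 FPKM share
#' matches `top1000_share_mev` (within 0.02, typically to 0.001).
#'
#' @param cfg A [sim_config()].
#' @param annotation Matching [gene_annotation()] (only its gene set is
#'   used here).
#' @return Object of class `sim_truth`: base profile, per-animal true
#'   muscle/EV FPKM, transfer factors, maintained flags, true abundance
#'   classes, planted MEG sets, animal table and the calibrated depletion
#'   depth.
#' @export
simulate_expression <- function(cfg, annotation) {
  validate_sim_config(cfg)
  ids <- rownames(annotation$genes)
  n <- length(ids)
  if (n != cfg$n_genes)
    stop("annotation gene count does not match cfg$n_genes")
  with_seed(cfg$seed + 1L, {
    ## (1) base abundance profile: exact share calibration, no randomness;
    ## the absolute scale satisfies the FPKM identity
    ## sum(FPKM * length_kb) = 1e6, so planted FPKM is on the scale the
    ## pipeline recovers from counts
    len_kb <- annotation$genes[ids, "gene_length"] / 1e3
    n_head <- 1000L
    n_tail <- n - n_head
    head_raw <- cfg$head_decay^(seq_len(n_head) - 1L)
    tail_raw <- cfg$tail_decay^(seq_len(n_tail) - 1L)
    head_f <- cfg$top1000_share_muscle * head_raw / sum(head_raw)
    tail_f <- (1 - cfg$top1000_share_muscle) * tail_raw / sum(tail_raw)
    if (tail_f[1L] >= head_f[n_head])
      stop("infeasible calibration: tail abundance overlaps the top-1,000 ",
           "block; decrease tail_decay or head_decay")
    base_fpkm <- setNames(c(head_f, tail_f), ids)
    base_fpkm <- base_fpkm * 1e6 / sum(base_fpkm * len_kb)
    class_true <- setNames(rep("Other", n), ids)
    class_true[1:100] <- "Top100"
    class_true[101:1000] <- "Mid"

    animals <- sim_animals(cfg)
    n_a <- nrow(animals)

    ## planted MEG sets: drawn from the lower half (by base abundance) of
    ## the Other class — enrichment is strongest for the least expressed
    ## muscle transcripts
    other_ids <- ids[class_true == "Other"]
    low_other <- other_ids[seq.int(ceiling(length(other_ids) / 2) + 1L,
                                   length(other_ids))]
    n_meg <- cfg$n_meg_shared + cfg$n_meg_breed_specific * length(cfg$breeds)
    if (n_meg > length(low_other))
      stop("infeasible calibration: more planted MEGs than low-abundance ",
           "Other-class genes")
    meg_pool <- sample(low_other, n_meg)
    meg_shared <- meg_pool[seq_len(cfg$n_meg_shared)]
    rest <- meg_pool[-seq_len(cfg$n_meg_shared)]
    meg_specific <- split(rest, rep(cfg$breeds,
                                    each = cfg$n_meg_breed_specific))

    ## (2) maintained flags and transfer factors per gene x animal
    breed_eff <- matrix(rlnorm(n * length(cfg$breeds),
                               meanlog = -cfg$breed_sdlog^2 / 2,
                               sdlog = cfg$breed_sdlog),
                        n, length(cfg$breeds),
                        dimnames = list(ids, cfg$breeds))
    jit <- matrix(rlnorm(n * n_a, meanlog = -cfg$jitter_sdlog^2 / 2,
                         sdlog = cfg$jitter_sdlog), n, n_a)
    muscle_fpkm <- base_fpkm * breed_eff[, animals$breed] * jit
    dimnames(muscle_fpkm) <- list(ids, animals$animal_id)

    p <- cfg$maintain_prob
    maintained <- matrix(FALSE, n, n_a, dimnames = dimnames(muscle_fpkm))
    active_meg <- matrix(FALSE, n, n_a, dimnames = dimnames(muscle_fpkm))
    for (a in seq_len(n_a)) {
      b <- animals$breed[a]
      active <- c(meg_shared, meg_specific[[b]])
      n_other <- length(other_ids)
      p_adj <- (p[["Other"]] * n_other - length(active)) /
        (n_other - length(active))
      if (p_adj < 0 || p_adj > 1)
        stop("infeasible calibration: planted MEG count exceeds the Other-",
             "class maintained budget implied by maintain_prob['Other']")
      m <- logical(n)
      m[class_true == "Top100"] <- runif(100L) < p[["Top100"]]
      m[class_true == "Mid"] <- runif(900L) < p[["Mid"]]
      ord_other <- ids %in% setdiff(other_ids, active)
      m[ord_other] <- runif(sum(ord_other)) < p_adj
      m[ids %in% active] <- TRUE
      maintained[, a] <- m
      active_meg[ids %in% active, a] <- TRUE
    }

    ## factor building blocks (u held fixed during depth calibration);
    ## depleted head genes use u bounded away from 0 so their factors sink
    ## uniformly as the depth grows (abundant transcripts are at least
    ## modestly depleted when not maintained)
    u_head <- matrix(runif(n * n_a, min = 1 / 3, max = 1), n, n_a)
    u_oth <- matrix(runif(n * n_a, min = 1e-9, max = 1), n, n_a)
    v_up <- matrix(runif(n * n_a, cfg$maintained_log2_min,
                         cfg$maintained_log2_max), n, n_a)
    w_meg <- matrix(runif(n * n_a, 0, 1), n, n_a)
    head_gene <- class_true %in% c("Top100", "Mid")

    ## FPKM is compositional: the observed EV/muscle FPKM ratio of a gene is
    ## its transfer factor times the ratio of length-weighted FPKM totals of
    ## the two compartments. Planted maintained flags are therefore only
    ## recoverable if the factors conserve that total per animal. The mass
    ## released by depleting non-maintained abundant genes is absorbed by
    ## the planted MEGs: per animal, a deterministic boost (>= 1) of MEG
    ## factors closes the balance in closed form.
    build_factors <- function(depth) {
      f <- 2^v_up                                  # maintained: >= 1
      f[active_meg] <- 2^(cfg$meg_log2fc_min + w_meg[active_meg])
      dep <- !maintained
      f[dep & head_gene] <- 2^(-depth * u_head[dep & head_gene])
      f[dep & !head_gene] <- 2^(-cfg$depleted_log2_other *
                                  u_oth[dep & !head_gene])
      w <- muscle_fpkm * len_kb
      boost <- numeric(n_a)
      for (a in seq_len(n_a)) {
        meg <- active_meg[, a]
        s_tot <- sum(w[, a])
        s_non <- sum(w[!meg, a] * f[!meg, a])
        s_meg <- sum(w[meg, a] * f[meg, a])
        boost[a] <- (s_tot - s_non) / s_meg
        if (is.finite(boost[a]) && boost[a] >= 1)
          f[meg, a] <- f[meg, a] * boost[a]
      }
      list(f = f, boost = boost)
    }
    ev_share <- function(depth) {
      b <- build_factors(depth)
      if (any(!is.finite(b$boost) | b$boost < 1)) return(Inf)
      ev <- muscle_fpkm * b$f
      mean(apply(ev, 2L, function(x)
        sum(sort(x, decreasing = TRUE)[seq_len(1000L)]) / sum(x)))
    }

    ## (3) bisection on the head depletion depth; shallow depths that cannot
    ## fund the MEG boost (balance < 1) read as share = Inf, so the search
    ## moves deeper. When nothing can be depleted or rebalanced (degenerate
    ## configurations such as maintain_prob all 1, or no planted MEGs) the
    ## share calibration is skipped.
    degenerate_cal <- !any(active_meg) ||
      !any(!maintained & head_gene)
    target <- cfg$top1000_share_mev
    if (degenerate_cal) {
      warning("EV top-1,000 share calibration skipped: no depleted ",
              "high-abundance genes or no planted MEGs to rebalance")
      depth <- 0
    } else {
      lo <- 0.2; hi <- 12
      s_hi <- ev_share(hi)
      if (!is.finite(s_hi) || s_hi > target + 0.02 ||
          ev_share(lo) < target - 0.02)
        stop(sprintf(paste0("infeasible calibration: EV top-1,000 share ",
                            "cannot reach target %.3f (share at maximal ",
                            "depletion %.3f)"), target, s_hi))
      for (i in 1:60) {
        mid <- (lo + hi) / 2
        s_mid <- ev_share(mid)
        if (abs(s_mid - target) < 1e-4) break
        if (s_mid > target) lo <- mid else hi <- mid
      }
      depth <- (lo + hi) / 2
    }
    built <- build_factors(depth)
    if (!degenerate_cal &&
        any(!is.finite(built$boost) | built$boost < 1))
      stop("infeasible calibration: MEG mass balance not satisfiable")
    tf <- built$f
    dimnames(tf) <- dimnames(muscle_fpkm)
    mev_fpkm <- muscle_fpkm * tf
    share_achieved <- mean(apply(mev_fpkm, 2L, function(x)
      sum(sort(x, decreasing = TRUE)[seq_len(min(1000L, n))]) / sum(x)))

    structure(list(base_fpkm = base_fpkm,
                   class_true = class_true,
                   muscle_fpkm = muscle_fpkm,
                   mev_fpkm = mev_fpkm,
                   transfer_factor = tf,
                   maintained = maintained,
                   active_meg = active_meg,
                   meg_shared = meg_shared,
                   meg_specific = meg_specific,
                   animals = animals,
                   depletion_depth = depth,
                   meg_boost = setNames(built$boost, animals$animal_id),
                   achieved_mev_share = share_achieved),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0("sim_truth: %d genes x %d animals; %d shared + %d ",
                     "breed-specific planted MEGs\n",
                     "  calibrated head depletion depth %.3f ",
                     "(EV top-1000 share %.4f)\n"),
              length(x$base_fpkm), nrow(x$animals), length(x$meg_shared),
              sum(lengths(x$meg_specific)), x$depletion_depth,
              x$achieved_mev_share))
  invisible(x)
}

# Vectorized 3-category multinomial via sequential binomials; preserves
# row-wise totals exactly.
rmultinom3 <- function(size, p1, p2, p3) {
  tot <- p1 + p2 + p3
  x1 <- rbinom(length(size), size, ifelse(tot > 0, p1 / tot, 0))
  rem <- size - x1
  p23 <- p2 + p3
  x2 <- rbinom(length(size), rem, ifelse(p23 > 0, p2 / p23, 0))
  cbind(x1, x2, rem - x2)
}

#' Draw observed counts from planted truth
#'
#' Gene-level fragment counts are negative binomial with mean proportional to
#' true FPKM x gene length x library size and the configured dispersion.
#' Region counts are multinomial over the compartment's baseline region
#' proportions re-weighted by the gene's region lengths, so region counts sum
#' exactly to the gene count. For a configured fraction of EV gene-samples
#' one UTR region is forced to zero (truncated cargo); the corresponding
#' full-length truth flag is FALSE.
#'
#' @param truth A `sim_truth` from [simulate_expression()].
#' @param cfg The matching [sim_config()].
#' @param annotation The matching [gene_annotation()].
#' @return List with `counts` (genes x samples matrix), `regions`
#'   ([region_counts()]), `samples` ([sample_sheet()]) and
#'   `full_length_truth` (logical genes x EV-samples matrix).
#' @export
simulate_counts <- function(truth, cfg, annotation) {
  validate_sim_config(cfg)
  ids <- names(truth$base_fpkm)
  g <- annotation$genes[ids, ]
  n <- length(ids)
  animals <- truth$animals
  samples_df <- rbind(
    data.frame(sample_id = paste0(animals$animal_id, "_muscle"),
               animal_id = animals$animal_id, breed = animals$breed,
               sex = animals$sex, compartment = "muscle",
               stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(animals$animal_id, "_MEV"),
               animal_id = animals$animal_id, breed = animals$breed,
               sex = animals$sex, compartment = "MEV",
               stringsAsFactors = FALSE))
  samples <- sample_sheet(samples_df, breeds = cfg$breeds)

  with_seed(cfg$seed + 2L, {
    len_kb <- g$gene_length / 1e3
    counts <- matrix(0, n, nrow(samples_df),
                     dimnames = list(ids, samples_df$sample_id))
    for (i in seq_len(nrow(samples_df))) {
      comp <- samples_df$compartment[i]
      a <- samples_df$animal_id[i]
      fpkm <- if (comp == "muscle") truth$muscle_fpkm[, a]
              else truth$mev_fpkm[, a]
      lib <- if (comp == "muscle") cfg$muscle_library_size
             else cfg$mev_library_size
      mu <- fpkm * len_kb * lib / 1e6
      counts[, i] <- if (cfg$dispersion <= 1e-12) rpois(n, mu)
                     else rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
    }

    mk <- function() matrix(0, n, nrow(samples_df),
                            dimnames = dimnames(counts))
    r5 <- mk(); rc <- mk(); r3 <- mk()
    ev_samples <- samples_df$sample_id[samples_df$compartment == "MEV"]
    ## truncation is a property of a gene's vesicle cargo, so the missing
    ## UTR is drawn once per gene and applied to every EV sample
    miss <- runif(n) < cfg$fraction_missing_region_mev
    drop5 <- miss & (runif(n) < 0.5)
    drop3 <- miss & !drop5
    fl_truth <- matrix(!miss, n, length(ev_samples),
                       dimnames = list(ids, ev_samples))
    for (i in seq_len(nrow(samples_df))) {
      comp <- samples_df$compartment[i]
      props <- if (comp == "muscle") cfg$region_props_muscle
               else cfg$region_props_mev
      w5 <- props[["utr5"]] * g$utr5_length
      wc <- props[["cds"]] * g$cds_length
      w3 <- props[["utr3"]] * g$utr3_length
      if (comp == "MEV") {
        w5[drop5] <- 0
        w3[drop3] <- 0
      }
      reg <- rmultinom3(counts[, i], w5, wc, w3)
      r5[, i] <- reg[, 1L]; rc[, i] <- reg[, 2L]; r3[, i] <- reg[, 3L]
    }
    list(counts = counts,
         regions = region_counts(r5, rc, r3),
         samples = samples,
         full_length_truth = fl_truth)
  })
}

#' Simulate a qPCR CT table from planted truth
#'
#' CT = `offset` - log2(true expression) + Normal(0, `qpcr_noise_sd`), per
#' panel gene and sample. The reference gene is simulated at constant true
#' expression across all samples.
#'
#' @param truth A `sim_truth`.
#' @param cfg The matching [sim_config()].
#' @param gene_panel Character vector of panel gene ids (must exist in
#'   `truth`).
#' @param samples The [sample_sheet()] from [simulate_counts()].
#' @param reference_gene Id used for the reference transcript.
#' @param offset CT intercept, cycles.
#' @param reference_expression Constant true expression of the reference.
#' @return A `qpcr_table` data.frame with attributes `reference_gene` and
#'   `calibrator_sample` (first muscle sample).
#' @export
simulate_qpcr <- function(truth, cfg, gene_panel, samples,
                          reference_gene = "GAPDH", offset = 30,
                          reference_expression = 1000) {
  validate_sim_config(cfg)
  if (any(!gene_panel %in% names(truth$base_fpkm)))
    stop("panel gene(s) absent from truth: ",
         paste(setdiff(gene_panel, names(truth$base_fpkm)), collapse = ", "))
  sdf <- as.data.frame(samples)
  with_seed(cfg$seed + 3L, {
    rows <- do.call(rbind, lapply(seq_len(nrow(sdf)), function(i) {
      a <- sdf$animal_id[i]
      expr <- if (sdf$compartment[i] == "muscle")
        truth$muscle_fpkm[gene_panel, a] else truth$mev_fpkm[gene_panel, a]
      data.frame(sample_id = sdf$sample_id[i],
                 gene_id = c(gene_panel, reference_gene),
                 true_expression = c(expr, reference_expression),
                 stringsAsFactors = FALSE)
    }))
    rows$ct <- offset - log2(rows$true_expression) +
      rnorm(nrow(rows), 0, cfg$qpcr_noise_sd)
    rows$true_expression <- NULL
    calib <- sort(sdf$sample_id[sdf$compartment == "muscle"])[1L]
    structure(rows, reference_gene = reference_gene,
              calibrator_sample = calib,
              class = c("qpcr_table", "data.frame"))
  })
}

#' Simulate a pathway gene-set collection with one planted enriched set
#'
#' One set is drawn from the planted shared MEGs (so over-representation
#' analysis of a recovered MEG catalog should rank it first); the remaining
#' sets are random draws from all genes.
#'
#' @param truth A `sim_truth`.
#' @param cfg The matching [sim_config()].
#' @param n_sets Total number of sets.
#' @param set_size Members per set.
#' @return A `gene_set_collection`; the planted set is named
#'   `"PLANTED_MEG_SET"`.
#' @export
simulate_gene_sets <- function(truth, cfg, n_sets = 20L, set_size = 100L) {
  with_seed(cfg$seed + 4L, {
    ids <- names(truth$base_fpkm)
    sets <- list(PLANTED_MEG_SET =
                   sample(truth$meg_shared, min(set_size,
                                                length(truth$meg_shared))))
    for (i in seq_len(n_sets - 1L))
      sets[[sprintf("RANDOM_SET_%02d", i)]] <- sample(ids, set_size)
    structure(sets,
              descriptions = setNames(names(sets), names(sets)),
              class = "gene_set_collection")
  })
}

#' Generate a complete synthetic paired dataset
#'
#' Runs [simulate_annotation()], [simulate_expression()],
#' [simulate_counts()], [simulate_qpcr()] and [simulate_gene_sets()] under
#' one configuration. The qPCR panel mirrors a differential-gene validation
#' panel: roughly half the genes are planted shared MEGs (vesicle-enriched)
#' and half are abundant muscle genes depleted in vesicles in every animal,
#' so the panel spans a wide dynamic range in both compartments.
#'
#' @param cfg A [sim_config()]; defaults to [default_scenario()].
#' @param panel_size qPCR panel size.
#' @return List with `annotation`, `truth`, `counts`, `regions`, `samples`,
#'   `full_length_truth`, `qpcr`, `gene_sets`, `panel` and `cfg`.
#' @export
simulate_dataset <- function(cfg = default_scenario(), panel_size = 13L) {
  annotation <- simulate_annotation(cfg)
  truth <- simulate_expression(cfg, annotation)
  obs <- simulate_counts(truth, cfg, annotation)
  panel <- with_seed(cfg$seed + 5L, {
    n_up <- ceiling(panel_size / 2)
    head_ids <- names(truth$class_true)[truth$class_true %in%
                                          c("Top100", "Mid")]
    down_pool <- head_ids[rowSums(truth$maintained[head_ids, ,
                                                   drop = FALSE]) == 0]
    n_down <- min(panel_size - n_up, length(down_pool))
    c(sample(truth$meg_shared, min(n_up, length(truth$meg_shared))),
      sample(down_pool, n_down))
  })
  qpcr <- simulate_qpcr(truth, cfg, panel, obs$samples)
  gene_sets <- simulate_gene_sets(truth, cfg)
  list(annotation = annotation, truth = truth, counts = obs$counts,
       regions = obs$regions, samples = obs$samples,
       full_length_truth = obs$full_length_truth, qpcr = qpcr,
       gene_sets = gene_sets, panel = panel, cfg = cfg)
}

#' Write a simulated dataset to an output directory
#'
#' Emits the standard plain-text formats consumed by the pipeline readers:
#' `annotation.gtf`, `counts.tsv`, `region_counts.tsv`, `samples.tsv`,
#' `qpcr.tsv`, `genesets.gmt` and a `truth.json` summary of the planted
#' state.
#'
#' @param sim Result of [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, `outdir`.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(sim$annotation, file.path(outdir, "annotation.gtf"))
  write_count_matrix(sim$counts, file.path(outdir, "counts.tsv"))
  write_region_counts(sim$regions, file.path(outdir, "region_counts.tsv"))
  write_sample_sheet(sim$samples, file.path(outdir, "samples.tsv"))
  write_qpcr(sim$qpcr, file.path(outdir, "qpcr.tsv"))
  write_gene_sets(sim$gene_sets, file.path(outdir, "genesets.gmt"))
  truth_summary <- list(
    seed = sim$cfg$seed,
    depletion_depth = sim$truth$depletion_depth,
    achieved_mev_share = sim$truth$achieved_mev_share,
    meg_shared = sim$truth$meg_shared,
    meg_specific = sim$truth$meg_specific,
    panel = sim$panel)
  jsonlite::write_json(truth_summary, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
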
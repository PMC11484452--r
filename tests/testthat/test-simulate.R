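test_that("generator is deterministic given the seed and varies across seeds", {
  a <- sim_degenerate(seed = 21L)
  b <- sim_degenerate(seed = 21L)
  c <- sim_degenerate(seed = 22L)
  p1 <- withr::local_tempfile(fileext = ".gtf")
  p2 <- withr::local_tempfile(fileext = ".gtf")
  write_annotation(a$annotation, p1)
  write_annotation(b$annotation, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(a$counts, b$counts)
  expect_identical(a$qpcr$ct, b$qpcr$ct)
  expect_false(identical(a$counts, c$counts))
})

test_that("simulated annotation has three positive-length regions per gene", {
  cfg <- degenerate_cfg(n_genes = 3000L)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$genes), 3000L)
  expect_equal(nrow(ann$features), 3L * 3000L)
  expect_true(all(ann$genes$utr5_length > 0))
  expect_true(all(ann$genes$cds_length > 0))
  expect_true(all(ann$genes$utr3_length > 0))
  expect_equal(ann$genes$gene_length,
               ann$genes$utr5_length + ann$genes$cds_length +
                 ann$genes$utr3_length)
})

test_that("base muscle profile carries the configured top-1000 share exactly", {
  truth <- get_sim()$truth
  share <- sum(sort(truth$base_fpkm, decreasing = TRUE)[1:1000]) /
    sum(truth$base_fpkm)
  expect_equal(share, default_scenario()$top1000_share_muscle,
               tolerance = 1e-9)
})

test_that("maintained flags and transfer factors are mutually consistent", {
  truth <- get_sim()$truth
  expect_identical(truth$maintained, truth$transfer_factor >= 1)
  # the EV profile is the muscle profile times the factor, exactly
  expect_equal(truth$mev_fpkm, truth$muscle_fpkm * truth$transfer_factor)
})

test_that("planted MEGs exceed the minimum fold in their active breeds", {
  sim <- get_sim()
  truth <- sim$truth
  min_fold <- 2^sim$cfg$meg_log2fc_min
  for (b in sim$cfg$breeds) {
    animals <- truth$animals$animal_id[truth$animals$breed == b]
    active <- c(truth$meg_shared, truth$meg_specific[[b]])
    expect_true(all(truth$transfer_factor[active, animals] >= min_fold))
  }
  # shared MEGs exceed it in every animal of both breeds
  expect_true(all(truth$transfer_factor[truth$meg_shared, ] >= min_fold))
})

test_that("calibrated EV top-1000 share hits its target", {
  sim <- get_sim()
  expect_lt(abs(sim$truth$achieved_mev_share - sim$cfg$top1000_share_mev),
            0.02)
})

test_that("degenerate all-maintained configuration skips calibration", {
  cfg <- degenerate_cfg(seed = 5L)
  ann <- simulate_annotation(cfg)
  expect_warning(truth <- simulate_expression(cfg, ann),
                 "calibration skipped")
  expect_true(all(truth$maintained))
  expect_true(all(truth$transfer_factor >= 1))
})

test_that("region counts conserve gene counts exactly", {
  sim <- get_sim()
  expect_identical(region_totals(sim$regions), sim$counts)
})

test_that("forced-missing UTRs match the full-length truth flags", {
  sim <- get_sim()
  ev <- colnames(sim$truth$mev_fpkm)
  ev_samples <- paste0(ev, "_MEV")
  # genes flagged truncated have one UTR at zero in every EV sample
  trunc <- rownames(sim$full_length_truth)[!sim$full_length_truth[, 1L]]
  has_zero <- (sim$regions$utr5[trunc, ev_samples] == 0) |
    (sim$regions$utr3[trunc, ev_samples] == 0)
  expect_true(all(has_zero))
  # with no truncation, well-covered EV gene-samples keep all three regions
  sim0 <- sim_degenerate(seed = 31L, fraction_missing_region_mev = 0)
  ev0 <- paste0(sim0$truth$animals$animal_id, "_MEV")
  big <- sim0$counts[, ev0] >= 300
  for (r in c("utr5", "cds", "utr3"))
    expect_true(all(sim0$regions[[r]][, ev0][big] > 0))
})

test_that("observed FPKM converges to planted FPKM as dispersion vanishes", {
  # mass-balanced scenario, vanishing dispersion, deep libraries: counting
  # noise becomes negligible and the planted FPKM scale is recovered
  for (seed in 41:43) {
    cfg <- default_scenario(seed = seed, dispersion = 1e-13,
                          muscle_library_size = 4e9,
                          mev_library_size = 5.2e9)
    ann <- simulate_annotation(cfg)
    truth <- simulate_expression(cfg, ann)
    obs <- simulate_counts(truth, cfg, ann)
    fp <- compute_fpkm(obs$counts, ann)
    a <- truth$animals$animal_id[1L]
    for (cp in c("muscle", "MEV")) {
      tru <- if (cp == "muscle") truth$muscle_fpkm[, a]
             else truth$mev_fpkm[, a]
      o <- fp[, paste0(a, "_", cp)]
      sel <- tru > 1
      rel_err <- abs(o[sel] - tru[sel]) / tru[sel]
      expect_lt(quantile(rel_err, 0.99), 0.05)
      expect_lt(median(rel_err), 0.03)
    }
  }
})

test_that("zero-noise qPCR tables encode log2 expression exactly", {
  cfg <- degenerate_cfg(seed = 13L, qpcr_noise_sd = 0)
  ann <- simulate_annotation(cfg)
  truth <- suppressWarnings(simulate_expression(cfg, ann))
  obs <- simulate_counts(truth, cfg, ann)
  panel <- names(truth$base_fpkm)[c(1L, 500L)]
  q <- simulate_qpcr(truth, cfg, panel, obs$samples, offset = 30)
  a <- truth$animals$animal_id[1L]
  s <- paste0(a, "_muscle")
  for (g in panel) {
    ct <- q$ct[q$sample_id == s & q$gene_id == g]
    expect_equal(ct, 30 - log2(truth$muscle_fpkm[g, a]))
  }
  # reference gene CT identical across samples at zero noise
  ref <- q$ct[q$gene_id == attr(q, "reference_gene")]
  expect_equal(ref, rep(ref[1L], length(ref)))
  # a gene with 2x expression in one sample reads one cycle earlier
  a2 <- truth$animals$animal_id[2L]
  g <- panel[1L]
  delta <- q$ct[q$sample_id == paste0(a2, "_muscle") & q$gene_id == g] -
    q$ct[q$sample_id == s & q$gene_id == g]
  expect_equal(delta, log2(truth$muscle_fpkm[g, a] /
                             truth$muscle_fpkm[g, a2]))
})

test_that("written datasets are readable by the package's own readers", {
  sim <- sim_degenerate(seed = 17L, n_genes = 3000L)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("annotation.gtf", "counts.tsv", "region_counts.tsv", "samples.tsv",
      "qpcr.tsv", "genesets.gmt", "truth.json")))))
  counts <- read_count_matrix(file.path(dir, "counts.tsv"))
  expect_equal(counts, sim$counts)
  ss <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(ss$sample_id, as.data.frame(sim$samples)$sample_id)
})
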
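test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(2, 4, 8, 4, 8, 16), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(sqrt(0.5), sqrt(2)), tolerance = 1e-12)

  # identical columns give unit factors
  m2 <- matrix(c(3, 7, 11), 3, 2, dimnames = list(c("g1", "g2", "g3"),
                                                  c("A", "B")))
  expect_equal(unname(size_factors(m2)), c(1, 1))

  # scaling one column by c multiplies the ratio of its factor to the
  # others by c (the per-gene geometric means rescale too)
  m3 <- m2
  m3[, "B"] <- m3[, "B"] * 5
  sf2 <- size_factors(m2); sf3 <- size_factors(m3)
  expect_equal(sf3[["B"]] / sf3[["A"]], 5 * sf2[["B"]] / sf2[["A"]])

  # global count scaling leaves median-of-ratios factors unchanged
  expect_equal(size_factors(m * 3), size_factors(m))

  # no gene positive everywhere -> empty reference set
  m4 <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("g1", "g2"),
                                                    c("A", "B")))
  expect_error(size_factors(m4), "reference set")
})

test_that("dispersion estimates recover Poisson and NB truth", {
  grp <- factor(rep(c("muscle", "MEV"), each = 2), c("muscle", "MEV"))
  meds <- vapply(1:5, function(s) with_seed(s, {
    counts <- matrix(rpois(2000 * 4, 100), 2000, 4,
                     dimnames = list(sprintf("g%04d", 1:2000),
                                     paste0("s", 1:4)))
    sf <- size_factors(counts)
    median(estimate_dispersion(counts, sf, grp))
  }), 1)
  expect_true(all(meds <= 0.01))

  # constant counts within groups floor at the minimum
  cc <- matrix(rep(c(10, 20), each = 2), 2, 4, byrow = TRUE,
               dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  sf <- setNames(rep(1, 4), paste0("s", 1:4))
  expect_true(all(estimate_dispersion(cc, sf, grp) <= 1e-6))

  # NB with alpha = 0.1 at 20 samples per group
  grp20 <- factor(rep(c("muscle", "MEV"), each = 20), c("muscle", "MEV"))
  med_nb <- with_seed(42L, {
    counts <- matrix(rnbinom(2000 * 40, mu = 100, size = 10), 2000, 40,
                     dimnames = list(sprintf("g%04d", 1:2000),
                                     paste0("s", 1:40)))
    median(estimate_dispersion(counts, size_factors(counts), grp20))
  })
  expect_gte(med_nb, 0.05)
  expect_lte(med_nb, 0.2)

  expect_error(estimate_dispersion(cc, sf, factor(c(1, 1, 1, 2))),
               ">= 2 samples")
})

test_that("BH step-up matches hand-applied and brute-force definitions", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    ranked <- p[o]
    adj <- vapply(seq_len(m), function(i)
      min(ranked[i:m] * m / (i:m)), 1)
    out <- numeric(m)
    out[o] <- pmin(1, adj)
    out
  }
  for (s in 1:20) {
    p <- with_seed(s, runif(sample(1:12, 1)))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
    # and the established reference implementation
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("Wald test is exact in the null and consistent in the limit", {
  grp <- factor(rep(c("muscle", "MEV"), each = 2), c("muscle", "MEV"))
  # identical group means: log2FC = 0, z = 0, p = 1
  counts <- matrix(rep(c(40, 60), 4), 2, 4, byrow = FALSE,
                   dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  sf <- setNames(rep(1, 4), paste0("s", 1:4))
  disp <- setNames(rep(0.1, 2), c("g1", "g2"))
  de <- wald_test(counts, sf, disp, grp)
  expect_equal(de$log2fc, c(0, 0))
  expect_equal(de$p, c(1, 1))

  # 4x group mean at negligible dispersion and large counts: log2FC -> 2
  big <- matrix(c(10000, 10000, 40000, 40000), 1, 4,
                dimnames = list("g1", paste0("s", 1:4)))
  de2 <- wald_test(big, sf, setNames(1e-8, "g1"), grp)
  expect_lt(abs(de2$log2fc - 2), 0.05)
  expect_lt(de2$padj, 1e-6)

  # log2FC invariant to global count rescaling (up to the fixed 0.5
  # pseudo-fraction on group means, negligible at these depths)
  counts2 <- matrix(c(5000, 7000, 9000, 26000), 2, 2,
                    dimnames = list(c("g1", "g2"), c("s1", "s2")))
  counts2 <- cbind(counts2, s3 = c(5500, 10000), s4 = c(6000, 24000))
  grp2 <- factor(c("muscle", "MEV", "muscle", "MEV"), c("muscle", "MEV"))
  d1 <- wald_test(counts2, size_factors(counts2),
                  setNames(c(0.05, 0.05), c("g1", "g2")), grp2)
  d2 <- wald_test(counts2 * 7, size_factors(counts2 * 7),
                  setNames(c(0.05, 0.05), c("g1", "g2")), grp2)
  expect_equal(d1$log2fc, d2$log2fc, tolerance = 1e-4)

  # all-zero genes are excluded and reported
  counts3 <- rbind(counts2, g0 = c(0, 0, 0, 0))
  d3 <- wald_test(counts3, size_factors(counts2),
                  setNames(rep(0.05, 3), rownames(counts3)), grp2)
  expect_equal(attr(d3, "excluded"), "g0")
  expect_equal(nrow(d3), 2L)
})

test_that("null NB counts give calibrated raw p-values at 2 vs 2", {
  grp <- factor(rep(c("muscle", "MEV"), each = 2), c("muscle", "MEV"))
  frac <- vapply(1:5, function(s) with_seed(s, {
    n <- 5000L
    mu <- exp(runif(n, log(20), log(2000)))
    counts <- matrix(rnbinom(n * 4, mu = mu, size = 1 / 0.05), n, 4,
                     dimnames = list(sprintf("g%04d", 1:n),
                                     paste0("s", 1:4)))
    sf <- size_factors(counts)
    de <- wald_test(counts, sf, estimate_dispersion(counts, sf, grp), grp)
    mean(de$p <= 0.05)
  }), 1)
  expect_gte(mean(frac), 0.03)
  expect_lte(mean(frac), 0.08)
})

test_that("MEG calling applies both the padj and fold thresholds", {
  de <- structure(data.frame(
    gene_id = c("a", "b", "c"),
    base_mean = 100, log2fc = c(log2(2.5), 3, log2(1.9)),
    se_log2fc = 0.1, wald_z = 5,
    p = c(0.001, 0.02, 0.001), padj = c(0.04, 0.06, 0.01)),
    class = c("de_result", "data.frame"))
  cat <- call_megs(de, "test")
  expect_equal(cat$genes, "a")
  expect_equal(cat$n_tested, 3L)
})

test_that("catalog Venn partition enumerates all seven regions", {
  mk <- function(level, genes) structure(
    list(level = level, genes = genes, n_tested = 10L,
         ratio = length(genes) / 10), class = "meg_catalog")
  v <- compare_catalogs(mk("LW", c("a", "b")), mk("WB", c("b", "c")),
                        mk("Global", "b"))
  expect_equal(unname(v$counts[c("LW", "WB", "LW&WB&Global")]),
               c(1L, 1L, 1L))
  expect_equal(v$regions[["LW&WB&Global"]], "b")
  expect_equal(sum(v$counts), 3L)

  # identical catalogs collapse to the triple region
  v2 <- compare_catalogs(mk("LW", c("x", "y")), mk("WB", c("x", "y")),
                         mk("Global", c("x", "y")))
  expect_equal(unname(v2$counts[["LW&WB&Global"]]), 2L)
  expect_equal(sum(v2$counts), 2L)

  # disjoint catalogs populate only singleton regions
  v3 <- compare_catalogs(mk("LW", "x"), mk("WB", "y"), mk("Global", "z"))
  expect_equal(unname(v3$counts[c("LW", "WB", "Global")]), c(1L, 1L, 1L))
})

test_that("planted MEGs are recovered with high sensitivity and low FDR", {
  runs <- get_recovery_runs()
  sens <- vapply(runs, function(r)
    mean(r$planted_shared %in% r$catalog$genes), 1)
  fdr <- vapply(runs, function(r) {
    called <- r$catalog$genes
    if (!length(called)) return(0)
    mean(!(called %in% r$planted_all))
  }, 1)
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fdr), 0.15)
})

test_that("breed-specific MEGs land in the matching breed catalog", {
  sim <- get_sim()
  fpkm <- compute_fpkm(sim$counts, sim$annotation)
  expr <- filter_low_expression(fpkm)$expr
  cats <- lapply(c("LargeWhite", "WildBoar"), function(b)
    call_megs(meg_de(sim$counts, sim$samples, b, genes = rownames(expr))))
  names(cats) <- c("LargeWhite", "WildBoar")
  for (b in c("LargeWhite", "WildBoar")) {
    other <- setdiff(c("LargeWhite", "WildBoar"), b)
    spec <- sim$truth$meg_specific[[b]]
    in_own <- mean(spec %in% cats[[b]]$genes)
    in_other <- mean(spec %in% cats[[other]]$genes)
    expect_gt(in_own, 0.8)
    expect_lt(in_other, 0.2)
  }
})
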
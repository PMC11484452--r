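test_that("rank classes partition genes with fixed sizes and tie-breaks", {
  n <- 1500L
  ids <- sprintf("g%04d", seq_len(n))
  expr <- matrix(rev(seq_len(n)), n, 1, dimnames = list(ids, "s1"))
  cl <- assign_rank_classes(expr)
  expect_equal(sum(cl == "Top100"), 100L)
  expect_equal(sum(cl == "Mid"), 900L)
  expect_equal(sum(cl == "Other"), 500L)
  expect_equal(unname(cl[1L, 1L]), "Top100")

  # tie at the 100/101 boundary: lexicographically smaller id wins Top100
  expr2 <- expr
  expr2[100:101, 1] <- mean(expr[100:101, 1])
  cl2 <- assign_rank_classes(expr2)
  expect_equal(unname(cl2["g0100", 1]), "Top100")
  expect_equal(unname(cl2["g0101", 1]), "Mid")

  # fully tied input still yields a valid partition of the stated sizes
  expr3 <- matrix(1, n, 1, dimnames = list(ids, "s1"))
  cl3 <- assign_rank_classes(expr3)
  expect_equal(as.vector(table(cl3)[c("Top100", "Mid", "Other")]),
               c(100L, 900L, 500L))

  expect_warning(assign_rank_classes(expr[1:500, , drop = FALSE]),
                 "truncate")
})

make_pair_sheet <- function() {
  sample_sheet(data.frame(
    sample_id = c("a_m", "a_e"), animal_id = "a", breed = "LargeWhite",
    sex = "F", compartment = c("muscle", "MEV")))
}

test_that("maintained fractions count EV >= muscle with ties maintained", {
  ids <- sprintf("g%04d", 1:1200)
  muscle <- matrix(rev(seq_len(1200)), 1200, 1, dimnames = list(ids, "a_m"))
  mev <- muscle
  colnames(mev) <- "a_e"
  samples <- make_pair_sheet()
  classes <- assign_rank_classes(muscle)

  # identical matrices: ties count as maintained, 100% everywhere
  mf <- maintained_fractions(muscle, mev, samples, classes)
  expect_equal(mf$fraction_maintained, rep(100, 3))

  # EV all zero: 0% everywhere
  mf0 <- maintained_fractions(muscle, mev * 0, samples, classes)
  expect_equal(mf0$fraction_maintained, rep(0, 3))

  # 2 of 3 genes in a class maintained -> 66.67%
  mev2 <- mev
  drop_idx <- which(classes[, 1] == "Other")[1L]
  mev2[drop_idx, 1] <- 0
  mf2 <- maintained_fractions(muscle, mev2, samples, classes)
  other <- mf2[mf2$class == "Other", ]
  expect_equal(other$fraction_maintained,
               100 * (other$n_genes - 1) / other$n_genes)

  # invariant to gene reordering
  ord <- rev(seq_len(1200))
  mf3 <- maintained_fractions(muscle[ord, , drop = FALSE],
                              mev2[ord, , drop = FALSE], samples,
                              classes[ord, , drop = FALSE])
  expect_equal(mf3[order(mf3$class), ], mf2[order(mf2$class), ],
               ignore_attr = TRUE)
})

test_that("cumulative share is a normalized, monotone top-n statistic", {
  expr <- matrix(c(90, 5, 3, 2), 4, 1,
                 dimnames = list(paste0("g", 1:4), "s1"))
  expect_equal(unname(cumulative_share(expr, 1)), 0.90)
  expect_equal(unname(cumulative_share(expr, 4)), 1.0)
  # uniform FPKM: share of top k is k/N
  uni <- matrix(1, 10, 1, dimnames = list(paste0("g", 1:10), "s1"))
  expect_equal(unname(cumulative_share(uni, 3)), 0.3)
  shares <- vapply(1:4, function(k) unname(cumulative_share(expr, k)), 1)
  expect_true(all(diff(shares) >= 0))
  expect_error(cumulative_share(expr, 5), "exceeds")
  expect_error(cumulative_share(expr, 0), ">= 1")
})

test_that("ANOVA + LSD reproduce hand-computed statistics", {
  # identical groups: F = 0, p = 1
  df0 <- data.frame(class = rep(c("A", "B", "C"), each = 3),
                    fraction_maintained = rep(c(1, 2, 3), 3))
  r0 <- anova_lsd(df0)
  expect_equal(r0$F, 0)
  expect_equal(r0$p_anova, 1)

  # zero within-group variance with distinct means: degenerate, all pairs
  # significant
  dfd <- data.frame(class = rep(c("A", "B", "C"), each = 2),
                    fraction_maintained = c(10, 10, 20, 20, 30, 30))
  rd <- anova_lsd(dfd)
  expect_true(rd$degenerate)
  expect_equal(rd$p_anova, 0)
  expect_true(all(rd$pairwise$significant))

  # hand-computed pooled-variance example:
  # group means 20 / 25 / 60, SSB = 3800, SSW = 24 on 9 df,
  # F = 1900 / (8/3) = 712.5; t(Other vs Top100) = 40 / sqrt((8/3)(1/2))
  dfh <- data.frame(
    class = rep(c("Top100", "Mid", "Other"), each = 4),
    fraction_maintained = c(18, 22, 20, 20, 23, 27, 25, 25, 58, 62, 60, 60))
  rh <- anova_lsd(dfh)
  expect_equal(rh$F, 712.5, tolerance = 1e-9)
  expect_equal(rh$ms_within, 8 / 3, tolerance = 1e-9)
  pw <- rh$pairwise
  ot <- pw[(pw$class_a == "Other" & pw$class_b == "Top100") |
             (pw$class_a == "Top100" & pw$class_b == "Other"), ]
  expect_equal(abs(ot$t), 40 / sqrt((8 / 3) * 0.5), tolerance = 1e-9)
  expect_lt(ot$p, 0.001)
  # letters: Other separated from both lower classes
  expect_false(grepl(rh$letters[["Other"]], rh$letters[["Top100"]],
                     fixed = TRUE))
  expect_false(grepl(rh$letters[["Other"]], rh$letters[["Mid"]],
                     fixed = TRUE))

  expect_error(anova_lsd(data.frame(class = c("A", "B"),
                                    fraction_maintained = c(1, 2))),
               ">= 2 observations")
})

test_that("recovered class fractions separate Other from the head classes", {
  runs <- get_recovery_runs()
  pooled <- do.call(rbind, lapply(runs, `[[`, "rank_summary"))
  lsd <- anova_lsd(pooled)
  expect_lte(lsd$p_anova, 0.05)
  expect_false(grepl(lsd$letters[["Other"]], lsd$letters[["Top100"]],
                     fixed = TRUE))
  expect_false(grepl(lsd$letters[["Other"]], lsd$letters[["Mid"]],
                     fixed = TRUE))
})
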
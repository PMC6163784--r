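test_that("Wilcoxon exact p matches the sign-flip enumeration oracle", {
  set.seed(51)
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(7)
    for (alt in c("two.sided", "greater", "less")) {
      got <- wilcoxon_signed_rank(a, b, alternative = alt)
      expect_equal(got$p_value, wilcoxon_signflip_oracle(a, b, alt),
                   tolerance = 1e-12)
    }
  }
  # with tied absolute differences (mid-ranks) the DP still enumerates exactly
  a <- c(1, 2, 3, 4, 5, 6, 7)
  b <- a + c(0.5, -0.5, 0.5, -0.5, 1.5, 1.5, 2.5)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               wilcoxon_signflip_oracle(a, b, "two.sided"), tolerance = 1e-12)
})

test_that("Wilcoxon agrees with stats::wilcox.test on tie-free data", {
  set.seed(52)
  for (n in c(6, 9, 14)) {
    a <- rnorm(n); b <- rnorm(n)
    got <- wilcoxon_signed_rank(a, b)
    ref <- wilcox.test(b, a, paired = TRUE, exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(got$statistic, unname(ref$statistic))
  }
})

test_that("Wilcoxon edge cases behave as documented", {
  a <- 1:7
  # uniform positive shift: one-sided p attains its minimum 2^-n
  g <- wilcoxon_signed_rank(a, a + 1, alternative = "greater")
  expect_equal(g$p_value, 2^-7)
  expect_equal(wilcoxon_signed_rank(a, a + 1)$p_value, 2 * 2^-7)
  # mirrored differences: statistic at the distribution center, p = 1
  b <- a + c(-3, -2, -1, 1, 2, 3, 0)
  m <- wilcoxon_signed_rank(a, b)
  expect_equal(m$statistic, sum(1:6) / 2)
  expect_equal(m$p_value, 1)
  # all-zero differences: degenerate with warning
  expect_warning(z <- wilcoxon_signed_rank(a, a), "zero")
  expect_equal(z$p_value, 1)
  # positive affine transforms preserve the ranks and the p-value
  set.seed(53)
  x <- rnorm(7); y <- rnorm(7)
  expect_equal(wilcoxon_signed_rank(2 * x + 5, 2 * y + 5)$p_value,
               wilcoxon_signed_rank(x, y)$p_value)
  # pratt zero handling runs and gives a valid p
  expect_warning(p <- wilcoxon_signed_rank(a, a + c(0, 1, 2, 3, -1, 2, 1),
                                           zero_method = "pratt"), NA)
  expect_true(p$p_value > 0 && p$p_value <= 1)
})

test_that("Friedman chi-square path matches stats::friedman.test", {
  set.seed(54)
  for (i in 1:5) {
    m <- matrix(rnorm(21), 7, 3)
    got <- friedman_rm(m)
    ref <- friedman.test(m)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Friedman exact p matches the full permutation enumeration", {
  set.seed(55)
  # n = 5, k = 3: 7776 permutations enumerated by the independent oracle
  for (i in 1:3) {
    m <- matrix(rnorm(15), 5, 3)
    expect_equal(friedman_rm(m, exact = TRUE)$p_value,
                 friedman_permutation_oracle(m), tolerance = 1e-12)
  }
  # with ties in a block
  m <- matrix(c(1, 1, 2, 3, 2, 1, 2, 2, 3, 1, 3, 2, 1, 2, 3), 5, 3)
  expect_equal(friedman_rm(m, exact = TRUE)$p_value,
               friedman_permutation_oracle(m), tolerance = 1e-12)
})

test_that("Friedman handles degeneracy, missing blocks and monotone maps", {
  # identical conditions within every donor: no ranking signal
  m <- matrix(rep(c(1, 5, 2, 4, 3, 6, 7), 3), 7, 3)
  f <- friedman_rm(m)
  expect_equal(f$statistic, 0)
  expect_equal(f$p_value, 1)
  # rank-based: any strictly monotone transform leaves the statistic alone
  set.seed(56)
  x <- matrix(rnorm(21), 7, 3)
  expect_equal(friedman_rm(exp(x))$statistic, friedman_rm(x)$statistic)
  # listwise deletion of incomplete blocks
  x[2, 3] <- NA
  expect_warning(f2 <- friedman_rm(x), "incomplete")
  expect_equal(f2$n_blocks, 6)
  expect_error(friedman_rm(matrix(c(1, 2, NA, 2, 1, NA, 1, 2, NA), 3, 3)),
               "blocks")
  expect_error(friedman_rm(matrix(1:10, 5, 2)), "3 conditions")
})

test_that("Pfaffl ratios follow the efficiency-corrected closed form", {
  expect_equal(pfaffl_ratio(20, 20, 18, 18), 1)      # sample == control
  expect_equal(pfaffl_ratio(24, 25, 20, 20), 2)      # one target cycle earlier
  set.seed(57)
  for (i in 1:20) {
    cts <- runif(4, 15, 35); et <- runif(1, 1.7, 2.1); er <- runif(1, 1.7, 2.1)
    got <- pfaffl_ratio(cts[1], cts[2], cts[3], cts[4], et, er)
    oracle <- exp((cts[2] - cts[1]) * log(et) - (cts[4] - cts[3]) * log(er))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  expect_error(pfaffl_ratio(20, 20, 18, 18, e_target = 2.5), "efficienc")
  expect_error(pfaffl_ratio(-1, 20, 18, 18), "positive")
})

test_that("fold-change normalization pins controls at one", {
  df <- tidyr::expand_grid(donor = paste0("d", 1:7),
                           condition = c("control", "treated"))
  set.seed(58)
  df$ratio <- runif(nrow(df), 0.5, 2)
  df$ratio[df$condition == "treated"] <-
    2 * df$ratio[df$condition == "control"]
  fc <- fold_change_normalize(df)
  expect_true(all(fc$fold_change[fc$condition == "control"] == 1))
  expect_true(all(abs(fc$fold_change[fc$condition == "treated"] - 2) < 1e-12))
  # renormalizing the fold changes is idempotent
  fc2 <- fold_change_normalize(
    dplyr::select(fc, "donor", "condition", ratio = "fold_change"))
  expect_equal(fc2$fold_change, fc$fold_change)
  # a missing control propagates NA with a warning
  df2 <- df[!(df$donor == "d1" & df$condition == "control"), ]
  expect_warning(fc3 <- fold_change_normalize(df2), "control")
  expect_true(is.na(fc3$fold_change[fc3$donor == "d1"][1]))
})

test_that("generation time is the doubling-time closed form", {
  expect_equal(generation_time(1e5, 2e5, 24), 24)
  expect_equal(generation_time(1e5, 4e5, 24), 12)
  set.seed(59)
  for (i in 1:20) {
    n0 <- runif(1, 1e4, 1e6); gr <- runif(1, 1.1, 8); el <- runif(1, 12, 96)
    expect_equal(generation_time(n0, n0 * gr, el),
                 el * log(2) / log(gr), tolerance = 1e-12)
  }
  expect_warning(gt <- generation_time(100, 90, 24), "no growth")
  expect_true(is.na(gt))
  expect_error(generation_time(0, 10, 24), "positive")
})
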
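test_that("risk differences and Wald intervals match published contrasts", {
  # primary endpoint, molecular B-cell poor stratum
  rd <- risk_difference(12, 33, 20, 32)
  expect_equal(rd$effect, 100 * (20 / 32 - 12 / 33))
  expect_equal(rd$effect_rounded, 26)
  expect_equal(c(rd$ci_low_rounded, rd$ci_high_rounded), c(3, 50))
  # primary endpoint, histology B-cell poor stratum
  rd2 <- risk_difference(17, 38, 23, 41)
  expect_equal(rd2$effect_rounded, 11)
  expect_equal(c(rd2$ci_low_rounded, rd2$ci_high_rounded), c(-11, 33))
  # degenerate Wald case is flagged
  rd3 <- risk_difference(0, 10, 0, 10)
  expect_equal(rd3$effect, 0)
  expect_equal(c(rd3$ci_low, rd3$ci_high), c(0, 0))
  expect_true(rd3$degenerate)
  expect_false(risk_difference(0, 10, 0, 10, ci_method = "newcombe")$degenerate)
  expect_error(risk_difference(5, 0, 1, 10), "at least 1")
  expect_error(risk_difference(11, 10, 1, 10), "in \\[0, n\\]")
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_away(c(2.5, -2.5, 22.66, -3.5, 0.4)),
               c(3, -3, 23, -4, 0))
})

test_that("the binary test selects chi-squared or Fisher by expected cells", {
  bt <- binary_test(12, 33, 20, 32)
  expect_equal(bt$method, "chisq")
  expect_equal(bt$statistic, 4.4402, tolerance = 1e-4)
  expect_equal(bt$p_value, 0.0351, tolerance = 1e-3)
  expect_equal(binary_test(5, 10, 5, 10)$p_value, 1)
  bt2 <- binary_test(1, 5, 4, 5)
  expect_equal(bt2$method, "fisher")
  expect_true(any(bt2$expected < 5))
})

test_that("Fisher p-values equal exhaustive hypergeometric enumeration", {
  set.seed(7)
  for (i in 1:25) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    got <- binary_test(x1, n1, x2, n2, method = "fisher")$p_value
    expect_equal(got, fisher_enum_p(x1, n1, x2, n2), tolerance = 1e-10,
                 label = sprintf("table (%d/%d, %d/%d)", x1, n1, x2, n2))
  }
})

test_that("chi-squared p agrees with the exhaustive permutation null", {
  set.seed(8)
  for (i in 1:15) {
    n1 <- sample(3000:5000, 1); n2 <- sample(3000:5000, 1)
    x1 <- rbinom(1, n1, runif(1, 0.3, 0.7))
    x2 <- rbinom(1, n2, runif(1, 0.3, 0.7))
    p_asym <- binary_test(x1, n1, x2, n2, method = "chisq")$p_value
    expect_lt(abs(p_asym - chisq_perm_p(x1, n1, x2, n2)), 0.01)
  }
})

test_that("ANCOVA recovers a noiseless arm effect exactly", {
  set.seed(10)
  bl <- rnorm(40, 30, 5)
  arm <- rep(c("rituximab", "tocilizumab"), each = 20)
  fu <- bl - 10 - 3 * (arm == "tocilizumab") + 0.2 * (bl - 30)
  res <- suppressWarnings(ancova_change(bl, fu, arm))  # perfect fit
  expect_equal(res$effect, 3, tolerance = 1e-10)  # ref minus alt
  expect_lt(res$p_value, 1e-10)
  # identical arms: zero difference, p of 1
  fu0 <- bl - 5
  res0 <- suppressWarnings(ancova_change(bl, fu0, arm))
  expect_equal(res0$effect, 0, tolerance = 1e-10)
  expect_error(ancova_change(bl, fu, rep("a", 40)), "two levels")
})

test_that("ANCOVA estimate lands within sampling error of the truth", {
  set.seed(11)
  n <- 200
  bl <- rnorm(2 * n, 30, 6)
  arm <- rep(c("rituximab", "tocilizumab"), each = n)
  fu <- bl - 12 + 3 * (arm == "tocilizumab") + rnorm(2 * n, 0, 5)
  res <- ancova_change(bl, fu, arm)   # ref - alt = -3
  se <- sqrt(2 * 25 / n)
  expect_lt(abs(res$effect - (-3)), 3 * se)
  expect_true(res$ci_low <= res$effect && res$effect <= res$ci_high)
})

test_that("rank ANCOVA is monotone-invariant and separates shifted arms", {
  set.seed(12)
  bl <- rnorm(60, 30, 5)
  arm <- rep(c("a", "b"), 30)
  fu <- bl - 8 + rnorm(60, 0, 3)
  p1 <- rank_ancova_change(bl, fu, arm)$p_value
  # monotone transform of the change leaves the rank statistic unchanged
  fu2 <- bl + exp((fu - bl) / 10)
  p2 <- rank_ancova_change(bl, fu2, arm)$p_value
  expect_equal(p1, p2, tolerance = 1e-9)
  # noiseless shifted arms
  fu_shift <- bl - 5 - 10 * (arm == "b")
  expect_lt(rank_ancova_change(bl, fu_shift, arm)$p_value, 1e-3)
})

test_that("rank ANCOVA holds its nominal size under the null", {
  set.seed(13)
  rej <- mean(replicate(2000, {
    bl <- rnorm(60, 30, 8)
    fu <- bl - 10 + rnorm(60, 0, 5)
    rank_ancova_change(bl, fu, rep(c("a", "b"), each = 30))$p_value < 0.05
  }))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("the assumption check routes heavy-tailed data to the rank method", {
  set.seed(14)
  bl <- rnorm(80, 30, 5)
  arm <- rep(c("a", "b"), 40)
  fu_norm <- bl - 10 + rnorm(80, 0, 3)
  expect_true(ancova_assumptions_ok(bl, fu_norm, arm))
  fu_cauchy <- bl - 10 + rcauchy(80, 0, 5)
  expect_false(ancova_assumptions_ok(bl, fu_cauchy, arm))
})

test_that("paired Wilcoxon handles ties exactly and degenerates to p = 1", {
  b <- rnorm(20, 50, 5)
  expect_warning(res0 <- within_group_change(b, b), "zero")
  expect_equal(res0$p_value, 1)
  # constant shift: all |differences| tied, smallest attainable p
  res <- within_group_change(b, b - 5)
  expect_equal(res$p_value, 2 * 2^-20, tolerance = 1e-12)
  expect_equal(res$method, "wilcoxon_paired_exact")
})

test_that("exact signed-rank p matches brute-force sign enumeration", {
  set.seed(15)
  for (i in 1:10) {
    n <- sample(5:11, 1)
    d <- round(rnorm(n, 0.3, 1), 1)    # rounding induces ties
    d <- d[d != 0]
    if (length(d) < 2) next
    got <- within_group_change(rep(0, length(d)), d)$p_value
    expect_equal(got, signed_rank_brute_p(d), tolerance = 1e-10)
  }
})

test_that("large-sample Wilcoxon rejects at the nominal rate under the null", {
  set.seed(16)
  rej <- mean(replicate(2000, {
    b <- rnorm(500); within_group_change(b, b + rnorm(500))$p_value < 0.05
  }))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("the interaction LRT respects nesting and flags separation", {
  set.seed(17)
  arm <- rep(c("r", "t"), each = 200)
  path <- rep(rep(c("poor", "rich"), each = 100), 2)
  y <- rbinom(400, 1, 0.4)
  res <- interaction_lrt(y, arm, path)
  expect_gte(res$deviance_reduced, res$deviance_full)
  expect_gte(res$statistic, 0)
  # perfect separation errors with advice
  y_sep <- as.integer(arm == "t" & path == "rich")
  expect_error(interaction_lrt(y_sep, arm, path), "separation")
  expect_error(interaction_lrt(y, rep("r", 400), path), "both levels")
})

test_that("interaction LRT null p-values are uniform at large n", {
  set.seed(18)
  ps <- replicate(200, {
    arm <- rep(c("r", "t"), each = 2000)
    path <- rep(rep(c("poor", "rich"), each = 1000), 2)
    y <- rbinom(4000, 1, ifelse(path == "poor", 0.3, 0.5))
    interaction_lrt(y, arm, path)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.05)
})

test_that("interaction LRT is powered for the protocol's cell rates", {
  set.seed(19)
  rates <- c(r_poor = 0.20, t_poor = 0.55, r_rich = 0.50, t_rich = 0.48)
  rej <- mean(replicate(60, {
    arm <- rep(c("r", "t"), each = 2000)
    path <- rep(rep(c("poor", "rich"), each = 1000), 2)
    pr <- rates[paste(arm, path, sep = "_")]
    y <- rbinom(4000, 1, pr)
    interaction_lrt(y, arm, path)$p_value < 0.05
  }))
  expect_gt(rej, 0.8)
})
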
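test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(4, 9, 4, 9), nrow = 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- matrix(c(4, 9, 8, 18), nrow = 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # permutation of genes leaves factors unchanged
  set.seed(1)
  m3 <- matrix(rpois(200, 30) + 1, nrow = 20)
  expect_equal(size_factors(m3), size_factors(m3[sample(20), ]))
  m4 <- cbind(m2, c(0, 0)); colnames(m4)[3] <- "z"
  expect_error(size_factors(m4), "all-zero counts: z")
})

test_that("size factors are proportional to the DESeq2 estimator", {
  set.seed(2)
  mu <- exp(rnorm(300, 3, 1))
  sf_true <- c(0.5, 1, 1.5, 2)
  m <- sapply(sf_true, function(s) rnbinom(300, mu = mu * s, size = 5))
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(ours / ref, rep(mean(ours / ref), 4), tolerance = 1e-8)
})

test_that("the count transform is a shifted log of normalised counts", {
  expect_equal(vst_transform(matrix(0), sf = 1)[1, 1], 0)
  expect_equal(vst_transform(matrix(7), sf = 1)[1, 1], 3)
  m <- matrix(c(5, 10), nrow = 1)
  expect_equal(vst_transform(m, sf = c(1, 2))[1, 1],
               vst_transform(m, sf = c(1, 2))[1, 2])
  # monotone in counts
  tr <- vst_transform(matrix(0:20, nrow = 1), sf = rep(1, 21))
  expect_true(all(diff(tr[1, ]) > 0))
})

test_that("module scores aggregate found module genes per sample", {
  tr <- matrix(1:6, nrow = 3,
               dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  one <- module_score(tr, "g2")
  expect_equal(one$score, c(2, 5))
  const <- matrix(3, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(module_score(const, c("g1", "g2"))$score, c(3, 3))
  expect_warning(module_score(tr, c("g1", "gX", "gY", "gZ", "gW")),
                 "of 5 module genes")
  expect_error(module_score(tr, c("nope")), "none of the module genes")
})

test_that("median-cutoff classification splits the cohort as specified", {
  lab <- classify_molecular(c(1, 2, 3, 4))
  expect_equal(as.character(lab), c("bcell_poor", "bcell_poor",
                                    "bcell_rich", "bcell_rich"))
  # ties at the median go poor
  lab2 <- classify_molecular(c(1, 2, 2, 9))
  expect_equal(as.character(lab2), c("bcell_poor", "bcell_poor",
                                     "bcell_poor", "bcell_rich"))
  # even cohort of distinct scores splits exactly in half
  set.seed(3)
  lab3 <- classify_molecular(sample(seq_len(124)))
  expect_equal(unname(table(lab3)[c("bcell_poor", "bcell_rich")]),
               c(62L, 62L), ignore_attr = TRUE)
  expect_error(classify_molecular(rep(2, 10)), "identical")
  expect_error(classify_molecular(1), "at least two")
})

test_that("classification is invariant under strictly increasing transforms", {
  set.seed(5)
  for (rep_i in 1:10) {
    sc <- rnorm(31)
    base <- as.character(classify_molecular(sc))
    for (f in list(function(x) 3 * x + 2, exp, function(x) x^3,
                   function(x) rank(x, ties.method = "first"))) {
      expect_equal(as.character(classify_molecular(f(sc))), base)
    }
  }
})

test_that("molecular and histology labels agree under perfect concordance", {
  cfg <- small_config(n_patients = 300, n_genes = 500, module_size = 40,
                      prop_bcell_rich = 0.5, histology_concordance = 1,
                      ungradable_rate = 0, prop_gc_given_rich = 0, seed = 11)
  ds <- simulate_trial(cfg)
  ml <- molecular_labels(ds)
  ok <- !is.na(ml)
  agree <- mean(ml[ok] == ds$patients$histology_label[ok])
  expect_gte(agree, 0.95)
})

test_that("rich patients score higher than poor on the module", {
  cfg <- small_config(n_patients = 200, seed = 8)
  ds <- simulate_trial(cfg)
  ml <- molecular_labels(ds)
  sc <- attr(ml, "score")
  latent <- ds$patients$latent_class
  ok <- !is.na(sc)
  expect_gt(mean(sc[ok & latent == "rich"]), mean(sc[ok & latent == "poor"]))
})

test_that("the cutoff scan covers the requested grid and degenerates cleanly", {
  set.seed(6)
  n <- 160
  score <- c(rnorm(n / 2, 0), rnorm(n / 2, 3))
  treat <- rep(c("rituximab", "tocilizumab"), n / 2)
  resp <- rbinom(n, 1, ifelse(score < 1.5,
                              ifelse(treat == "tocilizumab", 0.55, 0.20), 0.5))
  sc <- cutoff_scan(score, resp, treat)
  expect_equal(nrow(sc), 21)
  expect_equal(sc$percentile, 40:60)
  # degenerate scan equals the plain median classification analysis
  sc0 <- cutoff_scan(score, resp, treat, halfwidth = 0)
  expect_equal(nrow(sc0), 1)
  lab <- classify_molecular(score)
  poor <- lab == "bcell_poor"
  rd <- risk_difference(sum(resp[poor & treat == "rituximab"]),
                        sum(poor & treat == "rituximab"),
                        sum(resp[poor & treat == "tocilizumab"]),
                        sum(poor & treat == "tocilizumab"))
  expect_equal(sc0$effect, rd$effect)
  expect_equal(sc0$n_poor, sum(poor))
  # empty-cell cutoffs are flagged, not fatal
  sc_flag <- cutoff_scan(score[treat == "rituximab" | score > 1],
                         resp[treat == "rituximab" | score > 1],
                         treat[treat == "rituximab" | score > 1],
                         center = 5, halfwidth = 2)
  expect_true(is.data.frame(sc_flag))
})
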
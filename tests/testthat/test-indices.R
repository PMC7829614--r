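test_that("CDAI is the sum of its four components over its full range", {
  expect_equal(cdai(0, 0, 0, 0), 0)
  expect_equal(cdai(28, 28, 10, 10), 76)
  expect_equal(cdai(11, 6, 7.5, 6.3), 30.8)
  expect_error(cdai(29, 0, 0, 0), "out of range")
  expect_error(cdai(5, 5, 11, 0), "out of range")
  expect_true(is.na(cdai(NA, 5, 5, 5)))
})

test_that("DAS28 matches hand evaluation of the published formulas", {
  expect_equal(das28(0, 0, 1, 0, "esr"), 0)
  expect_equal(das28(0, 0, 0, 0, "crp"), 0.96)
  # frozen hand evaluation: 0.56*sqrt(11)+0.28*sqrt(6)+0.70*log(31)+0.014*65
  expect_equal(das28(11, 6, 31, 65, "esr"), 5.856958, tolerance = 1e-6)
  expect_error(das28(5, 5, 0, 50, "esr"), "strictly positive")
  expect_error(das28(5, 5, -1, 50, "crp"), "non-negative")
})

test_that("DAS28 is strictly increasing in every component", {
  base <- c(tjc = 8, sjc = 5, marker = 25, gh = 50)
  for (variant in c("esr", "crp")) {
    ref <- das28(base["tjc"], base["sjc"], base["marker"], base["gh"], variant)
    for (i in seq_along(base)) {
      up <- base
      up[i] <- up[i] + 1
      expect_gt(das28(up["tjc"], up["sjc"], up["marker"], up["gh"], variant),
                ref)
    }
  }
})

test_that("EULAR categories follow the improvement and attained-level rules", {
  expect_equal(as.character(eular_response(5.0, 5.0)), "none")
  expect_equal(as.character(eular_response(6.0, 3.0)), "good")
  expect_equal(as.character(eular_response(6.5, 5.6)), "none")  # impr 0.9, >5.1
  expect_equal(as.character(eular_response(6.0, 4.0)), "moderate")
  expect_equal(as.character(eular_response(5.6, 4.9)), "moderate") # impr 0.7, <=5.1
  expect_true(is.na(eular_response(5, NA)))
})

test_that("endpoint flags honour the published thresholds and boundaries", {
  f <- endpoint_flags(30.8, 10.0, 6, 3.1, 6, 2.5)
  expect_true(f$cdai50); expect_true(f$cdai_mtr)
  expect_true(f$das28_esr_lda); expect_true(f$das28_crp_rem)
  # boundary: 10.05 <= 10.1 and 10.05 <= 10 after halving? no: 10.05 > 10
  f2 <- endpoint_flags(20, 10.05, 6, 4, 6, 4)
  expect_false(f2$cdai50)   # 10.05 > 10 = 0.5 * 20
  expect_true(f2$cdai_lda)
  f3 <- endpoint_flags(20.1, 10.05, 6, 4, 6, 4)
  expect_true(f3$cdai50); expect_true(f3$cdai_mtr)
  expect_warning(endpoint_flags(0, 0, 5, 5, 5, 5), "baseline CDAI of 0")
  expect_true(suppressWarnings(endpoint_flags(0, 0, 5, 5, 5, 5)$cdai50))
  expect_true(is.na(endpoint_flags(30, NA, 6, NA, 6, NA)$cdai50))
})

test_that("flag implications hold on random visits", {
  set.seed(4)
  bl <- runif(500, 5, 76)
  wk <- runif(500, 0, 76)
  f <- endpoint_flags(bl, wk, runif(500, 3, 8), runif(500, 0, 8),
                      runif(500, 3, 8), runif(500, 0, 8))
  expect_true(all(!f$cdai_mtr | (f$cdai50 & f$cdai_lda)))
  expect_true(all(!f$das28_esr_rem | f$das28_esr_lda))
  expect_true(all(!f$das28_crp_rem | f$das28_crp_lda))
})
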
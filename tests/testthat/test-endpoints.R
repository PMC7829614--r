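test_that("endpoint tables cover both strata and all endpoint families", {
  ds <- simulate_trial(small_config(n_patients = 250, seed = 51))
  tab <- endpoint_table(ds, stratification = "histology", population = "itt")
  expect_setequal(unique(tab$stratum), c("bcell_poor", "bcell_rich"))
  expect_equal(sum(tab$type == "binary"), 18)      # 9 endpoints x 2 strata
  expect_equal(sum(tab$type == "continuous"), 14)  # 7 endpoints x 2 strata
  ok <- !tab$flagged
  expect_true(all(tab$ci_low[ok] <= tab$effect[ok] + 1e-9))
  expect_true(all(tab$effect[ok] <= tab$ci_high[ok] + 1e-9))
  expect_true(all(tab$p_value[ok] >= 0 & tab$p_value[ok] <= 1))
  expect_true(all(tab$method[ok & tab$type == "binary"] %in%
                    c("chisq", "fisher")))
  expect_true(all(tab$method[ok & tab$type == "continuous"] %in%
                    c("ancova", "rank_ancova")))
})

test_that("the per-protocol population nests inside intention-to-treat", {
  ds <- simulate_trial(small_config(n_patients = 250, seed = 52,
                                    violation_rate = 0.2))
  itt <- endpoint_table(ds, "histology", "itt")
  pp <- endpoint_table(ds, "histology", "per_protocol")
  key <- paste(itt$endpoint, itt$stratum)
  expect_identical(key, paste(pp$endpoint, pp$stratum))
  expect_true(all(pp$n_ref <= itt$n_ref))
  expect_true(all(pp$n_alt <= itt$n_alt))
})

test_that("uniform response yields zero binary differences", {
  ds <- simulate_trial(small_config(
    n_patients = 150, seed = 53, dropout_rate = 0, missing_rate = 0,
    not_dosed_rate = 0,
    response_rates = list(rituximab = c(poor = 1, rich = 1),
                          tocilizumab = c(poor = 1, rich = 1))),
    expression = FALSE)
  tab <- endpoint_table(ds, "histology", "itt")
  prim <- tab[tab$endpoint == "cdai50" & !tab$flagged, ]
  expect_true(all(prim$effect == 0))
})

test_that("molecular stratification runs the expression pipeline end to end", {
  ds <- simulate_trial(small_config(n_patients = 200, seed = 54))
  tab <- endpoint_table(ds, stratification = "molecular")
  prim <- tab[tab$endpoint == "cdai50" & tab$stratum == "bcell_poor", ]
  expect_false(prim$flagged)
  expect_gt(prim$effect, 0)   # tocilizumab favoured in the poor stratum
})

test_that("non-responder imputation uses the full population denominator", {
  ds <- simulate_trial(small_config(n_patients = 200, seed = 55,
                                    dropout_rate = 0.3), expression = FALSE)
  ev <- endpoint_table(ds, "histology", "itt")
  nri <- endpoint_table(ds, "histology", "itt", nonresponder_imputation = TRUE)
  b_ev <- ev[ev$endpoint == "cdai50", ]
  b_nri <- nri[nri$endpoint == "cdai50", ]
  expect_true(all(b_nri$n_ref >= b_ev$n_ref))
  # unevaluable patients count as non-responders, never as responders
  expect_equal(b_nri$x_ref, b_ev$x_ref)
  expect_equal(b_nri$x_alt, b_ev$x_alt)
})

test_that("safety tables deduplicate recurrent events and match published counts", {
  # synthetic event records engineered to the published safety margins
  arms <- c(rep("rituximab", 108), rep("tocilizumab", 117))
  names(arms) <- sprintf("P%03d", seq_along(arms))
  pts <- names(arms)
  ev <- rbind(
    data.frame(patient_id = pts[c(1:76, 109:202)], term = "any",
               serious = FALSE, related = NA),
    data.frame(patient_id = pts[c(1:8, 109:120)], term = "sae",
               serious = TRUE, related = c(rep(TRUE, 4), rep(FALSE, 4),
                                           rep(TRUE, 8), rep(FALSE, 4)))
  )
  # duplicate identical events must count once
  ev <- rbind(ev, ev[1:10, ])
  tab <- safety_table(ev, arms)
  any_ae <- tab[tab$endpoint == "any_ae", ]
  expect_equal(c(any_ae$x_ref, any_ae$x_alt), c(76, 94))
  expect_equal(any_ae$effect_rounded, 10)
  expect_equal(c(any_ae$ci_low_rounded, any_ae$ci_high_rounded), c(-1, 21))
  sae <- tab[tab$endpoint == "any_sae", ]
  expect_equal(c(sae$x_ref, sae$x_alt), c(8, 12))
  expect_equal(sae$effect_rounded, 3)
  expect_equal(c(sae$ci_low_rounded, sae$ci_high_rounded), c(-5, 10))
  rel <- tab[tab$endpoint == "sae_related", ]
  expect_equal(c(rel$x_ref, rel$x_alt), c(4, 8))
})
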
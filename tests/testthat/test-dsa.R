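test_that("an empty scenario is the base case", {
  expect_equal(scenario(), base_case())
})

test_that("the 3.5%/3.5% discounting scenario reproduces the published values", {
  sc <- scenario(setting_overrides = list(discount_costs = 0.035,
                                          discount_effects = 0.035))
  expect_equal(round(sc$til$qaly, 2), 0.43)
  expect_equal(round(sc$ipi$qaly, 2), 0.37)
  expect_lt(abs(sc$til$cost - 81172), 60)
  expect_lt(abs(sc$ipi$cost - 94732), 60)
  expect_equal(sc$incremental$classification, "dominant")
})

test_that("the Portuguese ipilimumab price flips the cost difference", {
  # drug cost 2975 EUR per 50 mg -> 59500 EUR per treatment course
  sc <- scenario(param_overrides = list(ipi_cost_drug = 59500))
  expect_gt(sc$incremental$d_cost, 0)
  expect_gt(sc$incremental$d_qaly, 0)
  expect_equal(sc$incremental$classification, "icer")
})

test_that("unknown overrides are rejected by name", {
  expect_error(scenario(param_overrides = list(nope = 1)), "nope")
  expect_error(scenario(setting_overrides = list(zzz = 1)), "zzz")
})

test_that("the tornado ranks survival, failures, and treatment costs as cost drivers", {
  tor <- suppressWarnings(one_way_sa())
  top_cost <- tor$name[1:8]
  expect_true(any(grepl("_os$|_pfs$", top_cost)))
  expect_true(any(c("til_f_lab", "til_f_progression") %in% top_cost))
  expect_true(any(c("ipi_cost_drug", "til_cost_production",
                    "til_cost_hospital") %in% top_cost))

  tor_q <- suppressWarnings(one_way_sa(outcome = "qaly"))
  top_q <- tor_q$name[1:6]
  expect_true(any(grepl("_os$|_pfs$", top_q)))
  expect_true(any(c("u_stable", "u_progression") %in% top_q))
})

test_that("cost parameters never move the incremental QALYs", {
  tor <- suppressWarnings(one_way_sa())
  cost_rows <- tor[tor$group == "cost", ]
  expect_true(all(cost_rows$range_qaly < 1e-12))
  expect_true(any(cost_rows$range_cost > 0))
})

test_that("shrinking the variation fraction shrinks every range", {
  wide <- suppressWarnings(one_way_sa(fraction = 0.25))
  narrow <- one_way_sa(fraction = 0.01)
  wide <- wide[order(wide$name), ]
  narrow <- narrow[order(narrow$name), ]
  expect_true(all(narrow$range_cost <= wide$range_cost + 1e-9))
  expect_true(all(narrow$range_qaly <= wide$range_qaly + 1e-9))
  expect_error(one_way_sa(fraction = 0), "fraction")
})

test_that("probabilities scaled past one are capped with a warning", {
  expect_warning(one_way_sa(), "capped")
})

test_that("threshold prices agree with the analytic inversion of the affine cost model", {
  tbl <- builtin_table1()
  s <- model_settings()
  m <- parameter_means(tbl)
  ev <- evaluate_cohort(m, s)
  ipi_total <- 91487.50
  # treat(T) = 0.9 T + 0.1 production + 0.2 ipi_total under rerouting
  analytic_dom <- (ev$cost_ipi - ev$state_cost_til -
                     0.1 * m$til_cost_production - 0.2 * ipi_total) / 0.9
  expect_lt(abs(threshold_price(tbl, s, "dominance") - analytic_dom), 1)

  d_qaly <- ev$qaly_til - ev$qaly_ipi
  analytic_icer <- (ev$cost_ipi + 80000 * d_qaly - ev$state_cost_til -
                      0.1 * m$til_cost_production - 0.2 * ipi_total) / 0.9
  expect_lt(abs(threshold_price(tbl, s, "icer", wtp = 80000) - analytic_icer), 1)

  # without failure rerouting the slope is one
  analytic_plain <- ev$cost_ipi - ev$state_cost_til
  expect_lt(abs(threshold_price(tbl, s, "dominance", failure_rerouting = FALSE) -
                  analytic_plain), 1)
})

test_that("doubling the state costs shifts the dominance threshold by the state-cost gap", {
  tbl <- builtin_table1()
  s <- model_settings()
  ev <- evaluate_cohort(parameter_means(tbl), s)
  t1 <- threshold_price(tbl, s, "dominance")
  tbl2 <- tbl
  i <- tbl2$name %in% c("cost_stable", "cost_progression")
  tbl2$mean[i] <- 2 * tbl2$mean[i]
  tbl2$se[i] <- 2 * tbl2$se[i]
  t2 <- threshold_price(tbl2, s, "dominance")
  # linearity: the shift is (d state_cost_ipi - d state_cost_til) / 0.9
  expected_shift <- (ev$state_cost_ipi - ev$state_cost_til) / 0.9
  expect_lt(abs((t2 - t1) - expected_shift), 2)
})

test_that("a bracket without a sign change reports the bracket", {
  expect_error(threshold_price(bracket = c(0, 1000)), "bracket")
  expect_error(threshold_price(bracket = c(5, 1)), "increasing")
})
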
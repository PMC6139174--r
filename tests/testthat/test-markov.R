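test_that("the transition matrix has the reverse-engineered structure", {
  m <- build_transition_matrix(0.366, 0.175)
  expect_equal(unname(m["stable", ]), c(0.175, 0.191, 0.634))
  expect_equal(unname(m["progressive", ]), c(0, 0.366, 0.634))
  expect_equal(unname(m["dead", ]), c(0, 0, 1))
  expect_equal(unname(rowSums(m)), c(1, 1, 1), tolerance = 1e-12)

  expect_equal(unname(build_transition_matrix(1, 1)["stable", "stable"]), 1)
  everyone_dies <- build_transition_matrix(0, 0)
  expect_equal(unname(everyone_dies[, "dead"]), c(1, 1, 1))
  expect_error(build_transition_matrix(0.3, 0.5), "exceed")
  expect_error(build_transition_matrix(1.1, 0.5), "\\[0, 1\\]")
})

test_that("the cohort trace conserves the cohort and matches closed forms", {
  os <- 0.366; pfs <- 0.175
  tr <- run_trace(build_transition_matrix(os, pfs), 10)
  expect_equal(nrow(tr), 11L)
  expect_equal(tr$stable + tr$progressive + tr$dead, rep(1, 11), tolerance = 1e-10)
  expect_true(all(diff(tr$dead) >= 0))
  expect_true(all(diff(tr$stable) <= 0))
  expect_equal(unlist(tr[tr$cycle == 1, c("stable", "progressive", "dead")],
                      use.names = FALSE),
               c(0.175, 0.191, 0.634))
  # both alive states survive the year with probability os, so the alive
  # fraction at cycle t is os^t exactly
  expect_equal(tr$stable + tr$progressive, os^(0:10), tolerance = 1e-10)
  expect_equal(tr$stable, pfs^(0:10), tolerance = 1e-10)
  expect_error(run_trace(matrix(1, 2, 2), 10), "3x3")
  expect_error(run_trace(build_transition_matrix(0.5, 0.2), 0), "at least 1")
})

test_that("expected adverse-event cost reproduces the published 914.50 EUR", {
  lik <- c(0.07, 0.06, 0.06, 0.04, 0.10, 0.03)
  cost <- c(198, 580, 1115, 100, 7680, 898)
  expect_equal(expected_ae_cost(lik, cost), 914.50)
  expect_equal(expected_ae_cost(numeric(0), numeric(0)), 0)
  expect_equal(expected_ae_cost(0.5, 100), 50)
  expect_error(expected_ae_cost(1.5, 100), "\\[0, 1\\]")
  expect_error(expected_ae_cost(c(0.5, 0.5), 100), "length")
})

test_that("expected adverse-event disutility matches the hand-summed profiles", {
  ipi_lik <- c(0.07, 0.06, 0.06, 0.04, 0.10, 0.03)
  ipi_dec <- c(0.09, 0.06, 0.13, 0.10, 0.09, 0.11)  # immune -> flu-like 0.09
  expect_equal(expected_ae_disutility(ipi_lik, ipi_dec, 1), 0.0340)
  til_lik <- c(0.001, 0.001, 0.56, 0.02, 0.22, 0.44)
  til_dec <- c(0.09, 0.06, 0.13, 0.10, 0.09, 0.11)
  expect_equal(round(expected_ae_disutility(til_lik, til_dec, 1), 4), 0.1432)
  expect_equal(expected_ae_disutility(til_lik, til_dec, 0), 0)
  expect_error(expected_ae_disutility(0.5, 0.1, -1), "non-negative")
})

test_that("the composite TIL treatment cost handles failures as specified", {
  expect_equal(til_expected_treatment_cost(62000, 35500, 91487.5, 0.10, 0.10),
               77647.50)
  expect_equal(til_expected_treatment_cost(62000, 35500, 91487.5, 0, 0), 62000)
  expect_equal(til_expected_treatment_cost(62000, 35500, 91487.5, 1, 0),
               35500 + 91487.5)
  expect_error(til_expected_treatment_cost(62000, 35500, 91487.5, 0.6, 0.6),
               "f_lab \\+ f_prog")
})

test_that("the deterministic base case reproduces the published results", {
  bc <- base_case()
  expect_equal(round(bc$ipi$ly, 2), 0.58)
  expect_equal(round(bc$ipi$qaly, 2), 0.38)
  expect_lt(abs(bc$ipi$cost - 94705), 50)
  expect_equal(round(bc$til$ly, 2), 0.70)
  expect_equal(round(bc$til$qaly, 2), 0.45)
  expect_lt(abs(bc$til$cost - 81140), 50)
  expect_equal(bc$incremental$classification, "dominant")
  expect_lte(bc$til$qaly, bc$til$ly)
  expect_lte(bc$ipi$qaly, bc$ipi$ly)
  expect_equal(bc$til$treatment_cost, 77647.50)
  expect_equal(bc$ipi$treatment_cost, 91487.50)
})

test_that("undiscounted life-years equal the finite geometric sum", {
  bc <- base_case()
  geom <- function(os, h) os * (1 - os^h) / (1 - os)
  expect_equal(bc$ipi$ly, geom(0.366, 10), tolerance = 1e-10)
  expect_equal(bc$til$ly, geom(0.412, 10), tolerance = 1e-10)
})

test_that("with zero discounting and no AE duration the QALY has a closed form", {
  fx <- degenerate_fixtures()
  bc <- base_case(settings = fx$settings_zero_discount)
  t <- 1:10
  closed <- function(os, pfs, us, up) {
    us * sum(pfs^t) + up * sum(os^t - pfs^t)
  }
  expect_equal(bc$ipi$qaly, closed(0.366, 0.175, 0.85, 0.59), tolerance = 1e-10)
  expect_equal(bc$til$qaly, closed(0.412, 0.234, 0.85, 0.59), tolerance = 1e-10)
})

test_that("outcomes are monotone in utilities, survival, and costs", {
  tbl <- builtin_table1()
  bump <- function(name, strategy, delta) {
    t2 <- tbl
    i <- t2$strategy == strategy & t2$name == name
    t2$mean[i] <- t2$mean[i] + delta
    base_case(t2)
  }
  bc <- base_case(tbl)
  expect_gt(bump("u_stable", "shared", 0.05)$til$qaly, bc$til$qaly)
  expect_gt(bump("os", "til", 0.05)$til$qaly, bc$til$qaly)
  expect_gt(bump("pfs", "til", 0.05)$til$qaly, bc$til$qaly)
  expect_gt(bump("cost_progression", "shared", 1000)$til$cost, bc$til$cost)
  expect_gt(bump("cost_drug", "ipi", 1000)$ipi$cost, bc$ipi$cost)
  # the ipilimumab treatment cost also enters the TIL failure pathway
  expect_gt(bump("cost_drug", "ipi", 1000)$til$cost, bc$til$cost)
})

test_that("the vectorized accrual agrees with the explicit matrix trace", {
  s <- model_settings()
  m <- parameter_means(builtin_table1())
  ev <- evaluate_cohort(m, s)
  for (arm in c("til", "ipi")) {
    tr <- run_trace(build_transition_matrix(m[[paste0(arm, "_os")]],
                                            m[[paste0(arm, "_pfs")]]),
                    s$horizon)
    alive <- tr$stable + tr$progressive
    expect_equal(ev[[paste0("ly_", arm)]], sum(alive[-1]), tolerance = 1e-10)
    state_cost <- sum((516 * tr$stable[-1] + 9125 * tr$progressive[-1]) *
                        (1.04)^-(1:s$horizon))
    expect_equal(ev[[paste0("state_cost_", arm)]], state_cost, tolerance = 1e-8)
  }
})

test_that("incremental classification follows the sign pattern", {
  a <- list(cost = 100, qaly = 1, ly = 1)
  b <- list(cost = 200, qaly = 0.5, ly = 0.6)
  expect_equal(incremental(a, b)$classification, "dominant")
  expect_equal(incremental(b, a)$classification, "dominated")
  expect_equal(incremental(a, a)$classification, "undefined")
  up <- list(cost = 300, qaly = 1.5, ly = 1.5)
  r <- incremental(up, a)
  expect_equal(r$classification, "icer")
  expect_equal(r$icer, 200 / 0.5)
  r_ly <- incremental(up, a, effect = "ly")
  expect_equal(r_ly$icer, 200 / 0.5)
})
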
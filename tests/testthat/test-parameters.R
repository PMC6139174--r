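test_that("Beta moment matching is exact and respects the variance bound", {
  u <- beta_params_from_moments(0.5, sqrt(1 / 12))
  expect_equal(u$shape1, 1, tolerance = 1e-12)
  expect_equal(u$shape2, 1, tolerance = 1e-12)

  p <- beta_params_from_moments(0.175, 0.012)
  expect_equal(round(p$shape1, 1), 175.3)
  expect_equal(round(p$shape2, 1), 826.3)

  # analytic mean and sd of the returned Beta equal the request, for every
  # beta row of the base table
  tbl <- builtin_table1()
  betas <- tbl[tbl$distribution == "beta", ]
  for (i in seq_len(nrow(betas))) {
    sh <- beta_params_from_moments(betas$mean[i], betas$se[i])
    a <- sh$shape1; b <- sh$shape2
    expect_equal(a / (a + b), betas$mean[i], tolerance = 1e-12)
    expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), betas$se[i],
                 tolerance = 1e-12)
  }

  expect_error(beta_params_from_moments(0.5, 0.7), "no Beta")
  expect_error(beta_params_from_moments(1.2, 0.1), "strictly inside")
  expect_error(beta_params_from_moments(0.5, 0), "strictly positive")
})

test_that("Gamma moment matching is exact", {
  g <- gamma_params_from_moments(62000, 0.25)
  expect_equal(g$shape, 16)
  expect_equal(g$scale, 3875)
  expect_equal(g$shape * g$scale, 62000)
  # implied SE is mean * cv
  g2 <- gamma_params_from_moments(90100, 0.25)
  expect_equal(sqrt(g2$shape) * g2$scale, 22525)
  # mean preserved for any cv
  for (cv in c(0.1, 0.25, 0.9)) {
    g1 <- gamma_params_from_moments(1, cv)
    expect_equal(g1$shape * g1$scale, 1, tolerance = 1e-12)
  }
  expect_error(gamma_params_from_moments(-5), "positive")
  expect_error(gamma_params_from_moments(100, 0), "positive")
})

test_that("the built-in table reproduces the published treatment cost totals", {
  tbl <- builtin_table1()
  ipi <- tbl[tbl$strategy == "ipi", ]
  ae_lik <- ipi$mean[match(paste0("ae_", c("fatigue", "diarrhea", "colitis",
                                           "dyspnea", "immune", "anaemia")), ipi$name)]
  ae_cost <- ipi$mean[match(paste0("cost_ae_", c("fatigue", "diarrhea", "colitis",
                                                 "dyspnea", "immune", "anaemia")), ipi$name)]
  total_ipi <- ipi$mean[ipi$name == "cost_drug"] +
    ipi$mean[ipi$name == "cost_administration"] +
    expected_ae_cost(ae_lik, ae_cost)
  expect_equal(total_ipi, 91487.50)
  til_price <- sum(tbl$mean[tbl$strategy == "til" &
                              tbl$name %in% c("cost_production", "cost_hospital")])
  expect_equal(til_price, 62000)
  expect_silent(validate_parameter_table(tbl))
})

test_that("table validation names the offending row", {
  tbl <- builtin_table1()
  bad <- tbl
  bad$mean[bad$strategy == "ipi" & bad$name == "pfs"] <- 1.2
  expect_error(validate_parameter_table(bad), "ipi/pfs")

  dup <- rbind(tbl, tbl[tbl$strategy == "ipi" & tbl$name == "os", ])
  expect_error(validate_parameter_table(dup), "duplicate")

  missing <- tbl[!(tbl$strategy == "til" & tbl$name == "f_lab"), ]
  expect_error(validate_parameter_table(missing), "f_lab")

  wrong_dist <- tbl
  wrong_dist$distribution[wrong_dist$name == "cost_drug"] <- "beta"
  expect_error(validate_parameter_table(wrong_dist), "beta")

  loose_fixed <- tbl
  loose_fixed$se[loose_fixed$strategy == "ipi" & loose_fixed$name == "os"] <- 0
  expect_error(validate_parameter_table(loose_fixed), "fixed")

  crossed <- tbl
  crossed$mean[crossed$strategy == "til" & crossed$name == "pfs"] <- 0.5
  expect_error(validate_parameter_table(crossed), "exceeds")
})

test_that("parameter tables round-trip through CSV identically", {
  tbl <- builtin_table1()
  path <- withr::local_tempfile(fileext = ".csv")
  write_parameter_table(tbl, path)
  back <- load_parameter_table(path)
  expect_equal(back, tbl)
  expect_error(load_parameter_table(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("parameter_means lays parameters out with strategy prefixes", {
  m <- parameter_means(builtin_table1())
  expect_equal(nrow(m), 1L)
  expect_equal(m$ipi_cost_drug, 90100)
  expect_equal(m$til_os, 0.412)
  expect_equal(m$u_stable, 0.85)
  expect_equal(m$cost_progression, 9125)
})

test_that("settings are validated and round-trip through JSON", {
  s <- model_settings()
  expect_equal(s$horizon, 10L)
  expect_equal(s$discount_costs, 0.04)
  expect_equal(s$discount_effects, 0.015)
  expect_equal(s$wtp_threshold, 80000)
  path <- withr::local_tempfile(fileext = ".json")
  write_settings(s, path)
  expect_equal(load_settings(path), s)
  expect_error(model_settings(horizon = 0), "at least 1")
  expect_error(model_settings(discount_costs = -0.1), "non-negative")
  expect_error(model_settings(wtp_grid = c(5, 1)), "increasing")
})
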
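test_that("packaged baseline reproduces the registry values", {
  p <- default_parameters()
  expect_s3_class(p, "parameter_set")
  expect_equal(p$unit_costs$dental_bp_test, 117)
  expect_equal(p$unit_costs$drug_treatment_annual, 2150)
  expect_equal(p$unit_costs$post_stroke_annual, 85000)
  expect_equal(p$case_fatality_365d$ami$men, 0.144)
  expect_equal(p$case_fatality_365d$stroke$women, 0.144)
  expect_equal(p$added_mortality_post365d$stroke$men, 0.074)
  expect_equal(p$qaly_decrements$stroke_year, 0.50)
  expect_equal(p$cohort_men + p$cohort_women, p$cohort_size)
  expect_equal(p$identified_cases_screening, 170)
  expect_equal(p$identified_cases_screening_se, 17)
  expect_equal(p$sek_per_eur, 10.3)
})

test_that("validation rejects incomplete or out-of-range configurations", {
  p <- unclass(default_parameters())

  q <- p; q$discount_rate <- NULL
  expect_error(validate_parameters(q), "discount_rate")

  q <- p; q$unit_costs$ecg <- NULL
  expect_error(validate_parameters(q), "ecg")

  q <- p; q$case_fatality_365d$ami$men <- 1.3
  expect_error(validate_parameters(q), "\\[0, 1\\]")

  q <- p; q$unit_costs$lab <- -1
  expect_error(validate_parameters(q), "non-negative")

  q <- p; q$cohort_men <- 931
  expect_error(validate_parameters(q), "cohort_size")

  q <- p; q$sbp_treated_hypertensive <- 150
  expect_error(validate_parameters(q), "sbp_normotensive")

  q <- p; q$horizon_years <- 0
  expect_error(validate_parameters(q), "horizon")
})

test_that("configuration round-trips through YAML and JSON bit-for-bit", {
  p <- default_parameters()
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_parameters(p, f)
    q <- load_parameters(f)
    expect_identical(unlist(unclass(p)), unlist(unclass(q)),
                     label = paste("round-trip via", ext))
  }
})

test_that("unsupported or missing configuration files raise clear errors", {
  expect_error(load_parameters("no-such-file.yaml"), "not found")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", f)
  expect_error(load_parameters(f), "unsupported")
})

test_that("elicited distributions match their moments", {
  # the screening yield's distribution is stated directly: Normal(170, 17)
  d <- elicit_distribution(170, "normal", sd = 17)
  expect_equal(d$pars$mean, 170)
  expect_equal(d$pars$sd, 17)

  # +/-20% read as a central 95% interval: sd = 0.2 * mean / 1.96
  g <- elicit_distribution(117, "gamma", pm_fraction = 0.2)
  expect_equal(g$mean, 117)
  expect_equal(g$sd, 0.2 * 117 / qnorm(0.975))
  # moment-matching oracle: solved shape/rate reproduce (mean, sd)
  expect_equal(g$pars$shape / g$pars$rate, 117, tolerance = 1e-12)
  expect_equal(sqrt(g$pars$shape) / g$pars$rate, g$sd, tolerance = 1e-12)
  set.seed(42)
  x <- sample_distribution(g, 1e6)
  expect_lt(abs(mean(x) - 117), 3 * g$sd / sqrt(1e6))
  expect_lt(abs(sd(x) - g$sd), 0.01 * g$sd)

  b <- elicit_distribution(0.144, "beta", pm_fraction = 0.2)
  m <- b$pars$shape1 / (b$pars$shape1 + b$pars$shape2)
  expect_equal(m, 0.144, tolerance = 1e-12)
  set.seed(43)
  y <- sample_distribution(b, 1e5)
  expect_true(all(y >= 0 & y <= 1))
  expect_lt(abs(mean(y) - 0.144), 3 * b$sd / sqrt(1e5))

  u <- elicit_distribution(NA, "uniform", bounds = c(0, 0.05))
  expect_equal(u$mean, 0.025)
  expect_true(all(sample_distribution(u, 1000) <= 0.05))
})

test_that("degenerate and infeasible elicitations are handled", {
  d <- elicit_distribution(0.3, "beta", pm_fraction = 0)
  expect_identical(d$family, "fixed")
  expect_true(all(sample_distribution(d, 100) == 0.3))

  expect_error(elicit_distribution(1.3, "beta", pm_fraction = 0.2),
               "elicitation error")
  expect_error(elicit_distribution(-5, "gamma", pm_fraction = 0.2),
               "elicitation error")
  expect_error(elicit_distribution(NA, "uniform", bounds = c(1, 0)),
               "bounds")

  # infeasible beta sd shrinks with a warning, mean preserved
  expect_warning(
    w <- elicit_distribution(0.5, "beta", sd = 0.6),
    "infeasible")
  expect_equal(w$pars$shape1 / (w$pars$shape1 + w$pars$shape2), 0.5,
               tolerance = 1e-9)
})

test_that("the full PSA registry recovers its base-case means", {
  p <- default_parameters()
  dists <- psa_distributions(p)
  expect_gt(length(dists), 25)
  set.seed(7)
  for (nm in names(dists)) {
    d <- dists[[nm]]
    x <- sample_distribution(d, 2e4)
    expect_lt(abs(mean(x) - d$mean), 3 * d$sd / sqrt(2e4) + 1e-12,
              label = paste("mean recovery for", nm))
  }
})
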
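params <- default_parameters()
lt <- default_life_table()

test_that("coronary risk matches the independently expanded oracle", {
  grid <- expand.grid(sex = c("male", "female"), age = c(40, 53, 65, 74),
                      sbp = c(131, 140, 147), ratio = c(3.2, 4.0),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- annual_event_probability(
      risk_profile(g$age, g$sex, g$sbp, g$ratio), "ami",
      mi_share = c(male = 1, female = 1))  # raw coronary endpoint
    expect_lt(abs(p - oracle_chd_risk(g$sex, g$age, g$sbp, g$ratio)),
              1e-6,
              label = sprintf("|chd(%s, age %s, sbp %s) - oracle|",
                              g$sex, g$age, g$sbp))
  }
})

test_that("stroke risk reproduces a frozen hand computation", {
  # man, 60 years, SBP 147: mu = 26.5116 - 2.3741 log 60 - 2.4643 log 147,
  # sigma = exp(-0.4312), p = 1 - exp(-exp(-mu / sigma))
  mu <- 26.5116 - 2.3741 * log(60) - 2.4643 * log(147)
  p_hand <- 1 - exp(-exp((0 - mu) / exp(-0.4312)))
  p <- annual_event_probability(risk_profile(60, "male", 147, 4.0),
                                "stroke")
  expect_equal(p, p_hand, tolerance = 1e-10)
})

test_that("annual risks are probabilities, monotone in SBP, age and lipids", {
  for (sx in c("male", "female")) {
    for (ev in c("ami", "stroke")) {
      risks <- vapply(c(131, 140, 147), function(s) {
        annual_event_probability(risk_profile(55, sx, s, 4.0), ev)
      }, numeric(1))
      expect_true(all(risks > 0 & risks < 1))
      expect_true(all(diff(risks) > 0),
                  label = paste("SBP monotonicity", sx, ev))
      by_age <- vapply(c(45, 55, 65, 74), function(a) {
        annual_event_probability(risk_profile(a, sx, 147, 4.0), ev)
      }, numeric(1))
      expect_true(all(diff(by_age) > 0),
                  label = paste("age monotonicity", sx, ev))
    }
    by_ratio <- vapply(c(3.2, 4.0, 5.0), function(r) {
      annual_event_probability(risk_profile(55, sx, 147, r), "ami")
    }, numeric(1))
    expect_true(all(diff(by_ratio) > 0))
  }
})

test_that("ages beyond the equations' range are clamped with a warning", {
  expect_warning(
    p_old <- annual_event_probability(risk_profile(90, "male", 147, 4.0),
                                      "ami"),
    "clamped")
  p_74 <- annual_event_probability(risk_profile(74, "male", 147, 4.0),
                                   "ami")
  expect_equal(p_old, p_74)
})

test_that("risk profiles validate their domain", {
  expect_error(risk_profile(25, "male", 147, 4.0), "age")
  expect_error(risk_profile(55, "male", 300, 4.0), "sbp")
  expect_error(risk_profile(55, "male", 147, -1), "ratio")
  # diabetes was an exclusion criterion: always false
  expect_false(risk_profile(55, "male", 147, 4.0)$diabetic)
})

test_that("life table lookups behave at and beyond the table edges", {
  expect_gt(background_mortality(80, "male", lt),
            background_mortality(50, "male", lt))
  expect_gt(background_mortality(80, "female", lt),
            background_mortality(50, "female", lt))
  expect_equal(background_mortality(100, "male", lt), 1)
  expect_equal(background_mortality(115, "female", lt), 1)

  # exact agreement with the packaged fixture file
  csv <- read.csv(system.file("extdata", "life_table_sweden_synthetic.csv",
                              package = "bpscreen"))
  q53 <- csv$qx[csv$age == 53 & csv$sex == "male"]
  expect_identical(background_mortality(53, "male", lt), q53)
  expect_true(all(csv$qx >= 0 & csv$qx <= 1))
})

test_that("transition matrices are row-stochastic with the stated entries", {
  for (sx in c("male", "female")) {
    key <- if (sx == "male") "men" else "women"
    for (age in c(40, 53, 60, 74)) {
      for (sbp in c(131, 140, 147)) {
        P <- build_transition_matrix(risk_profile(age, sx, sbp, 4.0),
                                     params, lt)
        expect_true(all(abs(rowSums(P) - 1) < 1e-12),
                    label = sprintf("row sums %s %d %d", sx, age, sbp))
        expect_true(all(P >= 0 & P <= 1))
        # dead is absorbing
        expect_identical(unname(P["dead", ]), c(0, 0, 0, 0, 0, 1))
        # event-year fatality and post-event mortality as specified
        expect_equal(P["ami_year", "dead"],
                     params$case_fatality_365d$ami[[key]])
        expect_equal(P["stroke_year", "dead"],
                     params$case_fatality_365d$stroke[[key]])
        q <- background_mortality(age, sx, lt)
        expect_equal(P["post_stroke", "dead"],
                     min(1, q + params$added_mortality_post365d$stroke[[key]]))
        expect_equal(P["post_ami", "dead"],
                     min(1, q + params$added_mortality_post365d$ami[[key]]))
        # no recurrent or cross-track events
        expect_equal(P["post_ami", "stroke_year"], 0)
        expect_equal(P["post_stroke", "ami_year"], 0)
      }
    }
  }
})

test_that("treatment lowers the event entries of the Healthy row", {
  for (sx in c("male", "female")) {
    Pt <- build_transition_matrix(risk_profile(60, sx, 140, 4.0), params, lt)
    Pu <- build_transition_matrix(risk_profile(60, sx, 147, 4.0), params, lt)
    expect_lt(Pt["healthy", "ami_year"], Pu["healthy", "ami_year"])
    expect_lt(Pt["healthy", "stroke_year"], Pu["healthy", "stroke_year"])
  }
})

test_that("risk scales act multiplicatively and can silence all transitions", {
  P0 <- build_transition_matrix(risk_profile(60, "male", 147, 4.0), params,
                                lt, risk_scale = c(ami = 0, stroke = 0,
                                                   mortality = 0))
  expect_equal(unname(P0["healthy", ]), c(1, 0, 0, 0, 0, 0))
  P2 <- build_transition_matrix(risk_profile(60, "male", 147, 4.0), params,
                                lt, risk_scale = c(ami = 2, stroke = 1,
                                                   mortality = 1))
  P1 <- build_transition_matrix(risk_profile(60, "male", 147, 4.0), params,
                                lt)
  expect_equal(P2["healthy", "ami_year"], 2 * P1["healthy", "ami_year"])
})

test_that("impossible competing risks raise an error; certain death does not", {
  expect_error(
    build_transition_matrix(risk_profile(74, "male", 147, 4.0), params, lt,
                            risk_scale = c(ami = 500, stroke = 500,
                                           mortality = 1)),
    "exceed 1")
  # at the life table's final age death takes precedence
  P <- build_transition_matrix(risk_profile(100, "male", 147, 4.0), params,
                               lt) |> suppressWarnings()
  expect_equal(unname(P["healthy", ]), c(0, 0, 0, 0, 0, 1))
})
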
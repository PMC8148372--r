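params <- default_parameters()
lt <- default_life_table()

test_that("discounted_sum follows the cycle-0-undiscounted convention", {
  expect_equal(discounted_sum(c(3, 1, 4, 1, 5), 0), 14)
  expect_equal(discounted_sum(c(100, 100), 0.03), 100 + 100 / 1.03)
  expect_equal(discounted_sum(numeric(0), 0.03), 0)
  expect_error(discounted_sum(1:3, -0.01), ">= 0")
})

test_that("a risk-free cohort accrues the closed-form QALY annuity", {
  strata <- data.frame(count = 250, sex = "female", age = 53,
                       status = "normotensive")
  tr <- run_cohort(strata, params, lt,
                   risk_scale = c(ami = 0, stroke = 0, mortality = 0))
  annuity <- sum(1 / 1.03^(0:19))
  expect_equal(unname(tr$totals["qaly"]), 250 * annuity, tolerance = 1e-12)
  expect_equal(unname(tr$totals["cost"]), 0)
  expect_equal(unname(tr$totals["life_years"]), 250 * 20)
})

test_that("a two-cycle trace equals hand-computed matrix-vector products", {
  strata <- data.frame(count = 1, sex = "male", age = 60,
                       status = "untreated")
  tr <- run_cohort(strata, params, lt, horizon = 2)

  P0 <- build_transition_matrix(risk_profile(60, "male", 147, 4.0), params,
                                lt)
  x0 <- c(1, 0, 0, 0, 0, 0)
  x1 <- as.vector(x0 %*% P0)
  expect_equal(unname(tr$occupancy[1, , 1]), x0)
  expect_equal(unname(tr$occupancy[2, , 1]), x1)

  dec <- params$qaly_decrements
  qw <- c(1, 1 - dec$ami_year, 1 - dec$stroke_year, 1 - dec$post_ami,
          1 - dec$post_stroke, 0)
  cw <- c(0, 112000, 112000, 2670, 85000, 0)
  expect_equal(unname(tr$totals["qaly"]),
               sum(x0 * qw) + sum(x1 * qw) / 1.03, tolerance = 1e-12)
  expect_equal(unname(tr$totals["cost"]),
               sum(x0 * cw) + sum(x1 * cw) / 1.03, tolerance = 1e-12)
})

test_that("occupancy is conserved and QALYs bounded by life-years", {
  for (arm in c("screening", "no_screening")) {
    tr <- run_cohort(cohort_spec(params, arm, "all"), params, lt)
    counts <- tr$strata$count
    for (s in seq_along(counts)) {
      expect_true(all(abs(rowSums(tr$occupancy[, , s]) - counts[s]) < 1e-9),
                  label = paste("conservation", arm, "stratum", s))
      expect_true(all(tr$occupancy[, , s] >= 0))
    }
    expect_lte(tr$totals[["qaly"]], tr$totals[["life_years_disc"]] + 1e-9)
    expect_lte(tr$totals[["life_years_disc"]], tr$totals[["life_years"]])
    expect_lte(tr$totals[["life_years"]], 20 * sum(counts))
  }
})

test_that("cohort specifications split cases by the cohort sex shares", {
  cs <- cohort_spec(params, "screening", "all")
  expect_equal(sum(cs$count), 2025)
  expect_equal(sum(cs$count[cs$status == "treated"]), 170)
  cc <- cohort_spec(params, "no_screening", "all")
  expect_equal(sum(cc$count[cc$status == "treated"]), 46)
  expect_equal(sum(cc$count[cc$status == "untreated"]), 124)
  expect_equal(sum(cc$count), 2025)
  # male share of every stratum follows the cohort composition
  m <- cs$count[cs$sex == "male" & cs$status == "treated"]
  expect_equal(m, 170 * 930 / 2025)

  men <- cohort_spec(params, "screening", "men")
  expect_true(all(men$sex == "male"))
  expect_equal(sum(men$count), 2025)
})

test_that("incremental results classify dominance and demand comparability", {
  tr <- run_cohort(cohort_spec(params, "screening", "all"), params, lt)
  same <- incremental_results(tr, tr, NULL, "payer")
  expect_identical(same$tag, "undefined")
  expect_equal(same$d_cost, 0)
  expect_true(is.na(same$icer))

  short <- run_cohort(cohort_spec(params, "screening", "all"), params, lt,
                      horizon = 10)
  expect_error(incremental_results(tr, short, NULL, "payer"), "horizon")
})

test_that("the ICER scales exactly with a joint rescaling of all costs", {
  k <- 3
  base <- run_cea(params, lt, subgroups = "all", perspectives = "payer")
  uc3 <- lapply(params$unit_costs, function(x) x * k)
  scaled <- run_cea(params, lt, subgroups = "all", perspectives = "payer",
                    overrides = list(unit_costs = uc3))
  expect_equal(scaled$icer, k * base$icer, tolerance = 1e-9)
  expect_equal(scaled$d_qaly, base$d_qaly, tolerance = 1e-12)
})

test_that("the microsimulation oracle agrees with the cohort engine", {
  strata <- data.frame(count = c(600, 400), sex = c("male", "female"),
                       age = 53, status = c("untreated", "treated"))
  cohort <- run_cohort(strata, params, lt)
  per_person <- cohort$totals[c("cost", "qaly")] / sum(strata$count)
  ms <- microsim_oracle(strata, params, lt, n_rep = 5000, reps = 20,
                        seed = 99)
  for (q in c("cost", "qaly")) {
    expect_lt(abs(ms$mean[[q]] - per_person[[q]]), 3 * ms$se[[q]],
              label = paste("microsim", q))
  }
  expect_equal(ms$n_total, 1e5)
})

test_that("usage errors: horizons and arms", {
  expect_error(run_cohort(cohort_spec(params, "screening", "all"), params,
                          lt, horizon = 0), "horizon")
  expect_error(cohort_spec(params, "no_screening", "all",
                           cases_screen = 30, cases_comp_true = 46),
               "negative")
})
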
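params <- default_parameters()
scen <- build_baseline_scenario(params)

test_that("baseline volumes reproduce the published cost lines", {
  led <- arm_cost_ledger(scen, params, "screening", "payer")
  lines <- setNames(led$total, led$item)
  expect_equal(unname(lines["BP test (dental care)"]), 2025 * 117)
  expect_equal(unname(lines["BP test (dental care)"]), 236925)
  expect_equal(unname(lines["Lab tests"]), 170 * 240)
  expect_equal(unname(lines["ECG"]), 12750)
  expect_equal(unname(lines["BP test (primary care)"]), 120988)
  expect_equal(unname(lines["Fixed screening program cost"]), 165343)
  expect_equal(attr(led, "grand_total"), 710086)

  comp <- arm_cost_ledger(scen, params, "no_screening", "payer")
  clines <- setNames(comp$total, comp$item)
  expect_equal(unname(clines["ECG"]), 61 * 75)
  expect_equal(unname(clines["Lab tests"]), 14640)
  expect_equal(attr(comp, "grand_total"), 115017)

  soc <- arm_cost_ledger(scen, params, "screening", "societal")
  expect_equal(attr(soc, "grand_total"), 1732971)
  expect_equal(attr(soc, "subtotal_B"), 1022885)
  soc_c <- arm_cost_ledger(scen, params, "no_screening", "societal")
  expect_equal(attr(soc_c, "grand_total"), 145883)
})

test_that("back-derived volumes match the unit-cost arithmetic", {
  s <- scen$screening
  expect_equal(s$phc_bp_visits, 120988 / 149)
  expect_equal(s$hours_home, 656320 / 160)
  expect_equal(s$hours_dental, 1012.5)
  expect_equal(s$trips, 9685 / 6.5)
  expect_equal(scen$no_screening$phc_bp_visits, 47978 / 149)
  expect_equal(scen$no_screening$dental_bp_tests, 0)
  expect_equal(scen$no_screening$admin_units, 0)
})

test_that("an empty cascade still carries the fixed administration cost", {
  empty <- scen
  for (f in setdiff(names(empty$screening), "admin_units")) {
    empty$screening[[f]] <- 0
  }
  led <- arm_cost_ledger(empty, params, "screening", "payer")
  expect_equal(attr(led, "grand_total"), 165343)
})

test_that("cost per identified case matches the published ratios", {
  st <- short_term_analysis(params)
  pay <- st$per_case$payer
  expect_equal(pay$delta_cost, 595069)
  expect_equal(pay$delta_cases, 124)
  expect_equal(round(pay$incremental_per_case), 4799)
  expect_equal(round(pay$within_arm[["screening"]]), 4177)
  expect_equal(round(pay$within_arm[["no_screening"]]), 2500)

  soc <- st$per_case$societal
  expect_equal(soc$delta_cost, 1587088)
  expect_equal(round(soc$incremental_per_case), 12799)
})

test_that("identical arms yield a tagged undefined ratio, not an error", {
  a <- arm_cost_ledger(scen, params, "screening", "payer")
  res <- cost_per_identified_case(a, a, 170, 170)
  expect_identical(res$tag, "undefined")
  expect_true(is.na(res$incremental_per_case))
  expect_equal(res$delta_cost, 0)
})

test_that("ledger additivity and perspective monotonicity hold", {
  for (arm in c("screening", "no_screening")) {
    pay <- arm_cost_ledger(scen, params, arm, "payer")
    soc <- arm_cost_ledger(scen, params, arm, "societal")
    expect_equal(attr(pay, "grand_total"), sum(pay$total))
    expect_equal(attr(soc, "grand_total"), sum(soc$total))
    expect_gte(attr(soc, "grand_total"), attr(pay, "grand_total"))
    expect_true(all(abs(pay$total - pay$volume * pay$unit_cost) < 1e-9))
  }
  # random non-negative rescalings preserve both properties
  set.seed(11)
  for (i in 1:5) {
    sc <- scen
    for (f in names(sc$screening)) {
      sc$screening[[f]] <- sc$screening[[f]] * runif(1, 0, 3)
    }
    pay <- arm_cost_ledger(sc, params, "screening", "payer")
    soc <- arm_cost_ledger(sc, params, "screening", "societal")
    expect_gte(attr(soc, "grand_total"), attr(pay, "grand_total"))
    expect_equal(attr(soc, "grand_total"), sum(soc$total))
  }
})

test_that("case-driven volumes scale linearly; fixed lines do not", {
  double <- build_baseline_scenario(params, cases_screen = 340,
                                    cases_comp = 122)
  expect_equal(double$screening$ecg, 340)
  expect_equal(double$screening$phc_bp_visits, 2 * 812)
  expect_equal(double$screening$trips, 2 * 1490)
  expect_equal(double$screening$dental_bp_tests, 2025)  # whole cohort
  expect_equal(double$screening$admin_units, scen$screening$admin_units)
  expect_equal(double$no_screening$lab, 122)
})

test_that("usage errors are reported", {
  expect_error(arm_cost_ledger(scen, params, "both", "payer"))
  expect_error(arm_cost_ledger(scen, params, "screening", "insurer"))
  expect_error(build_baseline_scenario(params, cases_screen = -1),
               "non-negative")
})
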
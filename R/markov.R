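#' @title 20-year Markov cohort model
#'
#' @description
#' The long-term model follows the cohort through six health states —
#' Healthy, AMI-year, Stroke-year, Post-AMI, Post-Stroke, Dead — over annual
#' cycles, accruing state costs and QALY weights, both discounted at the
#' registry rate. Everyone starts Healthy; event risks are re-evaluated each
#' cycle at the cohort's current age. The screening and no-screening arms
#' differ only in how many hypertensives receive treatment (treated
#' hypertensives sit at the treated blood-pressure level and accrue the
#' annual drug cost while alive).
#'
#' @name markov
NULL

#' Discounted sum of a per-cycle stream
#'
#' \eqn{\sum_t x_t / (1 + r)^t} with cycle 0 undiscounted (discounting starts
#' at cycle 1).
#'
#' @param stream Numeric vector, cycle 0 first.
#' @param rate Annual discount rate (>= 0).
#' @return Scalar.
#' @export
#' @examples
#' discounted_sum(c(100, 100), 0.03)  # 100 + 100/1.03
discounted_sum <- function(stream, rate) {
  if (rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  if (!length(stream)) return(0)
  sum(stream / (1 + rate)^(seq_along(stream) - 1))
}

#' Build the cohort strata for one arm
#'
#' Hypertensive cases are split between the sexes in proportion to the
#' cohort's sex composition (all-male or all-female under the subgroup
#' scenarios, which keep the total cohort size). The screening arm treats
#' all identified cases; the comparator treats only the opportunistically
#' identified ones and leaves the remainder untreated. Comparator white-coat
#' false positives accrue no drug cost and are not modelled as a separate
#' stratum. Both arms share an identical normotensive remainder.
#'
#' @param params A `parameter_set`.
#' @param arm `"screening"` or `"no_screening"`.
#' @param subgroup `"all"`, `"men"` or `"women"`.
#' @param cases_screen Identified (and treated) cases under screening;
#'   default 170.
#' @param cases_comp_true True positives treated in the comparator arm;
#'   default 46. The comparator's untreated hypertensives are
#'   `cases_screen - cases_comp_true`.
#' @return A `cohort_spec` data frame with columns `count`, `sex`, `age`,
#'   `status` (`normotensive`, `treated`, `untreated`).
#' @export
cohort_spec <- function(params, arm = c("screening", "no_screening"),
                        subgroup = c("all", "men", "women"),
                        cases_screen = params$identified_cases_screening,
                        cases_comp_true =
                          params$identified_cases_comparator_true) {
  arm <- match.arg(arm)
  subgroup <- match.arg(subgroup)
  n <- params$cohort_size
  share <- switch(subgroup,
    all   = c(male = params$cohort_men / n, female = params$cohort_women / n),
    men   = c(male = 1, female = 0),
    women = c(male = 0, female = 1))

  counts <- if (arm == "screening") {
    c(treated = cases_screen, untreated = 0)
  } else {
    c(treated = cases_comp_true,
      untreated = cases_screen - cases_comp_true)
  }
  counts["normotensive"] <- n - sum(counts)
  if (any(counts < 0)) {
    stop("inconsistent case counts: negative stratum size", call. = FALSE)
  }
  out <- expand.grid(sex = c("male", "female"),
                     status = c("normotensive", "treated", "untreated"),
                     stringsAsFactors = FALSE)
  out$count <- counts[out$status] * share[out$sex]
  out$age <- params$start_age
  out <- out[out$count > 0, c("count", "sex", "age", "status")]
  rownames(out) <- NULL
  structure(out, class = c("cohort_spec", "data.frame"), arm = arm,
            subgroup = subgroup)
}

# systolic BP by hypertension/treatment status
.sbp_for_status <- function(params, status) {
  switch(status,
    normotensive = params$sbp_normotensive,
    treated      = params$sbp_treated_hypertensive,
    untreated    = params$sbp_untreated_hypertensive,
    stop("unknown status: ", status, call. = FALSE))
}

#' Run the Markov cohort model
#'
#' Traces state occupancy for every stratum over the horizon, accruing
#' per-cycle costs (acute and chronic event-state costs; the annual drug
#' cost for treated strata while alive) and QALYs (weight 1 for Healthy
#' minus the registry decrements; 0 when Dead). Cycle-0 accruals are
#' undiscounted; discounting starts at cycle 1. No half-cycle correction is
#' applied by default.
#'
#' @param strata A `cohort_spec` (or any data frame with `count`, `sex`,
#'   `age`, `status`).
#' @param params A `parameter_set`.
#' @param table A `life_table`; defaults to the packaged one.
#' @param horizon Number of annual cycles (default: registry).
#' @param discount Annual discount rate (default: registry).
#' @param risk_scale Named multipliers (`ami`, `stroke`, `mortality`) passed
#'   to [build_transition_matrix()].
#' @param overrides Optional list overriding sampled registry entries
#'   (`case_fatality_365d`, `added_mortality_post365d`, `qaly_decrements`,
#'   `unit_costs`); used by the sensitivity analyses.
#' @param half_cycle Apply a half-cycle correction (average of start- and
#'   end-of-cycle occupancy)? Default `FALSE`, the convention of annual-cycle
#'   spreadsheet cohort models.
#' @return A `state_trace`: list with `occupancy` (cycle x state x stratum
#'   array), `streams` (per-cycle cost and QALY, raw and discounted),
#'   `totals` (discounted cost, QALYs, life-years), `events` (expected
#'   incident AMIs and strokes) and the run settings.
#' @export
run_cohort <- function(strata, params, table = default_life_table(),
                       horizon = params$horizon_years,
                       discount = params$discount_rate,
                       risk_scale = c(ami = 1, stroke = 1, mortality = 1),
                       overrides = NULL, half_cycle = FALSE) {
  if (horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  if (!is.null(overrides)) params <- .apply_overrides(params, overrides)
  dec <- params$qaly_decrements
  qw <- c(1, 1 - dec$ami_year, 1 - dec$stroke_year,
          1 - dec$post_ami, 1 - dec$post_stroke, 0)
  uc <- params$unit_costs
  cw <- c(0, uc$ami_first_year, uc$stroke_first_year,
          uc$post_ami_annual, uc$post_stroke_annual, 0)
  drug <- uc$drug_treatment_annual

  ns <- nrow(strata)
  occ <- array(0, dim = c(horizon, 6, ns),
               dimnames = list(NULL, .states, NULL))
  cost_cycle <- qaly_cycle <- ly_cycle <- numeric(horizon)
  events <- c(ami = 0, stroke = 0)

  for (s in seq_len(ns)) {
    count <- strata$count[s]
    sx <- strata$sex[s]
    a0 <- strata$age[s]
    treated <- strata$status[s] == "treated"
    sbp <- .sbp_for_status(params, strata$status[s])
    ratio <- params$tc_hdl_ratio[[if (sx == "male") "men" else "women"]]
    x <- c(count, 0, 0, 0, 0, 0)
    for (t in seq_len(horizon)) {
      occ[t, , s] <- x
      P <- build_transition_matrix(
        risk_profile(min(a0 + t - 1, 100), sx, sbp, ratio),
        params, table, risk_scale)
      x_next <- as.vector(x %*% P)
      w <- if (half_cycle) (x + x_next) / 2 else x
      alive <- sum(w[1:5])
      qaly_cycle[t] <- qaly_cycle[t] + sum(w * qw)
      ly_cycle[t] <- ly_cycle[t] + alive
      cost_cycle[t] <- cost_cycle[t] + sum(w * cw) +
        if (treated) drug * alive else 0
      events["ami"] <- events["ami"] + x[1] * P["healthy", "ami_year"]
      events["stroke"] <- events["stroke"] + x[1] * P["healthy", "stroke_year"]
      x <- x_next
    }
  }

  df <- (1 + discount)^(-(seq_len(horizon) - 1))
  streams <- data.frame(
    cycle = seq_len(horizon) - 1L,
    cost = cost_cycle, qaly = qaly_cycle, life_years = ly_cycle,
    cost_disc = cost_cycle * df, qaly_disc = qaly_cycle * df)
  structure(list(
    occupancy = occ, strata = strata, streams = streams,
    totals = c(cost = sum(streams$cost_disc),
               qaly = sum(streams$qaly_disc),
               life_years_disc = discounted_sum(ly_cycle, discount),
               life_years = sum(ly_cycle)),
    events = events, horizon = horizon, discount = discount),
    class = "state_trace")
}

# replace registry entries named in `overrides` (nested lists merged shallowly)
.apply_overrides <- function(params, overrides) {
  p <- unclass(params)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(p[[nm]])) {
      p[[nm]] <- utils::modifyList(p[[nm]], overrides[[nm]])
    } else {
      p[[nm]] <- overrides[[nm]]
    }
  }
  structure(p, class = "parameter_set")
}

#' @export
print.state_trace <- function(x, ...) {
  cat(sprintf("<state_trace> %d strata, %d cycles, discount %.1f%%\n",
              dim(x$occupancy)[3], x$horizon, 100 * x$discount))
  cat(sprintf("  discounted totals: cost %s SEK, QALYs %.2f\n",
              format(round(x$totals["cost"]), big.mark = ","),
              x$totals["qaly"]))
  cat(sprintf("  expected events: %.2f AMI, %.2f stroke\n",
              x$events["ami"], x$events["stroke"]))
  invisible(x)
}

#' Incremental cost-effectiveness from two cohort traces
#'
#' Combines the long-term care-cost difference with the short-term programme
#' cost of the chosen perspective, takes the QALY difference from the
#' traces, and classifies dominance: `"normal"` (positive cost, positive
#' QALYs), `"dominant"` (cheaper and better), `"dominated"` (dearer and
#' worse), `"undefined"` (no QALY difference).
#'
#' @param screen,comp `state_trace` objects (identical horizon/discount).
#' @param short_term A `short_term_results` object (or `NULL` to include no
#'   programme cost).
#' @param perspective `"payer"` or `"societal"`.
#' @param subgroup Label carried into the result.
#' @return A `ce_result` data frame row: `subgroup`, `perspective`,
#'   `d_cost`, `d_qaly`, `icer`, `tag`.
#' @export
incremental_results <- function(screen, comp, short_term = NULL,
                                perspective = c("payer", "societal"),
                                subgroup = "all") {
  stopifnot(inherits(screen, "state_trace"), inherits(comp, "state_trace"))
  perspective <- match.arg(perspective)
  if (screen$horizon != comp$horizon ||
      !isTRUE(all.equal(screen$discount, comp$discount))) {
    stop("traces must share horizon and discount rate", call. = FALSE)
  }
  st <- if (is.null(short_term)) 0 else .short_term_delta(short_term,
                                                          perspective)
  d_cost <- unname(screen$totals["cost"] - comp$totals["cost"] + st)
  d_qaly <- unname(screen$totals["qaly"] - comp$totals["qaly"])
  tag <- if (d_qaly == 0) {
    "undefined"
  } else if (d_qaly > 0 && d_cost >= 0) {
    "normal"
  } else if (d_qaly > 0) {
    "dominant"
  } else {
    "dominated"
  }
  icer <- if (tag == "normal") d_cost / d_qaly else NA_real_
  structure(data.frame(subgroup = subgroup, perspective = perspective,
                       d_cost = d_cost, d_qaly = d_qaly, icer = icer,
                       tag = tag, stringsAsFactors = FALSE),
            class = c("ce_result", "data.frame"))
}

#' Run the full cost-effectiveness comparison
#'
#' The package's main driver: runs both arms of the Markov model for each
#' requested subgroup, attaches the short-term programme cost, and returns
#' one `ce_result` row per subgroup x perspective — the analogue of the
#' published long-term results table.
#'
#' @param params A `parameter_set`.
#' @param table A `life_table`.
#' @param subgroups Subset of `c("all", "men", "women")`.
#' @param perspectives Subset of `c("payer", "societal")`.
#' @param horizon,discount Override the registry horizon or discount rate.
#' @param cases_screen,cases_comp_true Override the screening yield (the
#'   hypertension-prevalence sensitivity axis scales these).
#' @param risk_scale,overrides,half_cycle Passed to [run_cohort()].
#' @return A `cea_results` data frame (one row per subgroup x perspective)
#'   with the incremental events as attribute `events`.
#' @export
#' @examples
#' \donttest{
#' run_cea(subgroups = "all", perspectives = "payer")
#' }
run_cea <- function(params = default_parameters(),
                    table = default_life_table(),
                    subgroups = c("all", "men", "women"),
                    perspectives = c("payer", "societal"),
                    horizon = params$horizon_years,
                    discount = params$discount_rate,
                    cases_screen = params$identified_cases_screening,
                    cases_comp_true =
                      params$identified_cases_comparator_true,
                    risk_scale = c(ami = 1, stroke = 1, mortality = 1),
                    overrides = NULL, half_cycle = FALSE) {
  scale <- cases_screen / params$identified_cases_screening
  scen <- build_baseline_scenario(
    params, cases_screen = cases_screen,
    cases_comp = params$comparator_total_diagnosed * scale)
  st_params <- if (is.null(overrides)) params else
    .apply_overrides(params, overrides)
  st <- short_term_analysis(st_params, scen)

  rows <- list()
  events <- list()
  for (sg in subgroups) {
    tr <- lapply(c("screening", "no_screening"), function(arm) {
      run_cohort(cohort_spec(params, arm, sg, cases_screen,
                             cases_comp_true),
                 params, table, horizon = horizon, discount = discount,
                 risk_scale = risk_scale, overrides = overrides,
                 half_cycle = half_cycle)
    })
    events[[sg]] <- tr[[2]]$events - tr[[1]]$events  # avoided by screening
    for (pp in perspectives) {
      rows[[paste(sg, pp)]] <-
        incremental_results(tr[[1]], tr[[2]], st, pp, sg)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("cea_results", "data.frame"),
            events = events, short_term = st)
}

#' @export
print.cea_results <- function(x, ...) {
  cat("<cea_results> incremental cost-effectiveness, screening vs none\n")
  df <- as.data.frame(x)
  # costs rounded to the nearest 100,000 SEK for display, as in the source
  df$d_cost <- sprintf("%.1fM", round(df$d_cost, -5) / 1e6)
  df$d_qaly <- sprintf("%.2f", df$d_qaly)
  df$icer <- ifelse(is.na(df$icer), "-",
                    sprintf("%.1fM/QALY", round(df$icer, -5) / 1e6))
  print(df, row.names = FALSE)
  invisible(x)
}
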
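#' @title Parameter registry for the screening cost-effectiveness model
#'
#' @description
#' Every model input — unit costs (2019 SEK), transition inputs, QALY
#' decrements, modelling assumptions, discount rate and horizon — lives in a
#' single validated `parameter_set` object. The packaged default
#' (`table1_baseline.yaml`) holds the base-case values; [load_parameters()]
#' reads a YAML or JSON configuration with the same keys.
#'
#' @name parameters
NULL

#' Default model parameters (base case)
#'
#' Returns the packaged base-case parameter registry: a cohort of 2,025
#' previously unscreened 40-75-year-olds (930 men, 1,095 women), unit costs in
#' 2019 SEK, sex-specific 365-day case fatality and post-event added mortality
#' for AMI and stroke, QALY-weight decrements, mean systolic blood pressure by
#' hypertension status (147 untreated / 140 treated / 131 normotensive),
#' total-cholesterol/HDL ratios, screening yield (170 identified cases,
#' standard error 17) and the opportunistic comparator (46 true + 15 false
#' positives), a 20-year horizon and 3% annual discounting.
#'
#' @return A `parameter_set` object (validated named list).
#' @seealso [load_parameters()], [validate_parameters()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$unit_costs$dental_bp_test
default_parameters <- function() {
  path <- system.file("extdata", "table1_baseline.yaml", package = "bpscreen")
  load_parameters(path)
}

#' Load and validate model parameters from a configuration file
#'
#' Reads a flat YAML or JSON document whose keys mirror the fields of the
#' packaged baseline (see [default_parameters()]). Missing fields raise a
#' configuration error naming the field; out-of-range values raise a
#' validation error.
#'
#' @param config Path to a `.yaml`/`.yml` or `.json` file, or a named list
#'   with the same structure. `NULL` returns the packaged baseline.
#' @return A `parameter_set` object.
#' @export
load_parameters <- function(config = NULL) {
  if (is.null(config)) return(default_parameters())
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("configuration file not found: ", config, call. = FALSE)
    }
    ext <- tolower(tools::file_ext(config))
    raw <- switch(ext,
      yaml = ,
      yml  = yaml::read_yaml(config),
      json = jsonlite::fromJSON(config, simplifyVector = TRUE),
      stop("unsupported configuration format '.", ext,
           "' (use YAML or JSON)", call. = FALSE)
    )
  } else if (is.list(config)) {
    raw <- config
  } else {
    stop("`config` must be a file path, a list, or NULL", call. = FALSE)
  }
  validate_parameters(raw)
}

# fields every configuration must provide
.required_fields <- c(
  "cohort_size", "cohort_men", "cohort_women", "start_age",
  "discount_rate", "horizon_years", "sek_per_eur",
  "unit_costs", "case_fatality_365d", "added_mortality_post365d",
  "qaly_decrements", "sbp_untreated_hypertensive",
  "sbp_treated_hypertensive", "sbp_normotensive", "tc_hdl_ratio",
  "identified_cases_screening", "identified_cases_screening_se",
  "identified_cases_comparator_true", "comparator_false_positives",
  "comparator_total_diagnosed", "mi_share"
)

.cost_items <- c(
  "dental_bp_test", "phc_bp_test", "ecg", "lab", "diagnosis",
  "screening_admin", "ami_first_year", "post_ami_annual",
  "stroke_first_year", "post_stroke_annual", "drug_treatment_annual",
  "patient_time_hour", "patient_travel_trip"
)

#' Validate a raw parameter list
#'
#' Checks completeness (every required field present), probability and cost
#' ranges, cohort additivity (men + women = cohort size) and the ordering of
#' the systolic blood-pressure assumptions
#' (normotensive < treated < untreated).
#'
#' @param raw Named list of parameter values.
#' @return The validated list with class `parameter_set`.
#' @export
validate_parameters <- function(raw) {
  missing <- setdiff(.required_fields, names(raw))
  if (length(missing)) {
    stop("configuration error: missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  missing_costs <- setdiff(.cost_items, names(raw$unit_costs))
  if (length(missing_costs)) {
    stop("configuration error: missing unit cost(s): ",
         paste(missing_costs, collapse = ", "), call. = FALSE)
  }

  chk_prob <- function(x, what) {
    v <- unlist(x)
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      stop("validation error: ", what, " must lie in [0, 1]", call. = FALSE)
    }
  }
  chk_prob(raw$case_fatality_365d, "case_fatality_365d")
  chk_prob(raw$added_mortality_post365d, "added_mortality_post365d")
  chk_prob(raw$qaly_decrements, "qaly_decrements")
  chk_prob(raw$discount_rate, "discount_rate")

  costs <- unlist(raw$unit_costs)
  if (any(!is.finite(costs)) || any(costs < 0)) {
    stop("validation error: unit costs must be non-negative", call. = FALSE)
  }
  if (raw$horizon_years < 1) {
    stop("validation error: horizon_years must be >= 1", call. = FALSE)
  }
  if (raw$cohort_men + raw$cohort_women != raw$cohort_size) {
    stop("validation error: cohort_men + cohort_women must equal cohort_size",
         call. = FALSE)
  }
  if (!(raw$sbp_normotensive < raw$sbp_treated_hypertensive &&
        raw$sbp_treated_hypertensive < raw$sbp_untreated_hypertensive)) {
    stop("validation error: require sbp_normotensive < sbp_treated",
         "_hypertensive < sbp_untreated_hypertensive", call. = FALSE)
  }
  structure(raw, class = "parameter_set")
}

#' Serialize a parameter set back to YAML or JSON
#'
#' Round-trip companion of [load_parameters()]: `load_parameters(
#' write_parameters(p, f))` reproduces every value of `p`.
#'
#' @param params A `parameter_set`.
#' @param path Output file; the extension (`.yaml`/`.yml`/`.json`) selects
#'   the format.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "parameter_set"))
  x <- unclass(params)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml  = yaml::write_yaml(x, path, precision = 15),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported format '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat(sprintf("  cohort: %d (%d men, %d women), start age %s\n",
              x$cohort_size, x$cohort_men, x$cohort_women, x$start_age))
  cat(sprintf("  horizon: %d years, discount %.1f%%\n",
              x$horizon_years, 100 * x$discount_rate))
  cat(sprintf("  screening yield: %d cases (SE %s); comparator %d true + %d false\n",
              x$identified_cases_screening, x$identified_cases_screening_se,
              x$identified_cases_comparator_true, x$comparator_false_positives))
  cat(sprintf("  unit costs (SEK): %s ...\n",
              paste(utils::head(paste0(names(x$unit_costs), "=",
                                       unlist(x$unit_costs)), 4),
                    collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# distribution elicitation for the probabilistic sensitivity analysis

#' Elicit a sampling distribution from a point value and uncertainty range
#'
#' Converts the registry's point value plus uncertainty statement into a
#' parametric sampling distribution by moment matching. A symmetric
#' "+/- fraction" range (the registry's pervasive +/-20%) is read as a central
#' 95% interval, so `sd = fraction * point / 1.96`. Gamma and beta parameters
#' are solved from (mean, sd); if the requested sd is infeasible for a beta
#' mean, the sd is shrunk to 99% of the feasible maximum with a warning.
#'
#' @param point Base-case value; must lie inside the family's support.
#' @param family One of `"beta"`, `"gamma"`, `"normal"`, `"uniform"`,
#'   `"fixed"`.
#' @param pm_fraction Half-width of the symmetric relative range (e.g. `0.2`
#'   for +/-20%), interpreted as a central 95% interval. Used by beta, gamma
#'   and normal when `sd` is not given.
#' @param sd Standard deviation, given directly (e.g. the screening yield's
#'   standard error of 17).
#' @param bounds Length-2 numeric `c(low, high)`; required for `"uniform"`.
#' @return A `distribution_spec`: list with `family`, `mean`, `sd` and the
#'   solved natural parameters.
#' @export
#' @examples
#' elicit_distribution(170, "normal", sd = 17)
#' elicit_distribution(117, "gamma", pm_fraction = 0.2)
elicit_distribution <- function(point,
                                family = c("beta", "gamma", "normal",
                                           "uniform", "fixed"),
                                pm_fraction = NULL, sd = NULL,
                                bounds = NULL) {
  family <- match.arg(family)
  if (family == "uniform") {
    if (is.null(bounds) || length(bounds) != 2L || bounds[1] > bounds[2]) {
      stop("elicitation error: uniform requires bounds = c(low, high)",
           call. = FALSE)
    }
    spec <- list(family = "uniform", mean = mean(bounds),
                 sd = diff(bounds) / sqrt(12),
                 pars = list(min = bounds[1], max = bounds[2]))
    return(structure(spec, class = "distribution_spec"))
  }
  if (family == "fixed" ||
      (!is.null(pm_fraction) && pm_fraction == 0) ||
      (!is.null(sd) && sd == 0)) {
    spec <- list(family = "fixed", mean = point, sd = 0,
                 pars = list(value = point))
    return(structure(spec, class = "distribution_spec"))
  }
  if (is.null(sd)) {
    if (is.null(pm_fraction)) {
      stop("elicitation error: give either `sd` or `pm_fraction`",
           call. = FALSE)
    }
    # +/- fraction read as a central 95% interval
    sd <- pm_fraction * point / stats::qnorm(0.975)
  }
  pars <- switch(family,
    normal = list(mean = point, sd = sd),
    gamma = {
      if (point <= 0) {
        stop("elicitation error: gamma requires point > 0", call. = FALSE)
      }
      list(shape = (point / sd)^2, rate = point / sd^2)
    },
    beta = {
      if (point <= 0 || point >= 1) {
        stop("elicitation error: beta requires point in (0, 1)",
             call. = FALSE)
      }
      sd_max <- sqrt(point * (1 - point))
      if (sd >= sd_max) {
        warning("beta sd infeasible for mean ", point,
                "; shrunk to 99% of the feasible maximum", call. = FALSE)
        sd <- 0.99 * sd_max
      }
      nu <- point * (1 - point) / sd^2 - 1
      list(shape1 = point * nu, shape2 = (1 - point) * nu)
    }
  )
  structure(list(family = family, mean = point, sd = sd, pars = pars),
            class = "distribution_spec")
}

#' Draw samples from an elicited distribution
#'
#' @param spec A `distribution_spec` from [elicit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`; the empirical mean converges to the
#'   base-case point value.
#' @export
sample_distribution <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "distribution_spec"))
  p <- spec$pars
  switch(spec$family,
    fixed   = rep(p$value, n),
    normal  = stats::rnorm(n, p$mean, p$sd),
    gamma   = stats::rgamma(n, shape = p$shape, rate = p$rate),
    beta    = stats::rbeta(n, p$shape1, p$shape2),
    uniform = stats::runif(n, p$min, p$max)
  )
}

#' @export
print.distribution_spec <- function(x, ...) {
  cat(sprintf("<distribution_spec> %s(mean = %g, sd = %g)\n",
              x$family, x$mean, x$sd))
  invisible(x)
}

#' Assemble the full set of PSA sampling distributions
#'
#' Builds the joint sampling specification the probabilistic sensitivity
#' analysis uses: gamma (+/-20% as a 95% interval) for every unit cost, beta
#' (+/-20%) for case fatality, added mortality and QALY decrements, a normal
#' for the number of identified cases (mean 170, SE 17), and mean-1 gamma
#' hazard-scale factors (+/-20%) for the Framingham event risks and the
#' life-table background mortality. Cohort sizes and the discount rate are
#' fixed and never sampled.
#'
#' @param params A `parameter_set`.
#' @return Named list of `distribution_spec` objects.
#' @export
psa_distributions <- function(params) {
  d <- list()
  for (item in .cost_items) {
    d[[paste0("cost.", item)]] <-
      elicit_distribution(params$unit_costs[[item]], "gamma",
                          pm_fraction = 0.2)
  }
  for (ev in c("ami", "stroke")) {
    for (sx in c("men", "women")) {
      d[[paste0("cf.", ev, ".", sx)]] <-
        elicit_distribution(params$case_fatality_365d[[ev]][[sx]], "beta",
                            pm_fraction = 0.2)
      d[[paste0("added.", ev, ".", sx)]] <-
        elicit_distribution(params$added_mortality_post365d[[ev]][[sx]],
                            "beta", pm_fraction = 0.2)
    }
  }
  for (dec in names(params$qaly_decrements)) {
    d[[paste0("dec.", dec)]] <-
      elicit_distribution(params$qaly_decrements[[dec]], "beta",
                          pm_fraction = 0.2)
  }
  d$cases_screening <-
    elicit_distribution(params$identified_cases_screening, "normal",
                        sd = params$identified_cases_screening_se)
  d$risk_scale.ami        <- elicit_distribution(1, "gamma", pm_fraction = 0.2)
  d$risk_scale.stroke     <- elicit_distribution(1, "gamma", pm_fraction = 0.2)
  d$risk_scale.mortality  <- elicit_distribution(1, "gamma", pm_fraction = 0.2)
  d
}

#' Convert 2019 SEK to euro
#'
#' Reporting-time currency conversion at the fixed study exchange rate
#' (1 EUR = 10.3 SEK); all internal accounting stays in SEK.
#'
#' @param sek Amount in SEK.
#' @param rate SEK per EUR.
#' @return Amount in EUR.
#' @export
sek_to_eur <- function(sek, rate = 10.3) sek / rate
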
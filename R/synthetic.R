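#' @title Synthetic cohort and screening-cascade generator
#'
#' @description
#' Emulates the screening study so every downstream stage can be exercised
#' without external data: an individual roster with the study's demographics
#' (2,025 persons, 930 men and 1,095 women, ages normal (52.8, 8.7)
#' truncated to 40-75) and a stochastic two-step cascade — office blood
#' pressure at the dental visit (positive at >= 140 mmHg systolic), one week
#' of home measurement (positive at >= 135 mmHg), then referral to a primary
#' health-care centre where only true hypertensives are diagnosed. White-coat
#' hypertension (elevated office but normal home pressure, 25% of
#' normotensives) generates office false positives of which the home step
#' removes about 86%. The comparator arm receives opportunistic detection
#' (3% of the cohort diagnosed, 25% of those white-coat false positives).
#'
#' Generated systolic pressures are the status means of the registry (147
#' hypertensive / 131 normotensive) plus measurement noise; home readings run
#' 5 mmHg below office level, mirroring the 140/135 threshold offset. The
#' office and home noise standard deviations are tuning constants chosen so
#' the cascade's operating characteristics match the study (86% false-
#' positive reduction; positive predictive value about 0.76 at referral);
#' they are not study measurements.
#'
#' @name synthetic
NULL

# cascade noise model (tuning constants, see vignette)
.cascade_defaults <- list(
  office_sd = 4,      # sd of the two-reading office mean, mmHg
  home_sd = 8.33,     # sd of the one-week home mean around its level, mmHg
  wc_elevation = 13,  # office-only elevation of white-coat individuals, mmHg
  home_offset = 5,    # home readings run this much below office level, mmHg
  wc_rate = 0.25      # white-coat share among normotensives
)

#' Analytic expectations of the screening cascade
#'
#' Closed-form expected counts under the generator's normal noise model:
#' office positives, referrals (office and home positive) and confirmed true
#' positives, plus the two step-level sensitivities and the expected
#' positive predictive value at referral.
#'
#' @param n Cohort size.
#' @param prevalence Undetected-hypertension prevalence; `NULL` uses the
#'   package default (calibrated so expected confirmed cases are 170 of
#'   2,025; see [default_prevalence()]).
#' @param params A `parameter_set` (blood-pressure levels).
#' @param thresholds Named vector `c(office = , home = )`, mmHg systolic.
#' @param noise List overriding the cascade noise constants.
#' @return Named list of expectations.
#' @export
cascade_expectations <- function(n = 2025, prevalence = NULL,
                                 params = default_parameters(),
                                 thresholds = c(office = 140, home = 135),
                                 noise = list()) {
  nz <- utils::modifyList(.cascade_defaults, noise)
  hyper <- params$sbp_untreated_hypertensive
  normo <- params$sbp_normotensive
  pnz <- function(mean, thr, sd) {
    if (sd == 0) as.numeric(mean >= thr) else
      stats::pnorm(thr, mean, sd, lower.tail = FALSE)
  }
  sens_office <- pnz(hyper, thresholds[["office"]], nz$office_sd)
  sens_home <- pnz(hyper - nz$home_offset, thresholds[["home"]], nz$home_sd)
  # white-coat elevation appears at the office only
  fp_office_wc <- pnz(normo + nz$wc_elevation, thresholds[["office"]],
                      nz$office_sd)
  fp_office_plain <- pnz(normo, thresholds[["office"]], nz$office_sd)
  fp_home <- pnz(normo - nz$home_offset, thresholds[["home"]], nz$home_sd)

  if (is.null(prevalence)) prevalence <- default_prevalence(params)
  p_office <- prevalence * sens_office + (1 - prevalence) *
    (nz$wc_rate * fp_office_wc + (1 - nz$wc_rate) * fp_office_plain)
  p_ref_true <- prevalence * sens_office * sens_home
  p_ref_false <- (1 - prevalence) *
    (nz$wc_rate * fp_office_wc + (1 - nz$wc_rate) * fp_office_plain) *
    fp_home
  list(
    prevalence = prevalence,
    sens_office = sens_office, sens_home = sens_home,
    fp_reduction_home = 1 - fp_home,
    office_positives = n * p_office,
    referred = n * (p_ref_true + p_ref_false),
    confirmed_true = n * p_ref_true,
    ppv_at_referral = p_ref_true / (p_ref_true + p_ref_false)
  )
}

#' Default undetected-hypertension prevalence of the generator
#'
#' Calibrated so that the expected number of confirmed true positives equals
#' the study yield (170 of 2,025, i.e. 8%) after the cascade's two-step
#' sensitivity: `prevalence = yield / (sens_office * sens_home)`.
#'
#' @param params A `parameter_set`.
#' @param thresholds,noise As in [cascade_expectations()].
#' @return Scalar prevalence.
#' @export
default_prevalence <- function(params = default_parameters(),
                               thresholds = c(office = 140, home = 135),
                               noise = list()) {
  nz <- utils::modifyList(.cascade_defaults, noise)
  hyper <- params$sbp_untreated_hypertensive
  so <- stats::pnorm(thresholds[["office"]], hyper, nz$office_sd,
                     lower.tail = FALSE)
  sh <- stats::pnorm(thresholds[["home"]], hyper - nz$home_offset,
                     nz$home_sd, lower.tail = FALSE)
  yield <- params$identified_cases_screening / params$cohort_size
  min(1, yield / (so * sh))
}

#' Generate an individual cohort roster
#'
#' Ages are drawn from a normal (52.8, 8.7) truncated to 40-75 by inverse-CDF
#' sampling; undetected hypertension is Bernoulli with the calibrated
#' prevalence; white-coat status is assigned to a fixed share of the
#' normotensives. Office and home systolic pressures are generated from the
#' cascade noise model. Fully reproducible given `seed`.
#'
#' @param n Cohort size (default 2,025).
#' @param men Number of men (default 930; the remainder are women).
#' @param mean_age,sd_age Age distribution before truncation.
#' @param age_range Truncation bounds (default 40-75).
#' @param prevalence Undetected-hypertension prevalence; `NULL` uses
#'   [default_prevalence()].
#' @param params A `parameter_set`.
#' @param noise List overriding the cascade noise constants
#'   (`office_sd`, `home_sd`, `wc_elevation`, `home_offset`, `wc_rate`).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return An `individual_roster` data frame: `id`, `sex`, `age`,
#'   `hypertensive`, `white_coat`, `sbp_office`, `sbp_home`.
#' @export
generate_cohort <- function(n = 2025, men = 930, mean_age = 52.8,
                            sd_age = 8.7, age_range = c(40, 75),
                            prevalence = NULL,
                            params = default_parameters(),
                            noise = list(), seed = NULL) {
  if (men > n || men < 0 || n < 1) {
    stop("invalid counts: need 0 <= men <= n", call. = FALSE)
  }
  if (is.null(prevalence)) prevalence <- default_prevalence(params)
  if (prevalence < 0 || prevalence > 1) {
    stop("prevalence must lie in [0, 1]", call. = FALSE)
  }
  nz <- utils::modifyList(.cascade_defaults, noise)
  if (!is.null(seed)) set.seed(seed)

  # truncated-normal ages by inverse CDF
  lo <- stats::pnorm(age_range[1], mean_age, sd_age)
  hi <- stats::pnorm(age_range[2], mean_age, sd_age)
  age <- stats::qnorm(stats::runif(n, lo, hi), mean_age, sd_age)

  sex <- c(rep("male", men), rep("female", n - men))
  hyper <- stats::runif(n) < prevalence
  wc <- !hyper & stats::runif(n) < nz$wc_rate
  level <- ifelse(hyper, params$sbp_untreated_hypertensive,
                  params$sbp_normotensive)
  sbp_office <- level + nz$wc_elevation * wc +
    stats::rnorm(n, 0, nz$office_sd)
  sbp_home <- level - nz$home_offset + stats::rnorm(n, 0, nz$home_sd)

  structure(data.frame(
    id = seq_len(n), sex = sex, age = age, hypertensive = hyper,
    white_coat = wc, sbp_office = sbp_office, sbp_home = sbp_home,
    stringsAsFactors = FALSE),
    class = c("individual_roster", "data.frame"), noise = nz,
    prevalence = prevalence)
}

#' Simulate the two-step screening cascade over a roster
#'
#' Applies the office threshold, sends positives to home measurement,
#' refers home positives to primary care (where repeated measurement
#' confirms only true hypertensives), and converts the resulting counts into
#' [build_baseline_scenario()]-style activity volumes using per-event rates
#' back-derived from the baseline costing (0.5 dental hours per person
#' screened; home-measurement hours per office positive; primary-care
#' visits, hours and trips per referral). The comparator arm draws
#' opportunistic diagnoses as Binomial(n, 3%) with a 25% white-coat share.
#'
#' @param roster An `individual_roster`.
#' @param thresholds Named vector `c(office = , home = )`, mmHg systolic. A
#'   home threshold at or above the office threshold triggers a warning
#'   (the second step could not remove false positives).
#' @param params A `parameter_set`.
#' @param seed Seed for the comparator-arm draws.
#' @return A `cascade_result` list: `counts` (office positives, referred,
#'   confirmed true positives; comparator diagnosed/true/false) and
#'   `volumes` (a `scenario_volumes` object).
#' @export
simulate_screening_cascade <- function(roster,
                                       thresholds = c(office = 140,
                                                      home = 135),
                                       params = default_parameters(),
                                       seed = NULL) {
  stopifnot(inherits(roster, "individual_roster"))
  if (thresholds[["home"]] >= thresholds[["office"]]) {
    warning("home threshold at or above office threshold; the ",
            "confirmation step cannot remove white-coat positives",
            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(roster)

  office_pos <- roster$sbp_office >= thresholds[["office"]]
  referred <- office_pos & roster$sbp_home >= thresholds[["home"]]
  confirmed <- referred & roster$hypertensive

  comp_rate <- params$comparator_total_diagnosed / params$cohort_size
  fp_share <- params$comparator_false_positives /
    params$comparator_total_diagnosed
  comp_diag <- stats::rbinom(1, n, comp_rate)
  comp_false <- stats::rbinom(1, comp_diag, fp_share)
  comp_true <- comp_diag - comp_false

  counts <- list(
    n = n, office_positives = sum(office_pos), referred = sum(referred),
    confirmed_true = sum(confirmed),
    comparator_diagnosed = comp_diag, comparator_true = comp_true,
    comparator_false = comp_false
  )

  # per-event volume rates back-derived from the baseline costing
  ex <- cascade_expectations(params$cohort_size,
                             prevalence = attr(roster, "prevalence"),
                             params = params,
                             noise = as.list(attr(roster, "noise")))
  bl <- .baseline_volumes()
  home_hours_per_officepos <- bl$screening$hours_home / ex$office_positives
  visits_per_referral <- bl$screening$phc_bp_visits / ex$referred
  hours_per_visit <- bl$screening$hours_phc / bl$screening$phc_bp_visits
  trips_per_visit <- bl$screening$trips / bl$screening$phc_bp_visits
  diag_units_per_case <- bl$screening$diagnosis_units / 170
  cb <- bl$no_screening
  comp_per_diag <- list(visits = cb$phc_bp_visits / 61,
                        hours = cb$hours_phc / 61, trips = cb$trips / 61,
                        diag_units = cb$diagnosis_units / 61)

  phc_visits <- counts$referred * visits_per_referral
  volumes <- structure(list(
    screening = list(
      dental_bp_tests = n,
      phc_bp_visits = phc_visits,
      ecg = counts$confirmed_true,
      lab = counts$confirmed_true,
      diagnosis_units = counts$confirmed_true * diag_units_per_case,
      admin_units = bl$screening$admin_units,
      hours_dental = 0.5 * n,
      hours_phc = phc_visits * hours_per_visit,
      hours_home = counts$office_positives * home_hours_per_officepos,
      trips = phc_visits * trips_per_visit
    ),
    no_screening = list(
      dental_bp_tests = 0,
      phc_bp_visits = comp_diag * comp_per_diag$visits,
      ecg = comp_diag, lab = comp_diag,
      diagnosis_units = comp_diag * comp_per_diag$diag_units,
      admin_units = 0,
      hours_dental = 0, hours_home = 0,
      hours_phc = comp_diag * comp_per_diag$hours,
      trips = comp_diag * comp_per_diag$trips
    )), class = "scenario_volumes")

  structure(list(counts = counts, volumes = volumes,
                 thresholds = thresholds),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  ct <- x$counts
  cat("<cascade_result>\n")
  cat(sprintf("  screening: %d office positives -> %d referred -> %d confirmed\n",
              ct$office_positives, ct$referred, ct$confirmed_true))
  cat(sprintf("  comparator: %d diagnosed (%d true, %d white-coat)\n",
              ct$comparator_diagnosed, ct$comparator_true,
              ct$comparator_false))
  invisible(x)
}
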
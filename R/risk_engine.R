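#' @title Annual cardiovascular event risks and background mortality
#'
#' @description
#' Annual first-event probabilities of acute myocardial infarction (AMI) and
#' stroke come from the parametric (Weibull accelerated-failure-time)
#' Framingham risk functions of Anderson and colleagues (1991), evaluated as
#' a one-year risk at the cohort's current age and systolic blood pressure.
#' The published coronary endpoint of that model is broad CHD (myocardial
#' infarction, angina pectoris, coronary insufficiency and coronary death);
#' because the model's event state is an acute MI specifically — it carries
#' acute-care costs and an MI QALY decrement — the engine multiplies the CHD
#' first-event probability by the share of first coronary presentations that
#' are MI in the Framingham cohort (men 0.65, women 0.50). The stroke
#' endpoint is used as published. Background (non-event) mortality comes from
#' a bundled sex- and age-specific life table.
#'
#' The parametric model is
#' \deqn{p(t) = 1 - \exp(-\exp(u)), \quad u = (\log t - \mu)/\sigma,}
#' where \eqn{\mu} is linear in the risk factors and, for the coronary
#' endpoint, \eqn{\sigma} also depends on \eqn{\mu}. Diabetes was an
#' exclusion criterion of the screening study, so the diabetic flag is
#' forced false.
#'
#' @name risk_engine
NULL

#' Construct a cardiovascular risk profile
#'
#' @param age Age in years (valid 30-100; the risk equations are evaluated
#'   with age clamped to their 30-74 estimation range).
#' @param sex `"male"` or `"female"`.
#' @param sbp Systolic blood pressure, mmHg (80-250).
#' @param tc_hdl_ratio Total cholesterol / HDL ratio (> 0).
#' @param smoker,lvh Logical flags; default `FALSE`.
#' @return A `risk_profile` object.
#' @export
risk_profile <- function(age, sex = c("male", "female"), sbp, tc_hdl_ratio,
                         smoker = FALSE, lvh = FALSE) {
  sex <- match.arg(sex)
  if (age < 30 || age > 100) stop("age must lie in [30, 100]", call. = FALSE)
  if (sbp < 80 || sbp > 250) stop("sbp must lie in [80, 250]", call. = FALSE)
  if (tc_hdl_ratio <= 0) stop("tc_hdl_ratio must be > 0", call. = FALSE)
  structure(list(age = age, sex = sex, sbp = sbp,
                 tc_hdl_ratio = tc_hdl_ratio,
                 smoker = isTRUE(smoker), diabetic = FALSE,
                 lvh = isTRUE(lvh)),
            class = "risk_profile")
}

# Anderson et al. (1991) parametric risk functions, hand-transcribed
# worksheet form. `event` is the published endpoint ("chd" or "stroke").
# Vectorised over age/sbp.
.anderson_risk <- function(event, sex, age, sbp, ratio, t = 1,
                           smoker = FALSE, diabetic = FALSE, lvh = FALSE) {
  if (any(age < 30) || any(age > 74)) {
    age <- pmin(pmax(age, 30), 74)
    warning("age outside the 30-74 validity range of the risk equations; ",
            "clamped", call. = FALSE)
  }
  female <- sex == "female"
  smoker <- as.numeric(smoker); diabetic <- as.numeric(diabetic)
  lvh <- as.numeric(lvh)
  if (event == "chd") {
    a <- 11.1122 - 0.9119 * log(sbp) - 0.2767 * smoker -
      0.7181 * log(ratio) - 0.5865 * lvh
    m <- if (female) {
      a - 5.8549 + 1.8515 * (log(age / 74))^2 - 0.3758 * diabetic
    } else {
      a - 1.4792 * log(age) - 0.1759 * diabetic
    }
    mu <- 4.4181 + m
    sigma <- exp(-0.3155 - 0.2784 * m)
  } else if (event == "stroke") {
    mu <- 26.5116 + 0.2019 * female - 2.3741 * log(age) -
      2.4643 * log(sbp) - 0.3914 * smoker - 0.3087 * diabetic -
      0.2627 * lvh
    sigma <- exp(-0.4312)
  } else {
    stop("unknown endpoint: ", event, call. = FALSE)
  }
  1 - exp(-exp((log(t) - mu) / sigma))
}

#' Annual probability of a first AMI or stroke
#'
#' Evaluates the embedded Framingham risk function as a one-year risk
#' (`t = 1`) for the given profile. Strictly increasing in age, systolic
#' blood pressure and cholesterol ratio over the valid domain. Ages outside
#' the equations' 30-74 estimation range are clamped with a warning.
#'
#' @param profile A [risk_profile()].
#' @param event `"ami"` or `"stroke"`.
#' @param t Risk horizon in years (default 1, the model's cycle length).
#' @param mi_share Named vector `c(male = , female = )`: share of first
#'   coronary events counted as MI. Set both to 1 to obtain the raw broad-CHD
#'   endpoint.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' p <- risk_profile(53, "male", sbp = 147, tc_hdl_ratio = 4.0)
#' annual_event_probability(p, "ami")
annual_event_probability <- function(profile, event = c("ami", "stroke"),
                                     t = 1,
                                     mi_share = c(male = 0.65,
                                                  female = 0.50)) {
  stopifnot(inherits(profile, "risk_profile"))
  event <- match.arg(event)
  if (event == "ami") {
    mi_share[[profile$sex]] *
      .anderson_risk("chd", profile$sex, profile$age, profile$sbp,
                     profile$tc_hdl_ratio, t = t, smoker = profile$smoker,
                     diabetic = profile$diabetic, lvh = profile$lvh)
  } else {
    .anderson_risk("stroke", profile$sex, profile$age, profile$sbp,
                   profile$tc_hdl_ratio, t = t, smoker = profile$smoker,
                   diabetic = profile$diabetic, lvh = profile$lvh)
  }
}

# ---------------------------------------------------------------------------
# life table

#' Load a sex- and age-specific life table
#'
#' Reads a three-column CSV (`age`, `sex`, `qx` — the annual all-cause death
#' probability). The packaged default,
#' `life_table_sweden_synthetic.csv`, is a synthetic Gompertz-Makeham
#' approximation of recent Swedish national mortality (ages 40-100, final-age
#' probability 1); see the methods vignette for its construction.
#'
#' @param path CSV path; `NULL` loads the packaged table.
#' @return A `life_table` data frame.
#' @export
load_life_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "life_table_sweden_synthetic.csv",
                        package = "bpscreen")
  }
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", "qx")
  if (!all(need %in% names(lt))) {
    stop("life table must have columns age, sex, qx", call. = FALSE)
  }
  if (any(lt$qx < 0 | lt$qx > 1)) {
    stop("life-table qx must lie in [0, 1]", call. = FALSE)
  }
  structure(lt, class = c("life_table", "data.frame"))
}

#' Annual background (all-cause) mortality from a life table
#'
#' Ages above the table's maximum return 1 (absorbing end of table);
#' vectorised over `age`.
#'
#' @param age Age in years.
#' @param sex `"male"` or `"female"`.
#' @param table A `life_table` from [load_life_table()].
#' @return Annual death probability.
#' @export
background_mortality <- function(age, sex, table) {
  stopifnot(inherits(table, "life_table"))
  sub <- table[table$sex == sex, , drop = FALSE]
  if (!nrow(sub)) stop("life table has no rows for sex ", sex, call. = FALSE)
  idx <- match(floor(age), sub$age)
  out <- sub$qx[idx]
  out[floor(age) > max(sub$age)] <- 1
  out[floor(age) < min(sub$age)] <- sub$qx[which.min(sub$age)]
  out
}

#' Generate a Gompertz-Makeham life table
#'
#' `qx(age) = min(1, a + b * exp(theta * age))`, a smooth all-cause mortality
#' schedule used to build the packaged synthetic Swedish-style table. The
#' final age's probability is set to 1.
#'
#' @param ages Integer vector of ages.
#' @param makeham,slope,rate Named vectors (`male`, `female`) of the
#'   age-independent term `a`, the level `b` and the exponential rate
#'   `theta`. Defaults approximate recent Swedish national mortality.
#' @return A `life_table` data frame.
#' @export
gompertz_life_table <- function(ages = 40:100,
                                makeham = c(male = 5e-4, female = 3e-4),
                                slope = c(male = 1.31e-5, female = 6.84e-6),
                                rate = c(male = 0.1035, female = 0.1070)) {
  out <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    qx <- pmin(1, makeham[[sx]] + slope[[sx]] * exp(rate[[sx]] * ages))
    qx[length(qx)] <- 1
    data.frame(age = ages, sex = sx, qx = qx, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("life_table", "data.frame"))
}

#' Default (packaged) life table
#'
#' @return The bundled synthetic Swedish-style `life_table`.
#' @export
default_life_table <- function() load_life_table(NULL)

# ---------------------------------------------------------------------------
# transition matrix

.states <- c("healthy", "ami_year", "stroke_year", "post_ami", "post_stroke",
             "dead")

#' Build the annual six-state transition matrix
#'
#' States: Healthy, AMI-year, Stroke-year, Post-AMI, Post-Stroke, Dead.
#' From Healthy the cohort moves to the event-year states with the
#' Framingham probabilities and to Dead with background mortality; the
#' event-year states resolve into death (365-day case fatality) or the
#' chronic post-event state; post-event states add the published excess
#' mortality to background mortality (capped at 1). Dead is absorbing and no
#' recurrent or cross-track events occur. Competing probabilities out of
#' Healthy that sum above 1 raise an error (they signal bad inputs), except
#' at the life table's absorbing final age, where death is certain and takes
#' precedence.
#'
#' @param profile A [risk_profile()] at the cohort's current age and blood
#'   pressure.
#' @param params A `parameter_set` (case fatality, added mortality, MI
#'   share).
#' @param table A `life_table`.
#' @param risk_scale Named multipliers `ami`, `stroke`, `mortality` applied
#'   to the event probabilities and background mortality (used by the PSA).
#' @return 6x6 row-stochastic matrix with named dimensions.
#' @export
build_transition_matrix <- function(profile, params, table,
                                    risk_scale = c(ami = 1, stroke = 1,
                                                   mortality = 1)) {
  stopifnot(inherits(profile, "risk_profile"))
  sx <- profile$sex
  key <- if (sx == "male") "men" else "women"
  mi_share <- c(male = params$mi_share$men, female = params$mi_share$women)
  p_ami <- min(1, risk_scale[["ami"]] *
                 annual_event_probability(profile, "ami",
                                          mi_share = mi_share))
  p_str <- min(1, risk_scale[["stroke"]] *
                 annual_event_probability(profile, "stroke"))
  q <- min(1, risk_scale[["mortality"]] *
             background_mortality(profile$age, sx, table))
  if (q >= 1) {
    # absorbing end of the life table: death is certain this cycle
    p_ami <- 0
    p_str <- 0
    q <- 1
  } else if (p_ami + p_str + q > 1) {
    stop("competing transition probabilities from Healthy exceed 1 ",
         "(age ", profile$age, ", sex ", sx, ")", call. = FALSE)
  }
  cf_ami  <- params$case_fatality_365d$ami[[key]]
  cf_str  <- params$case_fatality_365d$stroke[[key]]
  add_ami <- params$added_mortality_post365d$ami[[key]]
  add_str <- params$added_mortality_post365d$stroke[[key]]

  P <- matrix(0, 6, 6, dimnames = list(.states, .states))
  P["healthy", ] <- c(1 - p_ami - p_str - q, p_ami, p_str, 0, 0, q)
  P["ami_year", c("post_ami", "dead")] <- c(1 - cf_ami, cf_ami)
  P["stroke_year", c("post_stroke", "dead")] <- c(1 - cf_str, cf_str)
  d_pa <- min(1, q + add_ami)
  d_ps <- min(1, q + add_str)
  P["post_ami", c("post_ami", "dead")] <- c(1 - d_pa, d_pa)
  P["post_stroke", c("post_stroke", "dead")] <- c(1 - d_ps, d_ps)
  P["dead", "dead"] <- 1
  P
}
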
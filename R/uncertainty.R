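#' @title Deterministic and probabilistic sensitivity analysis
#'
#' @description
#' One-way deterministic sensitivity analysis (tornado diagram) over the
#' registry's uncertainty ranges, and a probabilistic sensitivity analysis
#' (PSA) that jointly samples hypertension prevalence, unit costs,
#' transition inputs and QALY decrements, evaluates the incremental cost and
#' QALYs per draw, and summarises the draws on the cost-effectiveness plane
#' and as a cost-effectiveness acceptability curve (CEAC). The
#' cost-effectiveness decision rule is net monetary benefit,
#' \eqn{\lambda \Delta Q - \Delta C > 0}, which is robust to negative
#' denominators.
#'
#' @name uncertainty
NULL

.dsa_axes <- c("horizon", "prevalence", "ami_costs", "stroke_costs",
               "drug_cost", "ami_decrement", "stroke_decrement",
               "discount_rate")

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-computes the base-case ICER with each axis perturbed one at a time:
#' +/-20% for prevalence (identified cases, detection ratios fixed), costs
#' and QALY decrements; 10 vs 30 years for the horizon; 0 vs 5% for the
#' discount rate. Entries are sorted by bar width (largest first).
#'
#' @param params A `parameter_set`.
#' @param table A `life_table`.
#' @param axes Subset of the available axes (see Details); default all.
#' @param perspective `"payer"` or `"societal"`.
#' @param pm_fraction Relative perturbation for the +/- axes (default 0.2).
#' @return A `tornado` data frame: `parameter`, `low_input`, `high_input`,
#'   `icer_low_input`, `icer_high_input`, `icer_min`, `icer_max`, `width`;
#'   base-case ICER in attribute `base_icer`.
#' @export
one_way_dsa <- function(params = default_parameters(),
                        table = default_life_table(),
                        axes = .dsa_axes,
                        perspective = c("payer", "societal"),
                        pm_fraction = 0.2) {
  perspective <- match.arg(perspective)
  bad <- setdiff(axes, .dsa_axes)
  if (length(bad)) {
    stop("unknown DSA axis: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  icer_of <- function(...) {
    res <- suppressWarnings(  # horizon 30 runs past the risk-equation ages
      run_cea(params, table, subgroups = "all",
              perspectives = perspective, ...))
    res$icer[1]
  }
  base <- icer_of()

  pm <- c(1 - pm_fraction, 1 + pm_fraction)
  uc <- params$unit_costs
  dec <- params$qaly_decrements
  cs <- params$identified_cases_screening
  cc <- params$identified_cases_comparator_true

  one <- function(axis) {
    vals <- switch(axis,
      horizon = {
        lo <- round(params$horizon_years / 2)
        hi <- round(params$horizon_years * 1.5)
        c(lo, hi,
          icer_of(horizon = lo), icer_of(horizon = hi))
      },
      discount_rate = c(0, 0.05,
                        icer_of(discount = 0), icer_of(discount = 0.05)),
      prevalence = c(cs * pm[1], cs * pm[2],
        icer_of(cases_screen = cs * pm[1], cases_comp_true = cc * pm[1]),
        icer_of(cases_screen = cs * pm[2], cases_comp_true = cc * pm[2])),
      ami_costs = c(pm[1], pm[2],
        icer_of(overrides = list(unit_costs = list(
          ami_first_year = uc$ami_first_year * pm[1],
          post_ami_annual = uc$post_ami_annual * pm[1]))),
        icer_of(overrides = list(unit_costs = list(
          ami_first_year = uc$ami_first_year * pm[2],
          post_ami_annual = uc$post_ami_annual * pm[2])))),
      stroke_costs = c(pm[1], pm[2],
        icer_of(overrides = list(unit_costs = list(
          stroke_first_year = uc$stroke_first_year * pm[1],
          post_stroke_annual = uc$post_stroke_annual * pm[1]))),
        icer_of(overrides = list(unit_costs = list(
          stroke_first_year = uc$stroke_first_year * pm[2],
          post_stroke_annual = uc$post_stroke_annual * pm[2])))),
      drug_cost = c(pm[1], pm[2],
        icer_of(overrides = list(unit_costs = list(
          drug_treatment_annual = uc$drug_treatment_annual * pm[1]))),
        icer_of(overrides = list(unit_costs = list(
          drug_treatment_annual = uc$drug_treatment_annual * pm[2])))),
      ami_decrement = c(pm[1], pm[2],
        icer_of(overrides = list(qaly_decrements = list(
          ami_year = dec$ami_year * pm[1],
          post_ami = dec$post_ami * pm[1]))),
        icer_of(overrides = list(qaly_decrements = list(
          ami_year = dec$ami_year * pm[2],
          post_ami = dec$post_ami * pm[2])))),
      stroke_decrement = c(pm[1], pm[2],
        icer_of(overrides = list(qaly_decrements = list(
          stroke_year = dec$stroke_year * pm[1],
          post_stroke = dec$post_stroke * pm[1]))),
        icer_of(overrides = list(qaly_decrements = list(
          stroke_year = dec$stroke_year * pm[2],
          post_stroke = dec$post_stroke * pm[2]))))
    )
    data.frame(parameter = axis, low_input = vals[1], high_input = vals[2],
               icer_low_input = vals[3], icer_high_input = vals[4],
               icer_min = min(vals[3:4]), icer_max = max(vals[3:4]),
               width = abs(vals[4] - vals[3]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(axes, one))
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  structure(out, class = c("tornado", "data.frame"), base_icer = base,
            perspective = perspective)
}

# ---------------------------------------------------------------------------
# probabilistic sensitivity analysis

# Pre-computes everything in the incremental model that the PSA does not
# sample (base risk curves by sex/treatment status, background mortality,
# discount factors, the incremental case-driven cost-line volumes), and
# returns a function evaluating one joint draw. The incremental comparison
# reduces to per-person treated vs untreated traces per sex scaled by the
# number of additionally treated cases; the normotensive remainder is
# identical in both arms and cancels exactly.
.compile_increment_model <- function(params, table,
                                     horizon = params$horizon_years,
                                     discount = params$discount_rate,
                                     subgroup = "all") {
  ages <- params$start_age + seq_len(horizon) - 1
  share <- switch(subgroup,
    all = c(male = params$cohort_men / params$cohort_size,
            female = params$cohort_women / params$cohort_size),
    men = c(male = 1, female = 0),
    women = c(male = 0, female = 1))
  mi_share <- c(male = params$mi_share$men, female = params$mi_share$women)

  base <- list()
  for (sx in c("male", "female")) {
    ratio <- params$tc_hdl_ratio[[if (sx == "male") "men" else "women"]]
    for (status in c("treated", "untreated")) {
      sbp <- .sbp_for_status(params, status)
      key <- paste(sx, status, sep = ".")
      base[[key]] <- list(
        ami = vapply(ages, function(a) {
          mi_share[[sx]] * .anderson_risk("chd", sx, min(a, 74), sbp, ratio)
        }, numeric(1)),
        stroke = vapply(ages, function(a) {
          .anderson_risk("stroke", sx, min(a, 74), sbp, ratio)
        }, numeric(1))
      )
    }
    base[[paste0("q.", sx)]] <- background_mortality(ages, sx, table)
  }
  df <- (1 + discount)^(-(seq_len(horizon) - 1))
  base_cases <- params$identified_cases_screening
  extra_cases <- base_cases - params$identified_cases_comparator_true

  # per-person discounted (cost, qaly) for one sex/status under a draw
  person <- function(sx, status, dr) {
    key <- paste(sx, status, sep = ".")
    k <- if (sx == "male") "men" else "women"
    p_ami <- pmin(1, dr$scale_ami * base[[key]]$ami)
    p_str <- pmin(1, dr$scale_stroke * base[[key]]$stroke)
    q <- pmin(1, dr$scale_mort * base[[paste0("q.", sx)]])
    cf_a <- dr$cf$ami[[k]]; cf_s <- dr$cf$stroke[[k]]
    ad_a <- pmin(1, q + dr$added$ami[[k]])
    ad_s <- pmin(1, q + dr$added$stroke[[k]])
    qw <- c(1, 1 - dr$dec$ami_year, 1 - dr$dec$stroke_year,
            1 - dr$dec$post_ami, 1 - dr$dec$post_stroke, 0)
    cw <- c(0, dr$uc$ami_first_year, dr$uc$stroke_first_year,
            dr$uc$post_ami_annual, dr$uc$post_stroke_annual, 0)
    drug <- if (status == "treated") dr$uc$drug_treatment_annual else 0
    x <- c(1, 0, 0, 0, 0, 0)
    cost <- qaly <- 0
    for (t in seq_len(horizon)) {
      alive <- sum(x[1:5])
      qaly <- qaly + df[t] * sum(x * qw)
      cost <- cost + df[t] * (sum(x * cw) + drug * alive)
      ph <- max(0, 1 - p_ami[t] - p_str[t] - q[t])
      x <- c(x[1] * ph,
             x[1] * p_ami[t],
             x[1] * p_str[t],
             x[2] * (1 - cf_a) + x[4] * (1 - ad_a[t]),
             x[3] * (1 - cf_s) + x[5] * (1 - ad_s[t]),
             x[6] + x[1] * q[t] + x[2] * cf_a + x[3] * cf_s +
               x[4] * ad_a[t] + x[5] * ad_s[t])
    }
    c(cost = cost, qaly = qaly)
  }

  function(dr) {
    s <- dr$cases / base_cases
    d <- c(cost = 0, qaly = 0)
    for (sx in c("male", "female")) {
      if (share[[sx]] == 0) next
      d <- d + share[[sx]] *
        (person(sx, "treated", dr) - person(sx, "untreated", dr))
    }
    d * extra_cases * s
  }
}

# incremental short-term programme cost under sampled unit costs, with
# case-driven volumes rescaled by the sampled yield
.short_term_delta_fast <- function(uc, cases, base_cases = 170) {
  v <- .baseline_volumes()
  s <- cases / base_cases
  dv <- function(f, scale = TRUE) {
    d <- v$screening[[f]] - v$no_screening[[f]]
    if (scale) d * s else d
  }
  payer <- dv("admin_units", FALSE) * uc$screening_admin +
    dv("dental_bp_tests", FALSE) * uc$dental_bp_test +
    dv("phc_bp_visits") * uc$phc_bp_test +
    dv("ecg") * uc$ecg + dv("lab") * uc$lab +
    dv("diagnosis_units") * uc$diagnosis
  societal <- payer +
    dv("hours_dental", FALSE) * uc$patient_time_hour +
    (dv("hours_phc") + dv("hours_home")) * uc$patient_time_hour +
    dv("trips") * uc$patient_travel_trip
  c(payer = payer, societal = societal)
}

# turn one row of sampled values into the draw structure the compiled model
# expects
.draw_to_model_input <- function(sample, params) {
  g <- function(nm) unname(sample[[nm]])
  uc <- params$unit_costs
  for (item in names(uc)) uc[[item]] <- g(paste0("cost.", item))
  list(
    uc = uc,
    cf = list(ami = list(men = g("cf.ami.men"), women = g("cf.ami.women")),
              stroke = list(men = g("cf.stroke.men"),
                            women = g("cf.stroke.women"))),
    added = list(ami = list(men = g("added.ami.men"),
                            women = g("added.ami.women")),
                 stroke = list(men = g("added.stroke.men"),
                               women = g("added.stroke.women"))),
    dec = list(ami_year = g("dec.ami_year"),
               stroke_year = g("dec.stroke_year"),
               post_ami = g("dec.post_ami"),
               post_stroke = g("dec.post_stroke")),
    cases = max(1, g("cases_screening")),
    scale_ami = g("risk_scale.ami"),
    scale_stroke = g("risk_scale.stroke"),
    scale_mort = g("risk_scale.mortality")
  )
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` joint parameter samples from the registry's elicited
#' distributions ([psa_distributions()]), evaluates the incremental cost
#' (payer and societal) and incremental QALYs for each draw, and returns the
#' draws. Random numbers use L'Ecuyer-CMRG substreams keyed to the master
#' seed, so draw `i` is reproducible and independent of `n`. Fixed registry
#' entries (cohort sizes, discount rate) are never sampled.
#'
#' @param params A `parameter_set`.
#' @param n Number of Monte Carlo draws (study value 5,000).
#' @param seed Master seed.
#' @param table A `life_table`.
#' @param subgroup Cohort composition (default `"all"`).
#' @param dists Sampling distributions; defaults to
#'   [psa_distributions()]. Overriding (e.g. with all-`"fixed"` specs) is
#'   mainly useful for verification.
#' @return A `psa_draws` data frame: `draw`, one column per sampled
#'   parameter, `d_cost_payer`, `d_cost_societal`, `d_qaly`.
#' @export
run_psa <- function(params = default_parameters(), n = 5000, seed = 1L,
                    table = default_life_table(), subgroup = "all",
                    dists = psa_distributions(params)) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  model <- .compile_increment_model(params, table, subgroup = subgroup)

  # one L'Ecuyer substream per draw: reproducible, order-independent
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  old_kind <- RNGkind("L'Ecuyer-CMRG")
  on.exit({
    RNGkind(old_kind[1])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  stream <- get(".Random.seed", globalenv())

  pnames <- names(dists)
  samples <- matrix(NA_real_, n, length(pnames),
                    dimnames = list(NULL, pnames))
  out <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, c("d_cost_payer", "d_cost_societal",
                                        "d_qaly")))
  for (i in seq_len(n)) {
    stream <- parallel::nextRNGStream(stream)
    assign(".Random.seed", stream, globalenv())
    smp <- vapply(dists, sample_distribution, numeric(1), n = 1L)
    samples[i, ] <- smp
    dr <- .draw_to_model_input(as.list(smp), params)
    lt <- model(dr)
    st <- .short_term_delta_fast(dr$uc, dr$cases,
                                 params$identified_cases_screening)
    out[i, ] <- c(lt[["cost"]] + st[["payer"]],
                  lt[["cost"]] + st[["societal"]],
                  lt[["qaly"]])
  }
  res <- data.frame(draw = seq_len(n), samples, out, check.names = FALSE)
  structure(res, class = c("psa_draws", "data.frame"), seed = seed,
            subgroup = subgroup)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value \eqn{\lambda}, the probability that
#' screening is cost-effective is the share of PSA draws with positive
#' incremental net monetary benefit, \eqn{\lambda \Delta Q - \Delta C > 0}.
#'
#' @param draws A `psa_draws` data frame.
#' @param wtp Willingness-to-pay grid, SEK per QALY. The default spans
#'   0-3,000,000 SEK in 25,000-SEK steps, covering both informal Swedish
#'   thresholds (500,000 and 1,000,000 SEK).
#' @param perspective `"payer"` or `"societal"`.
#' @return A `ceac_curve` data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(draws, wtp = seq(0, 3e6, by = 25000),
                 perspective = c("payer", "societal")) {
  stopifnot(inherits(draws, "psa_draws"))
  if (!length(wtp)) stop("wtp grid must be nonempty", call. = FALSE)
  if (!nrow(draws)) stop("no draws", call. = FALSE)
  perspective <- match.arg(perspective)
  dc <- draws[[paste0("d_cost_", perspective)]]
  dq <- draws$d_qaly
  prob <- vapply(wtp, function(l) mean(l * dq - dc > 0), numeric(1))
  structure(data.frame(wtp = wtp, probability = prob),
            class = c("ceac_curve", "data.frame"),
            perspective = perspective, n = nrow(draws))
}

#' Cost-effectiveness plane quadrant summary
#'
#' Counts PSA draws per quadrant of the incremental cost / incremental QALY
#' plane (NE: dearer and better, and so on).
#'
#' @param draws A `psa_draws`.
#' @param perspective `"payer"` or `"societal"`.
#' @return Named integer vector `c(NE, NW, SE, SW)`; sums to the number of
#'   draws (boundary draws counted with the positive side).
#' @export
ce_plane_summary <- function(draws, perspective = c("payer", "societal")) {
  stopifnot(inherits(draws, "psa_draws"))
  perspective <- match.arg(perspective)
  dc <- draws[[paste0("d_cost_", perspective)]]
  dq <- draws$d_qaly
  c(NE = sum(dq >= 0 & dc >= 0), NW = sum(dq < 0 & dc >= 0),
    SE = sum(dq >= 0 & dc < 0), SW = sum(dq < 0 & dc < 0))
}

# ---------------------------------------------------------------------------
# figures

#' Tornado diagram of the one-way sensitivity analysis
#'
#' @param dsa A `tornado` data frame from [one_way_dsa()].
#' @return A ggplot object.
#' @export
plot_tornado <- function(dsa) {
  stopifnot(inherits(dsa, "tornado"))
  d <- as.data.frame(dsa)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_min,
                                       xend = .data$icer_max,
                                       yend = .data$parameter),
                          linewidth = 6, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(dsa, "base_icer"),
                        linetype = 1) +
    ggplot2::geom_vline(xintercept = 5e5, linetype = 2) +
    ggplot2::scale_x_continuous(labels = function(x)
      sprintf("%.1fM", x / 1e6)) +
    ggplot2::labs(x = "ICER (SEK per QALY)", y = NULL,
                  title = "One-way sensitivity analysis",
                  subtitle = "dashed line: 500,000 SEK per QALY") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane scatter of the PSA draws
#'
#' @param draws A `psa_draws`.
#' @param perspective `"payer"` or `"societal"`.
#' @param thresholds Willingness-to-pay lines to draw, SEK/QALY.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(draws, perspective = c("payer", "societal"),
                          thresholds = c(5e5, 1e6)) {
  stopifnot(inherits(draws, "psa_draws"))
  perspective <- match.arg(perspective)
  d <- data.frame(dq = draws$d_qaly,
                  dc = draws[[paste0("d_cost_", perspective)]])
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$dq, .data$dc)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::scale_y_continuous(labels = function(x)
      sprintf("%.0fM", x / 1e6)) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (SEK)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  for (l in thresholds) {
    p <- p + ggplot2::geom_abline(intercept = 0, slope = l, linetype = 2)
  }
  p
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param curve A `ceac_curve` from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  stopifnot(inherits(curve, "ceac_curve"))
  ggplot2::ggplot(as.data.frame(curve),
                  ggplot2::aes(.data$wtp, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(5e5, 1e6), linetype = 2) +
    ggplot2::scale_x_continuous(labels = function(x)
      sprintf("%.1fM", x / 1e6)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (SEK per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
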
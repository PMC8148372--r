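# Independent oracles used across the suite.

# Expanded single-formula transcription of the coronary risk function
# (female interactions multiplied out and frozen as numeric constants),
# evaluated with arithmetic independent of the package's two-branch
# worksheet form.
oracle_chd_risk <- function(sex, age, sbp, ratio, t = 1, smoker = 0,
                            diabetic = 0, lvh = 0) {
  f <- as.numeric(sex == "female")
  mu <- 15.5303 + 28.4440936686 * f - 1.4792 * log(age) -
    14.4587530401 * f * log(age) + 1.8515 * f * log(age)^2 -
    0.9119 * log(sbp) - 0.2767 * smoker - 0.7181 * log(ratio) -
    0.1759 * diabetic - 0.1999 * f * diabetic - 0.5865 * lvh
  log_sigma <- 0.91449904 - 0.2784 * mu
  u <- (log(t) - mu) / exp(log_sigma)
  1 - exp(-exp(u))
}

# Individual-level Monte Carlo counterpart of the cohort engine: same
# transition matrices, multinomial sampling of state counts. Returns
# per-person discounted cost and QALY means over `reps` replicates of
# `n_rep` individuals, with replicate standard errors.
microsim_oracle <- function(strata, params, table,
                            horizon = params$horizon_years,
                            discount = params$discount_rate,
                            n_rep = 5000, reps = 20, seed = 1) {
  set.seed(seed)
  dec <- params$qaly_decrements
  qw <- c(1, 1 - dec$ami_year, 1 - dec$stroke_year,
          1 - dec$post_ami, 1 - dec$post_stroke, 0)
  uc <- params$unit_costs
  cw <- c(0, uc$ami_first_year, uc$stroke_first_year,
          uc$post_ami_annual, uc$post_stroke_annual, 0)
  drug <- uc$drug_treatment_annual
  df <- (1 + discount)^(-(seq_len(horizon) - 1))
  total <- sum(strata$count)

  one_rep <- function() {
    cost <- qaly <- 0
    for (s in seq_len(nrow(strata))) {
      n_i <- round(n_rep * strata$count[s] / total)
      if (n_i == 0) next
      sx <- strata$sex[s]
      sbp <- switch(strata$status[s],
                    normotensive = params$sbp_normotensive,
                    treated = params$sbp_treated_hypertensive,
                    untreated = params$sbp_untreated_hypertensive)
      ratio <- params$tc_hdl_ratio[[if (sx == "male") "men" else "women"]]
      treated <- strata$status[s] == "treated"
      x <- c(n_i, 0, 0, 0, 0, 0)
      for (t in seq_len(horizon)) {
        alive <- sum(x[1:5])
        qaly <- qaly + df[t] * sum(x * qw)
        cost <- cost + df[t] * (sum(x * cw) + if (treated)
          drug * alive else 0)
        P <- build_transition_matrix(
          risk_profile(min(strata$age[s] + t - 1, 100), sx, sbp, ratio),
          params, table)
        x_new <- numeric(6)
        for (st in 1:6) {
          if (x[st] > 0) {
            x_new <- x_new + as.vector(stats::rmultinom(1, x[st], P[st, ]))
          }
        }
        x <- x_new
      }
    }
    c(cost = cost, qaly = qaly) / n_rep
  }
  res <- t(replicate(reps, one_rep()))
  list(mean = colMeans(res),
       se = apply(res, 2, stats::sd) / sqrt(reps),
       n_total = n_rep * reps)
}

# analytic mean of a normal truncated to [lo, hi]
truncnorm_mean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  mu + sigma * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}
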
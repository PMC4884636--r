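# Shared fixtures and independent oracles, built in code at load time.

# Population that never dies: relative survival == observed survival.
flat_lt <- uniform_life_table(annual_survival = 1)

# Small constant-survival table restricted to one race, for closed forms.
const_lt <- function(p, races = "white", ages = 40:119, years = 1990:2040) {
  uniform_life_table(annual_survival = p, ages = ages, years = years,
                     races = races)
}

# Build a cohort data.frame from follow-up months and status, defaulting
# the demographic and nodal fields.
tiny_cohort <- function(months, status,
                        age = 60L, sex = "male", race = "white",
                        dx_year = 2000L, examined = 10L, positive = 1L,
                        grade = "III", radiation = "no") {
  n <- length(months)
  data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    age_at_dx = rep_len(age, n), sex = rep_len(sex, n),
    race = rep_len(race, n), dx_year = rep_len(dx_year, n),
    follow_up_months = as.integer(months),
    vital_status = rep_len(status, n),
    nodes_examined = as.integer(rep_len(examined, n)),
    nodes_positive = as.integer(rep_len(positive, n)),
    grade = rep_len(grade, n), radiation = rep_len(radiation, n),
    stringsAsFactors = FALSE
  )
}

# Independent brute-force product-limit oracle: product over event times,
# deaths before censorings at tied times.
bf_product_limit <- function(time, dead, grid) {
  event_times <- sort(unique(time[dead]))
  vapply(grid, function(g) {
    s <- 1
    for (te in event_times[event_times <= g]) {
      n_at <- sum(time >= te)
      d <- sum(time == te & dead)
      s <- s * (1 - d / n_at)
    }
    s
  }, numeric(1))
}

# Random small censored cohort for oracle comparisons.
random_tiny_cohort <- function(n_max = 20L) {
  n <- sample(2:n_max, 1L)
  tiny_cohort(sample(0:24, n, replace = TRUE),
              sample(c("dead", "censored"), n, replace = TRUE))
}

# Wrap raw monthly value sequences (starting at month 0) as curve-shaped
# data.frames accepted by relative_survival().
as_observed <- function(values, se = 0) {
  data.frame(month = seq_along(values) - 1L, survival = values,
             std_err = rep_len(se, length(values)),
             n_risk = rev(seq_along(values)))
}
as_expected <- function(values) {
  data.frame(month = seq_along(values) - 1L, expected = values)
}

# Three-stratum truth used by the recovery experiments: subcohort-style
# depths with rates set so the true inflection points are 25, 10 and 7
# years; 20% cumulative dropout over a 300-month horizon.
recovery_spec <- function(n_per_stratum = 2000L, seed = 42L,
                          horizon = 300L) {
  rate <- monthly_dropout_rate(0.2, horizon)
  cohort_spec(
    list(
      stratum_spec("low", c(1e-6, 0.10), n_per_stratum, 0.513, 4.64,
                   log(4.64) / 25, censoring_rate = rate,
                   horizon_months = horizon),
      stratum_spec("mid", c(0.10, 0.40), n_per_stratum, 0.579, 5.22,
                   log(5.22) / 10, censoring_rate = rate,
                   horizon_months = horizon),
      stratum_spec("high", c(0.40, 1.0), n_per_stratum, 0.616, 4.00,
                   log(4.00) / 7, censoring_rate = rate,
                   horizon_months = horizon)
    ),
    seed = seed
  )
}
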
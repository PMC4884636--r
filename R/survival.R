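#' Kaplan-Meier observed survival on a monthly grid
#'
#' Product-limit estimate of all-cause observed survival for a cohort,
#' evaluated at every whole month from 0 to `max_months`, with Greenwood
#' standard errors \eqn{S(t)^2 \sum d_j / (n_j (n_j - d_j))} and at-risk
#' counts. Estimation is delegated to [survival::survfit()]; subjects dead
#' at a month leave the risk set before subjects censored at the same month
#' (the standard tie convention).
#'
#' @param cohort data.frame of patient records with `follow_up_months` and
#'   `vital_status` in `{dead, censored}`.
#' @param max_months length of the monthly grid.
#' @return A `survival_curve` data.frame: `month`, `survival`, `std_err`,
#'   `n_risk`, `n_event`.
#' @export
km_estimate <- function(cohort, max_months) {
  check_cohort(cohort)
  if (nrow(cohort) == 0L) stop_domain("km_estimate: cohort is empty")
  stopifnot(is.numeric(max_months), max_months >= 1)
  max_months <- as.integer(max_months)
  fit <- survival::survfit(
    survival::Surv(follow_up_months, vital_status == "dead") ~ 1,
    data = cohort
  )
  s <- summary(fit, times = 0:max_months, extend = TRUE)
  se <- s$std.err
  se[!is.finite(se)] <- 0
  structure(
    data.frame(
      month = 0:max_months,
      survival = s$surv,
      std_err = se,
      n_risk = s$n.risk,
      n_event = s$n.event
    ),
    class = c("survival_curve", "data.frame")
  )
}

#' Relative survival with capping and monotone correction
#'
#' Divides observed by expected survival month by month and applies the two
#' registry correction rules, in this order: (1) values above 100% are
#' capped at 1 (flag `"capped"`); (2) in a single left-to-right pass, any
#' value exceeding the previous month's value is replaced by it (flag
#' `"carried_back"`), making the curve non-increasing by construction.
#' Standard errors are `observed std_err / expected`, treating the
#' population-level expected curve as deterministic.
#'
#' @param observed a `survival_curve` from [km_estimate()].
#' @param expected an `expected_survival_curve` from [ederer2_expected()].
#'   Grids must be monthly from 0; the result covers their common range.
#' @return A `relative_survival_curve` data.frame: `month`, `rs`, `std_err`,
#'   `n_risk`, `correction` in `{none, capped, carried_back}`.
#' @export
relative_survival <- function(observed, expected) {
  for (nm in c("month")) {
    if (!is.data.frame(observed) || !is.data.frame(expected) ||
        !nm %in% names(observed) || !nm %in% names(expected)) {
      stop_domain("observed and expected must be curves with a 'month' column")
    }
  }
  months <- intersect(observed$month, expected$month)
  if (length(months) < 2L || !identical(as.integer(months),
                                        seq(0L, max(months)))) {
    stop_domain("relative_survival: grids do not align on months 0..M")
  }
  oi <- match(months, observed$month)
  ei <- match(months, expected$month)
  obs <- observed$survival[oi]
  obs_se <- observed$std_err[oi]
  exp_s <- expected$expected[ei]
  if (any(exp_s == 0 & obs > 0)) {
    stop_domain("relative_survival: expected survival is 0 where observed > 0 (month %d)",
                months[which(exp_s == 0 & obs > 0)[1]])
  }
  rs <- ifelse(exp_s == 0, 0, obs / exp_s)
  correction <- rep("none", length(rs))
  capped <- rs > 1
  rs[capped] <- 1
  correction[capped] <- "capped"
  for (i in seq_along(rs)[-1]) {
    if (rs[i] > rs[i - 1]) {
      rs[i] <- rs[i - 1]
      correction[i] <- "carried_back"
    }
  }
  structure(
    data.frame(
      month = as.integer(months),
      rs = rs,
      std_err = ifelse(exp_s == 0, 0, obs_se / exp_s),
      n_risk = observed$n_risk[oi],
      correction = correction
    ),
    class = c("relative_survival_curve", "data.frame")
  )
}

#' Z-test between two relative-survival curves at a fixed month
#'
#' Two-sided Z-test of the difference in relative survival at `at_month`,
#' treating the curves as independent:
#' `z = (rs_a - rs_b) / sqrt(se_a^2 + se_b^2)`, p from the standard normal.
#'
#' @param curve_a,curve_b `relative_survival_curve` objects.
#' @param at_month month at which to compare (must be on both grids).
#' @return An object of class `htest` with `statistic` (z) and `p.value`.
#' @export
rs_z_test <- function(curve_a, curve_b, at_month) {
  ia <- match(at_month, curve_a$month)
  ib <- match(at_month, curve_b$month)
  if (is.na(ia) || is.na(ib)) {
    stop_domain("rs_z_test: month %d is not on both curve grids", at_month)
  }
  ra <- curve_a$rs[ia]
  rb <- curve_b$rs[ib]
  sa <- curve_a$std_err[ia]
  sb <- curve_b$std_err[ib]
  if (sa == 0 && sb == 0) {
    if (ra != rb) {
      stop_domain("rs_z_test: both standard errors are zero with unequal values")
    }
    z <- 0
  } else {
    z <- (ra - rb) / sqrt(sa^2 + sb^2)
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(
      statistic = c(z = z), p.value = p,
      estimate = c(rs_a = ra, rs_b = rb),
      method = "Two-sample Z-test on relative survival",
      data.name = sprintf("relative survival at month %d", at_month)
    ),
    class = "htest"
  )
}

#' Two-group log-rank test on observed survival
#'
#' Standard two-sided log-rank test comparing the observed (all-cause)
#' survival of two cohorts, via [survival::survdiff()]: the statistic is
#' (O-E)^2/V with hypergeometric variance summed over distinct event months,
#' referred to a chi-square with 1 degree of freedom.
#'
#' @param cohort_a,cohort_b data.frames of patient records.
#' @return An object of class `htest` with `statistic` (chi-square) and
#'   `p.value`.
#' @export
logrank_test <- function(cohort_a, cohort_b) {
  check_cohort(cohort_a, "cohort_a")
  check_cohort(cohort_b, "cohort_b")
  if (nrow(cohort_a) == 0L || nrow(cohort_b) == 0L) {
    stop_domain("logrank_test: both cohorts must be non-empty")
  }
  df <- data.frame(
    time = c(cohort_a$follow_up_months, cohort_b$follow_up_months),
    dead = c(cohort_a$vital_status, cohort_b$vital_status) == "dead",
    group = rep(c("a", "b"), c(nrow(cohort_a), nrow(cohort_b)))
  )
  if (sum(df$dead) == 0L) {
    stop_domain("logrank_test: no events in either group; test undefined")
  }
  sd <- survival::survdiff(survival::Surv(time, dead) ~ group, data = df)
  structure(
    list(
      statistic = c(chisq = sd$chisq),
      parameter = c(df = 1),
      p.value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
      method = "Two-sided log-rank test on observed survival",
      data.name = sprintf("cohorts of n = %d and n = %d",
                          nrow(cohort_a), nrow(cohort_b))
    ),
    class = "htest"
  )
}

#' Write a survival or relative-survival curve as CSV
#'
#' @param curve a `survival_curve`, `expected_survival_curve` or
#'   `relative_survival_curve`.
#' @param path output file path.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(is.data.frame(curve))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
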
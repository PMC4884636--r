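test_that("Kaplan-Meier matches hand-computed product-limit values and
           Greenwood errors", {
  one <- tiny_cohort(5, "dead")
  k1 <- km_estimate(one, 8)
  expect_equal(k1$survival, c(rep(1, 5), rep(0, 4)))

  five <- tiny_cohort(c(3, 5, 7, 9, 10),
                      c("dead", "censored", "dead", "dead", "censored"))
  k <- km_estimate(five, 10)
  expect_equal(k$survival[k$month == 3], 0.8, tolerance = 1e-12)
  expect_equal(k$survival[k$month == 7], 0.8 * 2 / 3, tolerance = 1e-12)
  expect_equal(k$survival[k$month == 9], 0.8 * 2 / 3 / 2, tolerance = 1e-12)
  # Greenwood: S * sqrt(1/(5*4) + 1/(3*2) + 1/(2*1))
  expect_equal(k$std_err[k$month == 9],
               (4 / 15) * sqrt(1 / 20 + 1 / 6 + 1 / 2), tolerance = 1e-10)
  expect_true(all(diff(k$survival) <= 0))
  expect_true(all(diff(k$n_risk) <= 0))
})

test_that("Kaplan-Meier equals the brute-force product over event times on
           random small cohorts", {
  set.seed(202)
  for (i in 1:50) {
    co <- random_tiny_cohort()
    k <- km_estimate(co, 24)
    oracle <- bf_product_limit(co$follow_up_months,
                               co$vital_status == "dead", 0:24)
    expect_equal(k$survival, oracle, tolerance = 1e-12)
  }
})

test_that("relative survival applies capping then the carry-back rule", {
  # observed == expected: identity, no corrections
  obs <- as_observed(c(1, 0.95, 0.90, 0.85))
  rs0 <- relative_survival(obs, as_expected(c(1, 0.95, 0.90, 0.85)))
  expect_equal(rs0$rs, rep(1, 4))
  expect_true(all(rs0$correction == "none"))

  # raw ratios (1.0, 1.02, 0.95): month 1 capped at 100%
  rs1 <- relative_survival(as_observed(c(1.0, 1.02, 0.95)),
                           as_expected(c(1, 1, 1)))
  expect_equal(rs1$rs, c(1.0, 1.0, 0.95))
  expect_equal(rs1$correction, c("none", "capped", "none"))

  # raw ratios (1.0, 0.90, 0.93, 0.88): month 2 carried back
  rs2 <- relative_survival(as_observed(c(1.0, 0.90, 0.93, 0.88)),
                           as_expected(c(1, 1, 1, 1)))
  expect_equal(rs2$rs, c(1.0, 0.90, 0.90, 0.88))
  expect_equal(rs2$correction, c("none", "none", "carried_back", "none"))
})

test_that("corrected relative survival is non-increasing for adversarial
           inputs and equals observed survival under an immortal population", {
  set.seed(303)
  for (i in 1:50) {
    raw <- pmax(cumprod(c(1, runif(30, 0.9, 1.08))), 0)
    rs <- relative_survival(as_observed(raw), as_expected(rep(1, 31)))
    expect_true(all(diff(rs$rs) <= 0))
    expect_true(all(rs$rs >= 0 & rs$rs <= 1))
  }
  co <- tiny_cohort(c(4, 9, 15, 20, 30),
                    c("dead", "dead", "censored", "dead", "censored"))
  pip_obs <- km_estimate(co, 30)
  rs <- relative_survival(pip_obs, ederer2_expected(co, flat_lt, 30))
  expect_equal(rs$rs, pip_obs$survival, tolerance = 1e-12)
})

test_that("relative survival signals undefined ratios and misaligned grids", {
  expect_error(
    relative_survival(as_observed(c(1, 0.5, 0.4)),
                      as_expected(c(1, 0, 0))),
    "expected survival is 0"
  )
  bad_exp <- data.frame(month = c(0, 2, 4), expected = c(1, 0.9, 0.8))
  expect_error(relative_survival(as_observed(c(1, 0.9, 0.8)), bad_exp),
               "align")
})

test_that("Z-test between relative-survival curves is two-sided and
           antisymmetric", {
  ca <- data.frame(month = c(0, 120), rs = c(1, 0.97),
                   std_err = c(0, 0.01), n_risk = c(10, 5))
  cb <- data.frame(month = c(0, 120), rs = c(1, 0.71),
                   std_err = c(0, 0.03), n_risk = c(10, 5))
  zt <- rs_z_test(ca, cb, 120)
  expect_equal(unname(zt$statistic), 0.26 / sqrt(0.01^2 + 0.03^2),
               tolerance = 1e-10)
  expect_equal(unname(zt$statistic), 8.2219, tolerance = 1e-4)
  expect_lt(zt$p.value, 0.001)

  back <- rs_z_test(cb, ca, 120)
  expect_equal(unname(back$statistic), -unname(zt$statistic))
  expect_equal(back$p.value, zt$p.value)

  same <- rs_z_test(ca, ca, 120)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)

  degenerate_a <- data.frame(month = 0:1, rs = c(1, 0.9),
                             std_err = c(0, 0), n_risk = c(2, 1))
  degenerate_b <- data.frame(month = 0:1, rs = c(1, 0.8),
                             std_err = c(0, 0), n_risk = c(2, 1))
  expect_error(rs_z_test(degenerate_a, degenerate_b, 1), "zero")
})

test_that("log-rank test matches the single-event-time hypergeometric
           calculation and is symmetric", {
  a <- tiny_cohort(rep(1, 10), "dead")
  b <- tiny_cohort(rep(24, 10), "censored")
  lr <- logrank_test(a, b)
  # one event time: O - E = 10 - 5; V = 10 * 0.5 * 0.5 * 10/19
  expect_equal(unname(lr$statistic), 25 / (25 / 19), tolerance = 1e-10)
  expect_equal(unname(logrank_test(b, a)$statistic),
               unname(lr$statistic), tolerance = 1e-12)

  five <- tiny_cohort(c(3, 5, 7, 9, 10),
                      c("dead", "censored", "dead", "dead", "censored"))
  self <- logrank_test(five, five)
  expect_equal(unname(self$statistic), 0, tolerance = 1e-12)
  expect_equal(self$p.value, 1, tolerance = 1e-12)

  mixed <- rbind(a, b)
  perm <- mixed[rev(seq_len(nrow(mixed))), ]
  expect_equal(unname(logrank_test(mixed, perm)$statistic), 0,
               tolerance = 1e-12)
  expect_error(logrank_test(tiny_cohort(5, "censored"),
                            tiny_cohort(6, "censored")),
               "no events")
})
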
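test_that("generation is deterministic in the seed and leaves the RNG alone", {
  spec <- recovery_spec(n_per_stratum = 100L, seed = 9L)
  lt <- synthetic_life_table()
  set.seed(1)
  before <- .Random.seed
  a <- generate_cohort(spec, lt)
  expect_identical(before, .Random.seed)
  b <- generate_cohort(spec, lt)
  expect_identical(a, b)
  spec2 <- recovery_spec(n_per_stratum = 100L, seed = 10L)
  expect_false(identical(a, generate_cohort(spec2, lt)))
})

test_that("record-level invariants hold and %LN+ stays in its stratum range", {
  spec <- recovery_spec(n_per_stratum = 300L, seed = 3L)
  co <- generate_cohort(spec, synthetic_life_table())
  expect_equal(nrow(co), 900L)
  expect_identical(names(co), rsinflect:::patient_record_fields())
  expect_true(all(co$nodes_positive <= co$nodes_examined))
  expect_true(all(co$follow_up_months >= 0))
  expect_true(all(co$vital_status %in% c("dead", "censored")))
  frac <- co$nodes_positive / co$nodes_examined
  # strata are generated in order, n = 300 each
  expect_true(all(frac[1:300] > 0 & frac[1:300] < 0.10))
  expect_true(all(frac[301:600] >= 0.10 & frac[301:600] < 0.40))
  expect_true(all(frac[601:900] >= 0.40 & frac[601:900] <= 1))
})

test_that("with no excess risk, no dropout and an immortal population nobody
           dies before the horizon", {
  spec <- cohort_spec(
    stratum_spec("null", c(0.1, 0.4), 200L, b1 = 0, b2 = 5, b3 = 0.2,
                 censoring_rate = 0, horizon_months = 600L),
    demographics = cohort_demographics(year_range = c(2000, 2000)),
    seed = 4L
  )
  co <- generate_cohort(spec, flat_lt)
  expect_true(all(co$vital_status == "censored"))
  expect_true(all(co$follow_up_months == 600L))
})

test_that("with b1 = 0 the cohort's observed survival tracks the life table", {
  lt <- const_lt(0.94)
  dgm <- cohort_demographics(age_mean = 62, age_sd = 0, age_range = c(62, 62),
                             race_probs = c(white = 1),
                             year_range = c(2000, 2000))
  spec <- cohort_spec(
    stratum_spec("null", c(0.1, 0.4), 4000L, b1 = 0, b2 = 5, b3 = 0.2,
                 censoring_rate = 0, horizon_months = 240L),
    demographics = dgm, seed = 5L
  )
  co <- generate_cohort(spec, lt)
  k <- km_estimate(co, 240)
  for (m in c(60, 120, 240)) {
    truth <- 0.94^(m / 12)
    mc <- 4 * sqrt(truth * (1 - truth) / 4000)
    expect_lt(abs(k$survival[k$month == m] - truth), mc)
  }
})

test_that("marginal survival matches the true inverse Gompertz law within
           binomial error", {
  spec <- cohort_spec(
    stratum_spec("hi", c(0.4, 1), 10000L, b1 = 0.469, b2 = 4.51, b3 = 0.222,
                 censoring_rate = 0, horizon_months = 240L),
    seed = 6L
  )
  co <- generate_cohort(spec, flat_lt)
  k <- km_estimate(co, 240)
  truth <- inverse_gompertz_rs(k$month / 12, 0.469, 4.51, 0.222)
  se <- sqrt(pmax(truth * (1 - truth), 1e-12) / 10000)
  dev <- abs(k$survival - truth)
  expect_true(all(dev[-1] < 4 * se[-1] + 1e-9))
  expect_lt(abs(k$survival[k$month == 120] -
                  inverse_gompertz_rs(10, 0.469, 4.51, 0.222)),
            4 * sqrt(0.713 * 0.287 / 10000))
})

test_that("stratum and spec validation rejects invalid truth", {
  expect_error(stratum_spec("x", c(0.1, 0.4), 10, b1 = 1.5, b2 = 5, b3 = 0.2),
               "b1")
  expect_error(cohort_spec(list(
    stratum_spec("a", c(0.0, 0.2), 10, 0.5, 5, 0.2),
    stratum_spec("b", c(0.1, 0.4), 10, 0.5, 5, 0.2)
  )), "disjoint")
  empty <- cohort_spec(stratum_spec("z", c(0.1, 0.4), 0L, 0.5, 5, 0.2),
                       seed = 2L)
  expect_equal(nrow(generate_cohort(empty, flat_lt)), 0L)
})

test_that("a life-table coverage gap is reported with the missing cell", {
  lt <- uniform_life_table(0.9, ages = 40:90, years = 1995:2005)
  dgm <- cohort_demographics(year_range = c(2004, 2004))
  spec <- cohort_spec(
    stratum_spec("a", c(0.1, 0.4), 20L, 0.5, 5, 0.2, horizon_months = 120L),
    demographics = dgm, seed = 1L
  )
  expect_error(generate_cohort(spec, lt), "year=2006")
})

test_that("cohort CSV and spec config files round-trip", {
  spec <- recovery_spec(n_per_stratum = 50L, seed = 8L)
  lt <- synthetic_life_table()
  co <- generate_cohort(spec, lt)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  expect_identical(readLines(path, n = 1L),
                   paste(rsinflect:::patient_record_fields(), collapse = ","))
  co2 <- read_cohort_csv(path)
  expect_equal(co2, co)

  spath <- tempfile(fileext = ".dcf")
  write_cohort_spec(spec, spath)
  spec2 <- read_cohort_spec(spath)
  expect_identical(generate_cohort(spec2, lt), co)
})
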
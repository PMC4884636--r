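test_that("life table construction enforces rectangularity and bounds", {
  g <- expand.grid(sex = "male", race = c("white", "black"), age = 60:62,
                   year = 2000:2001, stringsAsFactors = FALSE)
  g$annual_survival <- 0.9
  expect_s3_class(life_table(g), "life_table")
  expect_error(life_table(g[-1, ]), "rectangular")
  expect_error(life_table(rbind(g, g[1, ])), "duplicated")
  g2 <- g
  g2$annual_survival[1] <- 1.2
  expect_error(life_table(g2), "\\[0, 1\\]")
  g3 <- g[g$age != 61, ]
  expect_error(life_table(g3), "contiguous")
})

test_that("life table CSV round trip is exact and headers are strict", {
  lt <- const_lt(0.93, ages = 60:65, years = 2000:2002)
  path <- tempfile(fileext = ".csv")
  write_life_table(lt, path)
  lt2 <- read_life_table(path)
  expect_equal(lt2$data, lt$data)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("sex,race,age,calendar_year,annual_survival",
               "male,white,60,2000,0.9"), bad)
  expect_error(read_life_table(bad), "expected header")
})

test_that("expected survival is 1 under an all-1 table and follows the
           constant-hazard closed form", {
  co <- tiny_cohort(36, "censored")
  e <- ederer2_expected(co, flat_lt, 36)
  expect_equal(e$expected, rep(1, 37))

  lt9 <- const_lt(0.9)
  e9 <- ederer2_expected(co, lt9, 24)
  expect_equal(e9$expected[e9$month == 12], 0.9, tolerance = 1e-12)
  expect_equal(e9$expected[e9$month == 24], 0.81, tolerance = 1e-12)
})

test_that("two-subject interval mean matches the hand-computed cumulative product", {
  g <- expand.grid(sex = "male", race = c("r1", "r2"), age = 60:62,
                   year = 2000:2002, stringsAsFactors = FALSE)
  g$annual_survival <- ifelse(g$race == "r1", 0.8, 1.0)
  lt <- life_table(g)
  co <- tiny_cohort(c(24, 24), "censored")
  co$race <- c("r1", "r2")
  e <- ederer2_expected(co, lt, 12)
  # hand oracle: monthly interval mean (0.8^(1/12) + 1)/2, cumulated 12 times
  hand <- ((0.8^(1 / 12) + 1) / 2)^12
  expect_equal(e$expected[e$month == 12], hand, tolerance = 1e-12)
  expect_equal(hand, 0.894891, tolerance = 1e-6)
})

test_that("homogeneous cohorts reproduce the single-subject life-table curve
           regardless of observed deaths", {
  lt <- const_lt(0.88)
  mixed <- tiny_cohort(c(5, 12, 40, 60, 60),
                       c("dead", "censored", "dead", "censored", "censored"))
  single <- tiny_cohort(60, "censored")
  e_mixed <- ederer2_expected(mixed, lt, 48)
  e_single <- ederer2_expected(single, lt, 48)
  expect_equal(e_mixed$expected, e_single$expected, tolerance = 1e-12)
})

test_that("expected curves are non-increasing, within [0,1], and truncate when
           the risk set empties", {
  lt <- synthetic_life_table(ages = 40:119, years = 1990:2040)
  set.seed(71)
  for (i in 1:5) {
    co <- tiny_cohort(sample(1:80, 8, replace = TRUE),
                      sample(c("dead", "censored"), 8, replace = TRUE),
                      age = sample(45:80, 8, replace = TRUE),
                      race = sample(c("white", "black", "other"), 8,
                                    replace = TRUE))
    e <- ederer2_expected(co, lt, 60)
    expect_true(all(diff(e$expected) <= 1e-12))
    expect_true(all(e$expected >= 0 & e$expected <= 1))
  }
  short <- tiny_cohort(c(6, 4), c("censored", "dead"))
  e <- ederer2_expected(short, flat_lt, 36)
  expect_equal(max(e$month), 6)
})

test_that("censoring subjects with below-average expected survival never
           decreases later interval means", {
  g <- expand.grid(sex = "male", race = c("frail", "fit"), age = 60:64,
                   year = 2000:2004, stringsAsFactors = FALSE)
  g$annual_survival <- ifelse(g$race == "frail", 0.7, 0.99)
  lt <- life_table(g)
  full <- tiny_cohort(rep(36, 4), "censored")
  full$race <- c("frail", "frail", "fit", "fit")
  depleted <- full
  depleted$follow_up_months[depleted$race == "frail"] <- 12L
  e_full <- ederer2_expected(full, lt, 30)
  e_dep <- ederer2_expected(depleted, lt, 30)
  ratio_full <- e_full$expected[-1] / e_full$expected[-31]
  ratio_dep <- e_dep$expected[-1] / e_dep$expected[-31]
  expect_true(all(ratio_dep[13:30] >= ratio_full[13:30] - 1e-12))
})

test_that("attained ages above the table maximum close at the top row and
           true coverage gaps are named", {
  lt <- const_lt(0.9, ages = 60:65, years = 2000:2010)
  old <- tiny_cohort(48, "censored", age = 64L)
  expect_message(e <- ederer2_expected(old, lt, 48), "maximum-age row")
  expect_equal(e$expected[e$month == 48], 0.9^4, tolerance = 1e-12)
  late <- tiny_cohort(48, "censored", dx_year = 2010L)
  expect_error(ederer2_expected(late, lt, 48), "year=2011")
})
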
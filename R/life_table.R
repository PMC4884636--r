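#' Construct a demographic life table
#'
#' A life table stores the annual probability of surviving one further year
#' for members of the general population, keyed by sex, race, integer age and
#' calendar year. It is the reference population used to compute expected
#' survival (and hence relative survival) for a cancer cohort.
#'
#' The key set must be rectangular: every combination of the sexes, races,
#' ages and years present in `data` must appear exactly once, and the age and
#' year ranges must be contiguous. Lookups above the maximum tabulated age use
#' the maximum-age row (standard life-table closure); any other lookup outside
#' the table is an error naming the missing cell.
#'
#' @param data data.frame with columns `sex`, `race`, `age`, `year`,
#'   `annual_survival` (probability in \[0, 1\]).
#' @return An object of class `life_table`.
#' @seealso [read_life_table()], [synthetic_life_table()], [ederer2_expected()]
#' @export
life_table <- function(data) {
  required <- c("sex", "race", "age", "year", "annual_survival")
  if (!is.data.frame(data) || !all(required %in% names(data))) {
    stop_domain("life table needs columns: %s", paste(required, collapse = ", "))
  }
  data <- data[required]
  data$sex <- as.character(data$sex)
  data$race <- as.character(data$race)
  data$age <- as.integer(data$age)
  data$year <- as.integer(data$year)
  data$annual_survival <- as.numeric(data$annual_survival)
  if (anyNA(data)) stop_domain("life table contains missing values")
  if (any(data$annual_survival < 0 | data$annual_survival > 1)) {
    stop_domain("annual_survival values must lie in [0, 1]")
  }
  sexes <- sort(unique(data$sex))
  races <- sort(unique(data$race))
  ages <- sort(unique(data$age))
  years <- sort(unique(data$year))
  if (!identical(ages, seq(min(ages), max(ages))) ||
      !identical(years, seq(min(years), max(years)))) {
    stop_domain("life table age and year ranges must be contiguous integers")
  }
  n_expected <- length(sexes) * length(races) * length(ages) * length(years)
  key <- lt_key(data$sex, data$race, data$age, data$year)
  if (anyDuplicated(key)) stop_domain("life table has duplicated (sex, race, age, year) cells")
  if (nrow(data) != n_expected) {
    stop_domain("life table is not rectangular: expected %d cells, found %d",
                n_expected, nrow(data))
  }
  structure(
    list(
      data = `rownames<-`(data[order(key), , drop = FALSE], NULL),
      lookup = stats::setNames(data$annual_survival, key),
      sexes = sexes, races = races,
      age_range = range(ages), year_range = range(years)
    ),
    class = "life_table"
  )
}

lt_key <- function(sex, race, age, year) {
  paste(sex, race, age, year, sep = "\r")
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf(
    "Life table: ages %d-%d, years %d-%d, sexes {%s}, races {%s} (%d cells)\n",
    x$age_range[1], x$age_range[2], x$year_range[1], x$year_range[2],
    paste(x$sexes, collapse = ", "), paste(x$races, collapse = ", "),
    nrow(x$data)
  ))
  invisible(x)
}

# Vectorised annual-survival lookup. Ages above the table maximum are closed
# at the maximum-age row; any other out-of-table cell is a coverage error.
lt_annual <- function(table, sex, race, age, year) {
  stopifnot(inherits(table, "life_table"))
  age <- as.integer(age)
  year <- as.integer(year)
  age <- pmin(age, table$age_range[2])
  p <- unname(table$lookup[lt_key(sex, race, age, year)])
  if (anyNA(p)) {
    i <- which(is.na(p))[1]
    stop_domain(
      "life table does not cover cell (sex=%s, race=%s, age=%d, year=%d)",
      sex[min(i, length(sex))], race[min(i, length(race))], age[i], year[i]
    )
  }
  p
}

# Annual-survival matrix for a cohort: one row per subject, one column per
# attained-year offset (0, 1, ...). `need` masks which (subject, offset)
# cells must be covered; uncovered unneeded cells stay NA.
lt_annual_matrix <- function(table, cohort, offsets, need = NULL) {
  n <- nrow(cohort)
  out <- matrix(NA_real_, n, length(offsets))
  for (j in seq_along(offsets)) {
    o <- offsets[j]
    rows <- if (is.null(need)) rep(TRUE, n) else need[, j]
    if (!any(rows)) next
    out[rows, j] <- lt_annual(
      table,
      cohort$sex[rows], cohort$race[rows],
      cohort$age_at_dx[rows] + o, cohort$dx_year[rows] + o
    )
  }
  out
}

expected_survival_curve <- function(month, expected) {
  structure(
    data.frame(month = as.integer(month), expected = as.numeric(expected)),
    class = c("expected_survival_curve", "data.frame")
  )
}

#' Ederer II expected survival for a cohort
#'
#' Computes the matched expected-survival curve of a cohort against a general
#' population life table using the Ederer II convention: at each month the
#' expected interval survival is the average of the individual monthly
#' expected survival probabilities over the subjects still at risk (alive and
#' uncensored) in the observed data, so the matched population shrinks with
#' the cohort. The curve is the cumulative product of these interval means.
#'
#' Annual probabilities are converted to monthly ones assuming a constant
#' hazard within each year (`p_month = p_annual^(1/12)`); attained age and
#' calendar year advance together in whole years, month `m` using offset
#' `floor(m/12)` from diagnosis. If the at-risk set empties before
#' `max_months`, the curve is truncated at the last month with subjects at
#' risk.
#'
#' @param cohort data.frame of patient records (see [generate_cohort()] for
#'   the column contract).
#' @param table a [life_table()].
#' @param max_months integer; length of the monthly grid.
#' @return An `expected_survival_curve` data.frame with columns `month`
#'   (0..max_months) and `expected` (cumulative expected survival,
#'   `expected[month 0] = 1`).
#' @export
ederer2_expected <- function(cohort, table, max_months) {
  check_cohort(cohort)
  stopifnot(inherits(table, "life_table"),
            is.numeric(max_months), max_months >= 1)
  max_months <- as.integer(max_months)
  if (nrow(cohort) == 0L) stop_domain("ederer2_expected: cohort is empty")
  fu <- cohort$follow_up_months
  max_attained <- max(cohort$age_at_dx + fu %/% 12)
  if (max_attained > table$age_range[2]) {
    message(sprintf(
      "ederer2_expected: attained ages above %d closed at the maximum-age row",
      table$age_range[2]
    ))
  }

  offsets <- 0:(max_months %/% 12)
  # subject contributes to offset o iff at risk for some month m with
  # floor(m/12) == o, i.e. fu >= max(1, 12*o)
  need <- outer(fu, pmax(1L, 12L * offsets), `>=`)
  pann <- lt_annual_matrix(table, cohort, offsets, need)
  pmon <- pann^(1 / 12)

  interval <- numeric(max_months)
  kept <- 0L
  for (m in seq_len(max_months)) {
    at_risk <- fu >= m
    if (!any(at_risk)) break
    interval[m] <- mean(pmon[at_risk, m %/% 12 + 1L])
    kept <- m
  }
  if (kept == 0L) stop_domain("ederer2_expected: no subjects at risk beyond month 0")
  expected_survival_curve(0:kept, c(1, cumprod(interval[seq_len(kept)])))
}

#' Read / write a life table as CSV
#'
#' The CSV must have exactly the header
#' `sex,race,age,year,annual_survival`, probabilities as decimals.
#'
#' @param path file path.
#' @return [read_life_table()] returns a `life_table`; `write_life_table`
#'   returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop_domain("life-table file not found: %s", path)
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  expected <- c("sex", "race", "age", "year", "annual_survival")
  if (!identical(header, expected)) {
    stop_domain("%s: expected header '%s', found '%s'",
                path, paste(expected, collapse = ","),
                paste(header, collapse = ","))
  }
  life_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_life_table
#' @param table a `life_table` object.
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "life_table"))
  utils::write.csv(table$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthetic population life tables
#'
#' `synthetic_life_table()` builds a plausible male general-population life
#' table from a Gompertz-Makeham hazard, `h(age) = a + b*exp(c*age)`, scaled
#' by a per-race hazard ratio and constant across calendar years. It is a
#' synthetic stand-in for registry-issued expected-survival tables, intended
#' for simulation and testing. `uniform_life_table()` sets every cell to the
#' same annual survival (the value 1 yields a population that never dies, for
#' which relative and observed survival coincide).
#'
#' @param ages,years integer vectors (contiguous) of ages and calendar years.
#' @param races,sexes category labels.
#' @param makeham named numeric vector `c(a=, b=, c=)` of hazard parameters
#'   (per-year hazard at age x is `a + b*exp(c*x)`).
#' @param race_hr named hazard ratios, one per race.
#' @return A [life_table()].
#' @export
synthetic_life_table <- function(ages = 30:119, years = 1980:2045,
                                 races = c("white", "black", "other"),
                                 sexes = "male",
                                 makeham = c(a = 5e-4, b = 3e-5, c = 0.09),
                                 race_hr = c(white = 1, black = 1.25, other = 0.9)) {
  stopifnot(all(races %in% names(race_hr)))
  grid <- expand.grid(sex = sexes, race = races, age = ages, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  hazard <- (makeham[["a"]] + makeham[["b"]] * exp(makeham[["c"]] * grid$age)) *
    race_hr[grid$race]
  grid$annual_survival <- pmin(1, pmax(0, exp(-unname(hazard))))
  life_table(grid)
}

#' @rdname synthetic_life_table
#' @param annual_survival constant annual survival probability for all cells.
#' @export
uniform_life_table <- function(annual_survival = 1, ages = 0:119,
                               years = 1980:2050,
                               races = c("white", "black", "other"),
                               sexes = "male") {
  stopifnot(annual_survival >= 0, annual_survival <= 1)
  grid <- expand.grid(sex = sexes, race = races, age = ages, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$annual_survival <- annual_survival
  life_table(grid)
}
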
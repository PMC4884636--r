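#' Specify one %LN+ stratum of a synthetic cohort
#'
#' A stratum prescribes, for a block of subjects whose lymph-node ratio
#' (%LN+) falls in `ln_range`, the true relative-survival law they are
#' simulated under: inverse Gompertzian kinetics with parameters
#' `(b1, b2, b3)` (see [inverse_gompertz_rs()]). Simulation truth is
#' restricted to `b1 <= 1` so that the implied survival law stays
#' non-negative for all t, even though [fit_inverse_gompertz()] deliberately
#' admits `b1 > 1` when fitting empirical curves.
#'
#' @param label stratum label.
#' @param ln_range numeric length-2, half-open %LN+ interval `[lo, hi)` in
#'   \[0, 1\] (`hi = 1` is treated as closed).
#' @param n number of subjects.
#' @param b1 true depth parameter, in \[0, 1\] (`b1 = 0` means relative
#'   survival identically 1).
#' @param b2,b3 true shape and rate parameters, `> 0` (`b3` per year).
#' @param censoring_rate monthly dropout probability in \[0, 1); dropout is
#'   geometric and independent of the event process. See
#'   [monthly_dropout_rate()] to convert a cumulative dropout fraction.
#' @param horizon_months administrative censoring time (months).
#' @return A `stratum_spec` object.
#' @export
stratum_spec <- function(label, ln_range, n, b1, b2, b3,
                         censoring_rate = 0, horizon_months = 300L) {
  stopifnot(length(ln_range) == 2L, ln_range[1] >= 0, ln_range[2] <= 1,
            ln_range[1] < ln_range[2])
  stopifnot(is.numeric(n), n >= 0)
  if (b1 < 0 || b1 > 1) {
    stop_domain("stratum_spec: true b1 must lie in [0, 1] (got %g)", b1)
  }
  if (b2 <= 0 || b3 <= 0) stop_domain("stratum_spec: b2 and b3 must be positive")
  stopifnot(censoring_rate >= 0, censoring_rate < 1, horizon_months >= 1)
  structure(
    list(label = as.character(label), ln_range = as.numeric(ln_range),
         n = as.integer(n), b1 = b1, b2 = b2, b3 = b3,
         censoring_rate = censoring_rate,
         horizon_months = as.integer(horizon_months)),
    class = "stratum_spec"
  )
}

#' Demographic composition of a synthetic registry cohort
#'
#' Defaults emulate a male radical-prostatectomy registry cohort: age at
#' diagnosis normal (mean 62.48, SD 7.4) rounded and truncated to
#' `age_range`; race drawn as white/black/other with probabilities
#' 0.8364/0.1154/0.0482; diagnosis year uniform over 1988-2012; tumour grade
#' predominantly III; about a fifth of subjects flagged as irradiated.
#'
#' @param age_mean,age_sd,age_range age-at-diagnosis distribution (years).
#' @param race_probs,grade_probs,radiation_probs named category
#'   probabilities (normalised internally).
#' @param year_range inclusive diagnosis-year range.
#' @return A `cohort_demographics` object.
#' @export
cohort_demographics <- function(age_mean = 62.48, age_sd = 7.4,
                                age_range = c(40, 90),
                                race_probs = c(white = 0.8364, black = 0.1154,
                                               other = 0.0482),
                                year_range = c(1988, 2012),
                                grade_probs = c(I = 0.0071, II = 0.2094,
                                                III = 0.7661, IV = 0.0119,
                                                unknown = 0.0056),
                                radiation_probs = c(no = 0.7615, yes = 0.2063,
                                                    unknown = 0.0322)) {
  norm <- function(p) p / sum(p)
  structure(
    list(age_mean = age_mean, age_sd = age_sd,
         age_range = as.integer(age_range),
         race_probs = norm(race_probs),
         year_range = as.integer(year_range),
         grade_probs = norm(grade_probs),
         radiation_probs = norm(radiation_probs)),
    class = "cohort_demographics"
  )
}

#' Distribution of the number of lymph nodes examined
#'
#' Shifted, truncated Poisson: `examined = min + Poisson(lambda)`, capped at
#' `max`. The default (`min = 1`, `lambda = 11`) gives a mean of about 12
#' nodes per dissection.
#'
#' @param lambda Poisson mean of the count above `min`.
#' @param min,max integer bounds (min >= 1).
#' @export
ln_examined_poisson <- function(lambda = 11, min = 1L, max = 60L) {
  stopifnot(lambda >= 0, min >= 1, max >= min)
  structure(list(lambda = lambda, min = as.integer(min), max = as.integer(max)),
            class = "ln_examined_poisson")
}

#' Convert a cumulative dropout fraction to a monthly rate
#'
#' Returns the monthly geometric dropout probability under which a fraction
#' `total` of subjects drop out before `horizon_months`.
#'
#' @param total cumulative dropout probability over the horizon, in \[0, 1).
#' @param horizon_months horizon in months.
#' @export
monthly_dropout_rate <- function(total, horizon_months) {
  stopifnot(total >= 0, total < 1, horizon_months >= 1)
  1 - (1 - total)^(1 / horizon_months)
}

#' Full specification of a synthetic cohort
#'
#' @param strata list of [stratum_spec()] objects with pairwise-disjoint
#'   `ln_range` intervals.
#' @param demographics a [cohort_demographics()].
#' @param ln_examined a [ln_examined_poisson()].
#' @param seed integer seed; two generations from the same spec are
#'   byte-identical.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(strata, demographics = cohort_demographics(),
                        ln_examined = ln_examined_poisson(), seed = 1L) {
  if (inherits(strata, "stratum_spec")) strata <- list(strata)
  stopifnot(length(strata) >= 1,
            all(vapply(strata, inherits, logical(1), "stratum_spec")),
            inherits(demographics, "cohort_demographics"),
            inherits(ln_examined, "ln_examined_poisson"))
  ranges <- t(vapply(strata, function(s) s$ln_range, numeric(2)))
  ord <- order(ranges[, 1])
  if (nrow(ranges) > 1L &&
      any(ranges[ord, 1][-1] < ranges[ord, 2][-nrow(ranges)])) {
    stop_domain("cohort_spec: stratum ln_range intervals must be disjoint")
  }
  structure(
    list(strata = strata, demographics = demographics,
         ln_examined = ln_examined, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic registry cohort
#'
#' Draws `sum(n)` patient records whose survival obeys, within each stratum,
#' `S(t) = S_expected(t | demographics) * RS_true(t; b1, b2, b3)`: the
#' expected-survival factor comes from the supplied life table (constant
#' monthly hazard within each tabulated year, attained age and calendar year
#' advancing at 12-month boundaries) and the relative-survival factor from
#' the stratum's inverse Gompertzian law. Death times are drawn by
#' inverse-transform sampling on the monthly survival grid and recorded at
#' the month of death; censoring is the minimum of an independent geometric
#' dropout time and the administrative horizon. The lymph-node pair
#' `(examined, positive)` is drawn so that the ratio falls in the stratum's
#' `ln_range` (the positive count is sampled uniformly over the feasible
#' counts for the drawn examined count; infeasible examined counts are
#' redrawn).
#'
#' @param spec a [cohort_spec()].
#' @param table a [life_table()] covering every generated
#'   (sex, race, age, year) cell through the horizon.
#' @return data.frame of patient records (one row per subject, columns as in
#'   `patient_record_fields()`).
#' @export
generate_cohort <- function(spec, table) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(table, "life_table"))
  old <- push_seed(spec$seed)
  on.exit(pop_seed(old), add = TRUE)
  parts <- lapply(spec$strata, generate_stratum, spec = spec, table = table)
  out <- do.call(rbind, parts)
  if (is.null(out) || nrow(out) == 0L) {
    out <- empty_cohort()
  } else {
    out$patient_id <- sprintf("P%06d", seq_len(nrow(out)))
    rownames(out) <- NULL
  }
  out[patient_record_fields()]
}

empty_cohort <- function() {
  data.frame(
    patient_id = character(), age_at_dx = integer(), sex = character(),
    race = character(), dx_year = integer(), follow_up_months = integer(),
    vital_status = character(), nodes_examined = integer(),
    nodes_positive = integer(), grade = character(), radiation = character(),
    stringsAsFactors = FALSE
  )
}

generate_stratum <- function(s, spec, table) {
  n <- s$n
  if (n == 0L) return(NULL)
  dgm <- spec$demographics
  age <- as.integer(pmin(pmax(round(stats::rnorm(n, dgm$age_mean, dgm$age_sd)),
                              dgm$age_range[1]), dgm$age_range[2]))
  race <- resample(names(dgm$race_probs), n, prob = dgm$race_probs)
  dx_year <- resample(seq(dgm$year_range[1], dgm$year_range[2]), n)
  grade <- resample(names(dgm$grade_probs), n, prob = dgm$grade_probs)
  radiation <- resample(names(dgm$radiation_probs), n,
                        prob = dgm$radiation_probs)

  nodes <- draw_node_counts(n, s$ln_range, spec$ln_examined)

  H <- s$horizon_months
  cohort_stub <- data.frame(sex = "male", race = race, age_at_dx = age,
                            dx_year = dx_year, stringsAsFactors = FALSE)
  offsets <- 0:(H %/% 12)
  pann <- lt_annual_matrix(table, cohort_stub, offsets)
  log_pmon <- log(pann) / 12
  month_offset <- (seq_len(H)) %/% 12 + 1L
  # cumulative log expected survival, n x H
  log_sexp <- t(apply(log_pmon[, month_offset, drop = FALSE], 1, cumsum))
  rs_true <- if (s$b1 == 0) rep(1, H) else {
    inverse_gompertz_rs(seq_len(H) / 12, s$b1, s$b2, s$b3)
  }
  surv <- exp(log_sexp) * rep(rs_true, each = n)

  u <- stats::runif(n)
  months_above <- rowSums(surv > u)       # months m with S(m) > u
  death <- ifelse(months_above < H, months_above + 1L, Inf)
  dropout <- if (s$censoring_rate > 0) {
    stats::rgeom(n, s$censoring_rate) + 1L
  } else rep(Inf, n)
  cens <- pmin(dropout, H)
  fu <- pmin(death, cens)
  status <- ifelse(death <= cens, "dead", "censored")

  data.frame(
    patient_id = NA_character_,
    age_at_dx = age, sex = "male", race = race, dx_year = dx_year,
    follow_up_months = as.integer(fu), vital_status = status,
    nodes_examined = nodes$examined, nodes_positive = nodes$positive,
    grade = grade, radiation = radiation,
    stringsAsFactors = FALSE
  )
}

# Draw (examined, positive) pairs with positive/examined in [lo, hi)
# (hi = 1 closed). Positive counts are uniform over the feasible set for the
# drawn examined count; examined counts with empty feasible sets are redrawn.
draw_node_counts <- function(n, ln_range, dist) {
  lo <- ln_range[1]
  hi <- ln_range[2]
  examined <- integer(n)
  positive <- integer(n)
  for (i in seq_len(n)) {
    for (attempt in 1:1000) {
      e <- min(dist$min + stats::rpois(1L, dist$lambda), dist$max)
      k <- 0:e
      frac <- k / e
      ok <- frac >= lo & (if (hi >= 1) frac <= 1 else frac < hi)
      if (any(ok)) {
        feasible <- k[ok]
        examined[i] <- e
        positive[i] <- feasible[sample.int(length(feasible), 1L)]
        break
      }
      if (attempt == 1000L) {
        stop_domain("could not draw node counts with ratio in [%g, %g)", lo, hi)
      }
    }
  }
  list(examined = examined, positive = positive)
}

#' Read / write a cohort as CSV
#'
#' The CSV header is exactly the patient-record field names
#' (`patient_id, age_at_dx, sex, race, dx_year, follow_up_months,
#' vital_status, nodes_examined, nodes_positive, grade, radiation`), one row
#' per subject. `read_cohort_csv()` validates the header and the record
#' invariants and names the offending file and row on failure.
#'
#' @param cohort data.frame of patient records.
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  check_cohort(cohort)
  utils::write.csv(cohort[patient_record_fields()], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_domain("cohort file not found: %s", path)
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  if (!identical(header, patient_record_fields())) {
    stop_domain("%s: expected header '%s'", path,
                paste(patient_record_fields(), collapse = ","))
  }
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  tryCatch(check_cohort(cohort, where = path),
           error = function(e) stop(e))
  cohort
}

#' Read / write a cohort specification as a flat config file
#'
#' Serialises a [cohort_spec()] in Debian-control (DCF) form: one block of
#' cohort-level keys (seed, demographics, node-count distribution) followed
#' by one block per stratum.
#'
#' @param spec a `cohort_spec`.
#' @param path file path.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  dgm <- spec$demographics
  kv <- function(x) paste(sprintf("%s=%.10g", names(x), x), collapse = ",")
  head_block <- c(
    block = "cohort", seed = spec$seed,
    age_mean = dgm$age_mean, age_sd = dgm$age_sd,
    age_min = dgm$age_range[1], age_max = dgm$age_range[2],
    year_min = dgm$year_range[1], year_max = dgm$year_range[2],
    race_probs = kv(dgm$race_probs), grade_probs = kv(dgm$grade_probs),
    radiation_probs = kv(dgm$radiation_probs),
    ln_lambda = spec$ln_examined$lambda,
    ln_min = spec$ln_examined$min, ln_max = spec$ln_examined$max
  )
  blocks <- c(list(head_block), lapply(spec$strata, function(s) {
    c(block = "stratum", label = s$label,
      ln_lo = s$ln_range[1], ln_hi = s$ln_range[2], n = s$n,
      b1 = s$b1, b2 = s$b2, b3 = s$b3,
      censoring_rate = s$censoring_rate, horizon_months = s$horizon_months)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  for (b in blocks) {
    write.dcf(t(as.matrix(b)), con)
    cat("\n", file = con)
  }
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) stop_domain("spec file not found: %s", path)
  m <- read.dcf(path)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    r <- m[i, ]
    r[!is.na(r)]
  })
  types <- vapply(rows, function(r) r[["block"]], character(1))
  if (types[1] != "cohort" || !all(types[-1] == "stratum")) {
    stop_domain("%s: expected one cohort block followed by stratum blocks", path)
  }
  h <- rows[[1]]
  parse_kv <- function(s) {
    parts <- strsplit(strsplit(s, ",")[[1]], "=")
    stats::setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                    vapply(parts, `[`, character(1), 1))
  }
  num <- function(r, k) as.numeric(r[[k]])
  dgm <- cohort_demographics(
    age_mean = num(h, "age_mean"), age_sd = num(h, "age_sd"),
    age_range = c(num(h, "age_min"), num(h, "age_max")),
    race_probs = parse_kv(h[["race_probs"]]),
    year_range = c(num(h, "year_min"), num(h, "year_max")),
    grade_probs = parse_kv(h[["grade_probs"]]),
    radiation_probs = parse_kv(h[["radiation_probs"]])
  )
  strata <- lapply(rows[-1], function(r) {
    stratum_spec(r[["label"]], c(num(r, "ln_lo"), num(r, "ln_hi")),
                 num(r, "n"), num(r, "b1"), num(r, "b2"), num(r, "b3"),
                 censoring_rate = num(r, "censoring_rate"),
                 horizon_months = num(r, "horizon_months"))
  })
  cohort_spec(strata, demographics = dgm,
              ln_examined = ln_examined_poisson(num(h, "ln_lambda"),
                                                num(h, "ln_min"),
                                                num(h, "ln_max")),
              seed = num(h, "seed"))
}
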
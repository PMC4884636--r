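#' Fraction of positive lymph nodes (%LN+)
#'
#' Ratio of pathologically positive to examined lymph nodes per record.
#' Records with no nodes examined cannot be classified and yield `NA` (an
#' exclusion signal, not an error); a positive count exceeding the examined
#' count is a data-integrity error.
#'
#' @param cohort data.frame of patient records (or any data.frame with
#'   `nodes_positive` and `nodes_examined` columns).
#' @return Numeric vector of fractions in \[0, 1\], `NA` where
#'   `nodes_examined == 0`.
#' @export
percent_ln_positive <- function(cohort) {
  if (!all(c("nodes_positive", "nodes_examined") %in% names(cohort))) {
    stop_domain("percent_ln_positive: need nodes_positive and nodes_examined")
  }
  pos <- cohort$nodes_positive
  ex <- cohort$nodes_examined
  if (any(pos > ex)) {
    stop_domain("percent_ln_positive: nodes_positive > nodes_examined (row %d)",
                which(pos > ex)[1])
  }
  ifelse(ex >= 1, pos / ex, NA_real_)
}

#' Filter a cohort by node positivity and covariates
#'
#' Keeps records matching all supplied criteria. Filtering on a covariate
#' excludes records whose value for that covariate is `"unknown"` (unless
#' `"unknown"` is explicitly requested). The node-positivity requirement
#' keeps records with `nodes_positive >= 1`.
#'
#' @param cohort data.frame of patient records.
#' @param ln_positive logical; require at least one positive node.
#' @param race,grade,radiation optional character vectors of admissible
#'   values; `NULL` means no filtering on that field.
#' @return The matching sub-cohort (possibly empty, with a warning).
#' @export
filter_cohort <- function(cohort, ln_positive = FALSE, race = NULL,
                          grade = NULL, radiation = NULL) {
  check_cohort(cohort)
  keep <- rep(TRUE, nrow(cohort))
  if (isTRUE(ln_positive)) keep <- keep & cohort$nodes_positive >= 1
  if (!is.null(race)) keep <- keep & cohort$race %in% race
  if (!is.null(grade)) keep <- keep & cohort$grade %in% grade
  if (!is.null(radiation)) keep <- keep & cohort$radiation %in% radiation
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("filter_cohort: no records match the criteria")
  out
}

#' Relative-survival pipeline for one cohort
#'
#' Convenience wrapper chaining [ederer2_expected()], [km_estimate()],
#' [relative_survival()] and [fit_inverse_gompertz()] on one cohort.
#'
#' @param cohort data.frame of patient records.
#' @param table a [life_table()].
#' @param max_months monthly grid length; defaults to the maximum observed
#'   follow-up.
#' @param seed seed passed to the fit's global optimizer.
#' @param truncate_month optional fit truncation month.
#' @param bounds optional fit bounds (see [fit_inverse_gompertz()]).
#' @return List of class `rs_pipeline`: `observed`, `expected`, `relative`,
#'   `fit`, `n`.
#' @export
rs_pipeline <- function(cohort, table, max_months = NULL, seed = 1L,
                        truncate_month = NULL, bounds = NULL) {
  check_cohort(cohort)
  if (nrow(cohort) == 0L) stop_domain("rs_pipeline: cohort is empty")
  max_months <- as.integer(max_months %||% max(cohort$follow_up_months))
  expected <- ederer2_expected(cohort, table, max_months)
  observed <- km_estimate(cohort, max_months)
  relative <- relative_survival(observed, expected)
  fit <- fit_inverse_gompertz(relative, bounds = bounds, seed = seed,
                              truncate_month = truncate_month)
  structure(
    list(observed = observed, expected = expected, relative = relative,
         fit = fit, n = nrow(cohort)),
    class = "rs_pipeline"
  )
}

#' %LN+ cutoff scan
#'
#' For each cutoff `c`, restricts the LN+ cohort to subjects with
#' `%LN+ < c` (the largest admissible cutoff, 1, is closed so that its row
#' is the whole LN+ cohort), runs the full relative-survival pipeline on the
#' subset, and records the fitted parameters and inflection point. On
#' cohorts in which survival worsens with %LN+, the IP-versus-cutoff profile
#' decreases: the scan is the instrument used to choose stratification
#' boundaries.
#'
#' @param cohort data.frame of patient records; restricted internally to
#'   records with at least one node examined and at least one positive node.
#' @param table a [life_table()].
#' @param cutoffs non-decreasing fractions in (0, 1\].
#' @param seed fit seed (the same seed is used at every cutoff, so the
#'   largest-cutoff row equals the whole-cohort fit).
#' @param min_n minimum sub-cohort size; smaller subsets yield a row flagged
#'   `skipped` with no fit.
#' @param max_months,truncate_month passed to [rs_pipeline()].
#' @return data.frame of class `cutoff_scan`: `cutoff`, `n`, `skipped`,
#'   fit columns (`b1`, `b2`, `b3`, `sse`, `r_squared`, `ip_years`,
#'   `converged`). Full pipeline objects are attached as attribute
#'   `pipelines`.
#' @export
cutoff_scan <- function(cohort, table, cutoffs = seq(0.05, 1, by = 0.025),
                        seed = 1L, min_n = 50L, max_months = NULL,
                        truncate_month = NULL) {
  check_cohort(cohort)
  if (is.unsorted(cutoffs)) stop_domain("cutoffs must be non-decreasing")
  if (any(cutoffs <= 0 | cutoffs > 1)) stop_domain("cutoffs must lie in (0, 1]")
  base <- cohort[cohort$nodes_examined >= 1 & cohort$nodes_positive >= 1, ,
                 drop = FALSE]
  frac <- percent_ln_positive(base)
  rows <- vector("list", length(cutoffs))
  pipelines <- vector("list", length(cutoffs))
  for (i in seq_along(cutoffs)) {
    cc <- cutoffs[i]
    inc <- if (cc >= 1) frac <= 1 else frac < cc
    sub <- base[inc, , drop = FALSE]
    if (nrow(sub) < min_n) {
      rows[[i]] <- data.frame(cutoff = cc, n = nrow(sub), skipped = TRUE,
                              b1 = NA_real_, b2 = NA_real_, b3 = NA_real_,
                              sse = NA_real_, r_squared = NA_real_,
                              ip_years = NA_real_, converged = NA)
    } else {
      pip <- rs_pipeline(sub, table, max_months = max_months, seed = seed,
                         truncate_month = truncate_month)
      pipelines[[i]] <- pip
      f <- pip$fit
      rows[[i]] <- data.frame(cutoff = cc, n = nrow(sub), skipped = FALSE,
                              b1 = f$b1, b2 = f$b2, b3 = f$b3, sse = f$sse,
                              r_squared = f$r_squared, ip_years = f$ip_years,
                              converged = f$converged)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("cutoff_scan", "data.frame"), pipelines = pipelines)
}

interval_label <- function(lower, upper) {
  pct <- function(x) sprintf("%g", round(100 * x, 6))
  if (lower == 0) {
    sprintf("<%s%%", pct(upper))
  } else if (upper >= 1) {
    sprintf(">=%s%%", pct(lower))
  } else {
    sprintf("%s-%s%%", pct(lower), pct(upper))
  }
}

# Shared engine for interval- and count-based stratification: runs the
# pipeline per group and the pairwise tests between fitted groups.
stratify_engine <- function(base, assignment, definitions, table, seed,
                            test_months, max_months, truncate_month) {
  labels <- names(definitions)
  pipelines <- stats::setNames(vector("list", length(labels)), labels)
  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    sub <- base[assignment == lab, , drop = FALSE]
    row <- data.frame(label = lab, definition = definitions[[lab]],
                      n = nrow(sub), b1 = NA_real_, b2 = NA_real_,
                      b3 = NA_real_, sse = NA_real_, r_squared = NA_real_,
                      ip_years = NA_real_, converged = NA,
                      stringsAsFactors = FALSE)
    if (nrow(sub) >= 4L) {
      pip <- rs_pipeline(sub, table, max_months = max_months, seed = seed,
                         truncate_month = truncate_month)
      pipelines[[lab]] <- pip
      f <- pip$fit
      row[c("b1", "b2", "b3", "sse", "r_squared", "ip_years")] <-
        list(f$b1, f$b2, f$b3, f$sse, f$r_squared, f$ip_years)
      row$converged <- f$converged
    }
    rows[[i]] <- row
  }
  groups <- do.call(rbind, rows)
  rownames(groups) <- NULL

  fitted <- labels[!vapply(pipelines, is.null, logical(1))]
  z_rows <- list()
  lr_rows <- list()
  if (length(fitted) >= 2L) {
    pairs <- utils::combn(fitted, 2L, simplify = FALSE)
    for (pr in pairs) {
      ca <- pipelines[[pr[1]]]$relative
      cb <- pipelines[[pr[2]]]$relative
      for (m in test_months) {
        if (m %in% ca$month && m %in% cb$month) {
          zt <- rs_z_test(ca, cb, m)
          z_rows[[length(z_rows) + 1L]] <- data.frame(
            group_a = pr[1], group_b = pr[2], month = m,
            rs_a = unname(zt$estimate["rs_a"]),
            rs_b = unname(zt$estimate["rs_b"]),
            z = unname(zt$statistic), p = zt$p.value,
            stringsAsFactors = FALSE
          )
        }
      }
      lr <- logrank_test(base[assignment == pr[1], , drop = FALSE],
                         base[assignment == pr[2], , drop = FALSE])
      lr_rows[[length(lr_rows) + 1L]] <- data.frame(
        group_a = pr[1], group_b = pr[2],
        chisq = unname(lr$statistic), p = lr$p.value,
        stringsAsFactors = FALSE
      )
    }
  }
  z_tests <- if (length(z_rows)) do.call(rbind, z_rows) else
    data.frame(group_a = character(), group_b = character(),
               month = integer(), rs_a = numeric(), rs_b = numeric(),
               z = numeric(), p = numeric())
  logrank <- if (length(lr_rows)) do.call(rbind, lr_rows) else
    data.frame(group_a = character(), group_b = character(),
               chisq = numeric(), p = numeric())
  list(groups = groups, pipelines = pipelines, z_tests = z_tests,
       logrank = logrank)
}

#' Stratify a LN+ cohort by %LN+ intervals
#'
#' Partitions the LN+ cohort into half-open %LN+ intervals
#' `[0, boundaries[1]), [boundaries[1], boundaries[2]), ...` with the top
#' interval closed at 1 (a ratio exactly equal to the upper boundary, e.g.
#' 0.40, belongs to the top group). Each group is run through the full
#' relative-survival pipeline; groups are compared pairwise with Z-tests at
#' `test_months` and log-rank tests on observed survival.
#'
#' @param cohort data.frame of patient records; restricted internally to
#'   LN+ records with at least one node examined.
#' @param table a [life_table()].
#' @param boundaries sorted interior boundaries in (0, 1); the default
#'   `c(0.10, 0.40)` yields the groups `<10%`, `10-40%`, `>=40%`.
#' @param seed fit seed (shared across groups).
#' @param test_months months for the pairwise Z-tests (defaults to 5, 10
#'   and 15 years).
#' @param max_months,truncate_month passed to [rs_pipeline()].
#' @return An object of class `stratification_result`: `groups` (summary
#'   data.frame with n, fitted parameters and IP per group), `pipelines`
#'   (named list of [rs_pipeline()] results), `z_tests`, `logrank`, plus the
#'   stratification settings. Empty or too-small groups (fewer than 4
#'   records) are reported with `n` and no fit.
#' @export
stratify_groups <- function(cohort, table, boundaries = c(0.10, 0.40),
                            seed = 1L, test_months = c(60L, 120L, 180L),
                            max_months = NULL, truncate_month = NULL) {
  check_cohort(cohort)
  if (is.unsorted(boundaries, strictly = TRUE) ||
      any(boundaries <= 0 | boundaries >= 1)) {
    stop_domain("boundaries must be strictly increasing and inside (0, 1)")
  }
  base <- cohort[cohort$nodes_examined >= 1 & cohort$nodes_positive >= 1, ,
                 drop = FALSE]
  frac <- percent_ln_positive(base)
  cuts <- c(0, boundaries, 1)
  labels <- vapply(seq_len(length(cuts) - 1L),
                   function(i) interval_label(cuts[i], cuts[i + 1]),
                   character(1))
  assignment <- labels[findInterval(frac, boundaries) + 1L]
  definitions <- stats::setNames(as.list(vapply(
    seq_len(length(cuts) - 1L),
    function(i) sprintf("[%g, %g%s", cuts[i], cuts[i + 1],
                        if (cuts[i + 1] >= 1) "]" else ")"),
    character(1)
  )), labels)
  eng <- stratify_engine(base, assignment, definitions, table, seed,
                         test_months, max_months, truncate_month)
  structure(
    c(eng, list(mode = "ln_fraction", boundaries = boundaries,
                seed = as.integer(seed), n_total = nrow(base))),
    class = "stratification_result"
  )
}

#' Stratify a LN+ cohort by positive-node count
#'
#' As [stratify_groups()], but grouping on the number of positive nodes:
#' classes `1, 2, ..., max_class - 1` and `>= max_class` (default classes
#' 1, 2, 3, >=4).
#'
#' @inheritParams stratify_groups
#' @param max_class counts at or above this value are pooled into the top
#'   class.
#' @return An object of class `stratification_result` (see
#'   [stratify_groups()]).
#' @export
stratify_by_ln_count <- function(cohort, table, max_class = 4L, seed = 1L,
                                 test_months = c(60L, 120L, 180L),
                                 max_months = NULL, truncate_month = NULL) {
  check_cohort(cohort)
  stopifnot(max_class >= 2L)
  base <- cohort[cohort$nodes_examined >= 1 & cohort$nodes_positive >= 1, ,
                 drop = FALSE]
  pos <- base$nodes_positive
  assignment <- ifelse(pos >= max_class, sprintf(">=%d", max_class),
                       as.character(pos))
  labels <- c(as.character(seq_len(max_class - 1L)),
              sprintf(">=%d", max_class))
  definitions <- stats::setNames(as.list(c(
    sprintf("%d positive node(s)", seq_len(max_class - 1L)),
    sprintf("%d or more positive nodes", max_class)
  )), labels)
  eng <- stratify_engine(base, assignment, definitions, table, seed,
                         test_months, max_months, truncate_month)
  structure(
    c(eng, list(mode = "ln_count", max_class = as.integer(max_class),
                seed = as.integer(seed), n_total = nrow(base))),
    class = "stratification_result"
  )
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf("Stratification by %s (n = %d, seed = %d)\n",
              ifelse(x$mode == "ln_fraction", "%LN+ interval",
                     "positive-node count"),
              x$n_total, x$seed))
  print(x$groups, row.names = FALSE)
  if (nrow(x$z_tests)) {
    cat("\nPairwise Z-tests on relative survival:\n")
    print(x$z_tests, row.names = FALSE)
  }
  if (nrow(x$logrank)) {
    cat("\nPairwise log-rank tests on observed survival:\n")
    print(x$logrank, row.names = FALSE)
  }
  invisible(x)
}
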
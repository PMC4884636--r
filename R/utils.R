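# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Save the global RNG state and seed the generator; pair with pop_seed() in
# on.exit() so user-visible RNG state is untouched by seeded operations.
push_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  set.seed(as.integer(seed))
  invisible(old)
}

pop_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# sample() that never interprets a length-1 vector as 1:x
resample <- function(x, n, prob = NULL) {
  x[sample.int(length(x), n, replace = TRUE, prob = prob)]
}

stop_domain <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# Column names of a patient-level registry record, in canonical order.
patient_record_fields <- function() {
  c("patient_id", "age_at_dx", "sex", "race", "dx_year",
    "follow_up_months", "vital_status", "nodes_examined",
    "nodes_positive", "grade", "radiation")
}

check_cohort <- function(cohort, where = "cohort") {
  if (!is.data.frame(cohort)) {
    stop_domain("%s must be a data.frame of patient records", where)
  }
  missing <- setdiff(patient_record_fields(), names(cohort))
  if (length(missing)) {
    stop_domain("%s is missing patient-record column(s): %s",
                where, paste(missing, collapse = ", "))
  }
  if (any(cohort$follow_up_months < 0)) {
    stop_domain("%s: follow_up_months must be non-negative", where)
  }
  bad <- !cohort$vital_status %in% c("dead", "censored")
  if (any(bad)) {
    stop_domain("%s: vital_status must be 'dead' or 'censored' (row %d)",
                where, which(bad)[1])
  }
  bad <- cohort$nodes_positive > cohort$nodes_examined
  if (any(bad)) {
    stop_domain("%s: nodes_positive exceeds nodes_examined (row %d)",
                where, which(bad)[1])
  }
  invisible(cohort)
}
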
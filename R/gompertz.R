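#' Inverse Gompertzian relative-survival model
#'
#' Evaluates the inverse Gompertzian survival law
#' \deqn{RS(t) = 1 - b_1 \exp(-b_2 \exp(-b_3 t))}
#' a sigmoid describing population-level relative survival: a slow early
#' decline (treatment success) followed by an accelerating exponential loss
#' (treatment failure), levelling off at `1 - b1`. Time is in years.
#'
#' Evaluation is unconstrained: for `b1 > 1` the model drops below zero at
#' large `t`, which is admitted when fitting empirical curves even though it
#' is not a valid survival law (see [stratum_spec()], which restricts
#' simulation truth to `b1 <= 1`).
#'
#' @param t time since surgery, in years (vectorised, `t >= 0`).
#' @param b1 depth parameter, `>= 0` (dimensionless).
#' @param b2 shape parameter, `> 0` (dimensionless).
#' @param b3 rate parameter, `> 0` (per year).
#' @return Relative survival value(s).
#' @seealso [rs_derivative()], [inflection_point()], [fit_inverse_gompertz()]
#' @export
inverse_gompertz_rs <- function(t, b1, b2, b3) {
  check_gompertz_pars(b1, b2, b3)
  if (any(t < 0)) stop_domain("t must be non-negative")
  1 - b1 * exp(-b2 * exp(-b3 * t))
}

#' Derivative of the inverse Gompertzian relative-survival curve
#'
#' Closed form of dRS/dt for the model in [inverse_gompertz_rs()]:
#' \deqn{dRS/dt = -b_1 b_2 b_3 \exp(-b_2 \exp(-b_3 t)) \exp(-b_3 t)}
#' Always non-positive; its minimum (steepest decline) defines the
#' inflection point.
#'
#' @inheritParams inverse_gompertz_rs
#' @return Derivative value(s), per year.
#' @export
rs_derivative <- function(t, b1, b2, b3) {
  check_gompertz_pars(b1, b2, b3)
  if (any(t < 0)) stop_domain("t must be non-negative")
  -b1 * b2 * b3 * exp(-b2 * exp(-b3 * t) - b3 * t)
}

check_gompertz_pars <- function(b1, b2, b3) {
  if (!is.finite(b1) || b1 < 0) stop_domain("b1 must be a non-negative number")
  if (!is.finite(b2) || b2 <= 0) stop_domain("b2 must be positive")
  if (!is.finite(b3) || b3 <= 0) stop_domain("b3 must be positive")
  invisible(NULL)
}

#' Inflection point of the inverse Gompertzian curve
#'
#' The inflection point (IP) is the time at which the relative-survival
#' decline is steepest, i.e. where [rs_derivative()] attains its minimum over
#' `t >= 0`. It depends only on `b2` and `b3` (the closed form is
#' `ln(b2)/b3` whenever `b2 > 1`), but is located here numerically: a
#' bounded minimisation of the derivative in the scaled time `tau = b3*t`,
#' polished by a root search on the central-difference slope. For `b2 <= 1`
#' the derivative is steepest at diagnosis and 0 is returned with attribute
#' `boundary = TRUE`.
#'
#' @param b2,b3 model parameters, both `> 0`.
#' @param search_init optional initial guess in years (default `ln(b2)/b3`).
#' @return IP in years, with logical attribute `boundary`.
#' @export
inflection_point <- function(b2, b3, search_init = NULL) {
  check_gompertz_pars(1, b2, b3)
  # negated magnitude of dRS/dt in scaled time tau = b3*t (b1, b3 factors
  # do not move the argmin)
  g <- function(tau) -exp(-b2 * exp(-tau) - tau)
  if (b2 <= 1) {
    # derivative magnitude decreasing on t >= 0: minimum at the boundary
    return(structure(0, boundary = TRUE))
  }
  tau0 <- if (is.null(search_init)) log(b2) else max(b3 * search_init, 1e-8)
  upper <- max(tau0, log(b2)) + 6
  opt <- stats::optimize(g, c(0, upper), tol = 1e-9)
  tau <- opt$minimum
  # polish: root of the finite-difference slope around the located minimum
  h <- 1e-4
  slope <- function(x) (g(x + h) - g(x - h)) / (2 * h)
  lo <- max(tau - 0.5, h)
  hi <- tau + 0.5
  if (slope(lo) < 0 && slope(hi) > 0) {
    tau <- stats::uniroot(slope, c(lo, hi), tol = 1e-13)$root
  }
  structure(tau / b3, boundary = FALSE)
}

# Seeded differential evolution (rand/1/bin) under box constraints; the
# global stage of the curve fit. Deliberately compact: the objective is a
# 3-parameter sum of squares, cheap to evaluate.
de_minimize <- function(fn, lower, upper, np = 40L, maxiter = 120L,
                        f = 0.8, cr = 0.9) {
  d <- length(lower)
  pop <- matrix(stats::runif(np * d), np, d)
  pop <- sweep(sweep(pop, 2, upper - lower, `*`), 2, lower, `+`)
  cost <- apply(pop, 1, fn)
  for (iter in seq_len(maxiter)) {
    for (i in seq_len(np)) {
      idx <- sample(seq_len(np)[-i], 3L)
      v <- pop[idx[1L], ] + f * (pop[idx[2L], ] - pop[idx[3L], ])
      j_forced <- sample.int(d, 1L)
      keep <- stats::runif(d) >= cr & seq_len(d) != j_forced
      v[keep] <- pop[i, keep]
      v <- pmin(pmax(v, lower), upper)
      cv <- fn(v)
      if (cv <= cost[i]) {
        pop[i, ] <- v
        cost[i] <- cv
      }
    }
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best])
}

#' Fit the inverse Gompertzian model to a relative-survival curve
#'
#' Least-squares fit of [inverse_gompertz_rs()] to a monthly
#' relative-survival curve: the objective is the sum of squared differences
#' between model and curve at every month of the grid (equal weights), with
#' the monthly grid converted to years as `t = month/12`. Optimisation is
#' two-stage, mirroring common practice for this family: a seeded global
#' evolutionary search (differential evolution) over box bounds, followed by
#' deterministic local refinement with the Levenberg-Marquardt least-squares
#' algorithm ([minpack.lm::nls.lm()]). The global-stage objective value never
#' increases through refinement (the better of the two solutions is kept).
#'
#' The default `b1` upper bound is 5, deliberately admitting `b1 > 1`:
#' empirical registry curves are often best fit with `b1 > 1` even though
#' the implied asymptote `1 - b1` is negative. A message is emitted when
#' that happens.
#'
#' @param curve a `relative_survival_curve` (from [relative_survival()]), or
#'   any data.frame with columns `month` and `rs`.
#' @param bounds named list of `c(lower, upper)` box bounds for `b1`, `b2`,
#'   `b3`; default `list(b1 = c(1e-8, 5), b2 = c(1e-8, 50), b3 = c(1e-8, 2))`.
#' @param seed integer seed for the global search (recorded in the result;
#'   identical seeds give identical fits).
#' @param truncate_month optional; drop curve points beyond this month before
#'   fitting.
#' @return An object of class `gompertz_fit`: list with `b1`, `b2`, `b3`,
#'   `sse`, `sse_global` (objective after the global stage alone; `sse` never
#'   exceeds it), `r_squared` (coefficient of determination against the curve
#'   mean; `NA` for a constant curve), `ip_years`, `ip_at_boundary`,
#'   `converged`, `at_bound` (any parameter within tolerance of a box
#'   bound), `optimizer_seed`, `n_points`.
#' @export
fit_inverse_gompertz <- function(curve, bounds = NULL, seed = 1L,
                                 truncate_month = NULL) {
  if (!is.data.frame(curve) || !all(c("month", "rs") %in% names(curve))) {
    stop_domain("curve must be a data.frame with columns 'month' and 'rs'")
  }
  dat <- curve[, c("month", "rs")]
  if (!is.null(truncate_month)) dat <- dat[dat$month <= truncate_month, ]
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) < 4L) {
    stop_domain("fit_inverse_gompertz: need at least 4 curve points, got %d",
                nrow(dat))
  }
  t_years <- dat$month / 12
  y <- dat$rs

  default_bounds <- list(b1 = c(1e-8, 5), b2 = c(1e-8, 50), b3 = c(1e-8, 2))
  bounds <- utils::modifyList(default_bounds, bounds %||% list())
  lower <- vapply(bounds[c("b1", "b2", "b3")], `[`, numeric(1), 1L)
  upper <- vapply(bounds[c("b1", "b2", "b3")], `[`, numeric(1), 2L)
  if (any(lower <= 0) || any(upper <= lower)) {
    stop_domain("bounds must satisfy 0 < lower < upper for each parameter")
  }

  sse_fn <- function(p) {
    sum((1 - p[1] * exp(-p[2] * exp(-p[3] * t_years)) - y)^2)
  }
  resid_fn <- function(p) {
    1 - p[1] * exp(-p[2] * exp(-p[3] * t_years)) - y
  }

  old <- push_seed(seed)
  on.exit(pop_seed(old), add = TRUE)

  global <- de_minimize(sse_fn, lower, upper)
  local <- minpack.lm::nls.lm(
    par = global$par, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 500)
  )
  local_sse <- sse_fn(local$par)
  if (local_sse <= global$value) {
    par <- local$par
    sse <- local_sse
    converged <- local$info %in% 1:3
  } else {
    par <- global$par
    sse <- global$value
    converged <- FALSE
  }
  names(par) <- c("b1", "b2", "b3")

  tss <- sum((y - mean(y))^2)
  r_squared <- if (tss > 0) 1 - sse / tss else NA_real_
  tol <- 1e-6 * (upper - lower)
  at_bound <- any(par - lower < tol | upper - par < tol)
  ip <- inflection_point(par[["b2"]], par[["b3"]])
  if (par[["b1"]] > 1) {
    message(sprintf(
      "fit_inverse_gompertz: fitted b1 = %.3f exceeds 1 (implied asymptote below zero)",
      par[["b1"]]
    ))
  }

  structure(
    list(
      b1 = par[["b1"]], b2 = par[["b2"]], b3 = par[["b3"]],
      sse = sse, sse_global = global$value, r_squared = r_squared,
      ip_years = as.numeric(ip), ip_at_boundary = isTRUE(attr(ip, "boundary")),
      converged = converged, at_bound = at_bound,
      optimizer_seed = as.integer(seed), n_points = nrow(dat)
    ),
    class = "gompertz_fit"
  )
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("Inverse Gompertzian fit\n")
  cat(sprintf("  b1 = %.4f, b2 = %.4f, b3 = %.4f /yr\n", x$b1, x$b2, x$b3))
  cat(sprintf("  SSE = %.4g over %d points, R^2 = %s\n", x$sse, x$n_points,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  cat(sprintf("  inflection point = %.2f years%s\n", x$ip_years,
              if (x$ip_at_boundary) " (at boundary t = 0)" else ""))
  if (x$at_bound) cat("  note: optimizer at a box bound\n")
  if (!x$converged) cat("  note: local refinement did not report convergence\n")
  invisible(x)
}

#' @export
as.data.frame.gompertz_fit <- function(x, ...) {
  data.frame(
    b1 = x$b1, b2 = x$b2, b3 = x$b3, sse = x$sse, r_squared = x$r_squared,
    ip_years = x$ip_years, converged = x$converged, at_bound = x$at_bound,
    optimizer_seed = x$optimizer_seed, n_points = x$n_points
  )
}
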
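#' Inflate a candidate value into a verification interval
#'
#' Turns a floating-point candidate `v > 0` (e.g. a quantile or a
#' noncentrality parameter produced by the software under test) into the
#' initial interval \eqn{[(1-\epsilon)v, (1+\epsilon)v]} for the interval
#' Newton method, with outward rounding so that `v` lies strictly in the
#' interior.  If verification succeeds on this interval, the candidate is
#' accurate to at least the relative radius `eps`; if the interval is proved
#' to contain no solution, it is not.
#'
#' @param v positive finite numeric scalar.
#' @param eps relative inflation, `0 < eps < 1`; values at or above 1e-4 are
#'   outside the sane range and trigger a warning (results stay rigorous,
#'   verification may degrade).
#' @return An `"interval"` containing `v` in its interior.
#' @examples
#' inflate_candidate(0.95, 1e-6)
#' @export
inflate_candidate <- function(v, eps = 1e-6) {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
    stop("candidate value must be a positive finite scalar ",
         "(multiplicative inflation is meaningless at zero)")
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps >= 1)
    stop("eps must lie in (0, 1)")
  if (eps >= 1e-4)
    warning("inflation parameter eps >= 1e-4 is outside the sane range; ",
            "expect performance degradation, never incorrect enclosures")
  lo_f <- .Call(C_iv_sub, c(1, 1), c(eps, eps))
  hi_f <- .Call(C_iv_add, c(1, 1), c(eps, eps))
  new_interval(.Call(C_iv_mul, c(lo_f[1L], hi_f[2L]), c(v, v)))
}

#' Verified enclosure of the central beta upper quantile
#'
#' Encloses the solution \eqn{x_{1-\alpha}} of \eqn{I_x(a,b) = 1-\alpha}
#' with the interval Newton method.  With an initial interval `x0` (normally
#' an inflated candidate, see [inflate_candidate()]) the three verified
#' outcomes of [newton_iterate()] apply: `"UNIQUE"` encloses the true
#' quantile, `"EMPTY"` proves `x0` contains no solution, `"FAILED"` means
#' verification did not succeed.
#'
#' With `x0 = NULL` (wide mode) the solver starts from essentially all of
#' \eqn{(0,1)}: since the cdf is strictly increasing, it first shrinks a
#' bracket via sign-certified point evaluations until the derivative
#' enclosure has one sign, then switches to the interval Newton iteration.
#'
#' @param a positive real shape (`nu1/2`).
#' @param b positive integer shape (`nu2/2`).
#' @param alpha type I error probability in (0,1).
#' @param x0 initial `"interval"` within \eqn{[0,1]}, or `NULL` for wide
#'   mode.
#' @param rel_tol,max_iter Newton controls, see [newton_iterate()].
#' @return A [newton_result].
#' @examples
#' quantile_enclosure(1, 2, 0.05)   # encloses 0.776393...
#' @export
quantile_enclosure <- function(a, b, alpha, x0 = NULL, rel_tol = 1e-13,
                               max_iter = 100L) {
  .check_a(a); b <- .check_b(b)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0,1)")
  target <- new_interval(.Call(C_iv_sub, c(1, 1), c(alpha, alpha)))
  f <- function(u) central_beta_cdf(u, a, b) - dint_constant(target)
  if (is.null(x0))
    return(.bracketed_monotone_newton(f, 1e-10, 1 - 1e-10, increasing = TRUE,
                                      rel_tol = rel_tol, max_iter = max_iter))
  x0 <- as_interval(x0)
  .check_unit_interval(.iv(x0), "x0")
  newton_iterate(f, x0, rel_tol = rel_tol, max_iter = max_iter)
}

#' Verified enclosure of the noncentrality parameter
#'
#' Encloses the noncentrality \eqn{\lambda} solving
#' \eqn{I_{x_{1-\alpha}}(a, b; \lambda) = \beta}, where the verified quantile
#' enclosure `x_enc` enters as a *thick* constant interval: the resulting
#' \eqn{\lambda} enclosure is then valid for every \eqn{x} in `x_enc`, which
#' preserves the guarantee of the two-step algorithm.
#'
#' With `lam0 = NULL` (wide mode) an upper bracket is found by doubling
#' \eqn{\Lambda} from 1 until the cdf enclosure at \eqn{\Lambda} lies
#' strictly below `beta_err` (capped at \eqn{2^{60}}), after which the same
#' bracketed monotone scheme as in [quantile_enclosure()] applies (the cdf is
#' strictly decreasing in \eqn{\lambda}).
#'
#' @inheritParams quantile_enclosure
#' @param beta_err prescribed type II error probability in (0,1).
#' @param x_enc verified enclosure of the upper-`alpha` quantile (an
#'   `"interval"`), typically the `"UNIQUE"` enclosure from
#'   [quantile_enclosure()].
#' @param lam0 initial `"interval"` within \eqn{[0,\infty)}, or `NULL` for
#'   wide mode.
#' @return A [newton_result].
#' @export
lambda_enclosure <- function(a, b, beta_err, x_enc, lam0 = NULL,
                             rel_tol = 1e-13, max_iter = 100L) {
  .check_a(a); b <- .check_b(b)
  if (!is.numeric(beta_err) || length(beta_err) != 1L ||
      beta_err <= 0 || beta_err >= 1)
    stop("beta_err must lie strictly in (0,1)")
  x_enc <- as_interval(x_enc)
  .check_unit_interval(.iv(x_enc), "x_enc")
  tgt <- dint_constant(interval(beta_err))
  g <- function(l) noncentral_beta_cdf(x_enc, a, b, l) - tgt
  if (!is.null(lam0)) {
    lam0 <- as_interval(lam0)
    if (lower(lam0) < 0) stop("lam0 must lie within [0, Inf)")
    return(newton_iterate(g, lam0, rel_tol = rel_tol, max_iter = max_iter))
  }
  # wide mode: verified doubling bracket, then monotone decreasing solve
  g_at <- function(l) dint_val(g(dint_variable(interval(l))))
  if (!(lower(g_at(0)) > 0))
    return(new_newton_result("FAILED", interval(0, Inf), 0L, NULL,
                             "cdf at lambda = 0 not verifiably above beta"))
  lo <- 0; hi <- 1
  repeat {
    if (upper(g_at(hi)) < 0) break
    lo <- hi; hi <- 2 * hi
    if (hi > 2^60)
      stop("no sign change found for lambda up to 2^60")
  }
  .bracketed_monotone_newton(g, lo, hi, increasing = FALSE,
                             rel_tol = rel_tol, max_iter = max_iter)
}

# Wide-initial-interval solver for strictly monotone target functions.
# Point evaluations of f are tight, so a sign-certified bisection shrinks the
# bracket cheaply until the derivative enclosure over it has a verified sign;
# the interval Newton iteration (with its interior-containment uniqueness
# test) finishes the job.  Falls back to the generic newton_iterate() if a
# sign certificate cannot be obtained.
.bracketed_monotone_newton <- function(f, lo, hi, increasing, rel_tol,
                                       max_iter, max_bisect = 200L) {
  sgn <- if (increasing) 1 else -1
  val_at <- function(u) dint_val(f(dint_variable(interval(u))))
  ok_lo <- upper(val_at(lo)) * sgn < 0
  ok_hi <- lower(val_at(hi)) * sgn > 0
  if (!ok_lo || !ok_hi) {
    # no sign certificate at the endpoints: hand over to the generic
    # iteration, which remains rigorous about all three outcomes
    return(newton_iterate(f, interval(lo, hi), rel_tol = rel_tol,
                          max_iter = max_iter))
  }
  bis <- 0L
  repeat {
    x <- interval(lo, hi)
    dfx <- f(dint_variable(x))
    fd <- dint_der(dfx)
    if (!in_interval(0, fd)) {
      r <- newton_iterate(f, x, rel_tol = rel_tol, max_iter = max_iter)
      r$iterations <- r$iterations + bis
      return(r)
    }
    if (bis >= max_bisect)
      return(new_newton_result("FAILED", x, bis, NULL,
                               "bracket could not certify a derivative sign"))
    m0 <- mid(x)
    moved <- FALSE
    for (m in c(m0, m0 + 0.25 * wid(x), m0 - 0.25 * wid(x))) {
      if (m <= lo || m >= hi) next
      fm <- val_at(m)
      if (upper(fm) * sgn < 0) { lo <- m; moved <- TRUE; break }
      if (lower(fm) * sgn > 0) { hi <- m; moved <- TRUE; break }
    }
    bis <- bis + 1L
    if (!moved) {
      r <- newton_iterate(f, x, rel_tol = rel_tol, max_iter = max_iter)
      r$iterations <- r$iterations + bis
      return(r)
    }
  }
}

#' Verified cross-check of a power-analysis computation
#'
#' Runs the three-step self-validating algorithm for one problem instance:
#'
#' 1. The candidate values `x_cand` (upper-`alpha` central beta quantile) and
#'    `lam_cand` (noncentrality attaining type II error `beta_err`) are
#'    inflated into initial intervals of relative radius `eps_x`,
#'    `eps_lambda` (see [inflate_candidate()]).
#' 2. The quantile equation \eqn{I_x(a,b) = 1-\alpha} is solved by the
#'    interval Newton method on the inflated interval.
#' 3. If step 2 verified a unique solution, the power equation
#'    \eqn{I_{x}(a,b;\lambda) = \beta} is solved on the inflated
#'    \eqn{\lambda} interval, with the step-2 enclosure entering as a thick
#'    constant.
#'
#' A `"UNIQUE"` status means the candidate is at least as accurate as the
#' inflation radius; `"EMPTY"` proves it is not; `"FAILED"` draws no
#' conclusion (usually remedied by a larger radius).  Omitting a candidate
#' (`NULL`) switches that step to wide mode, computing the value from scratch
#' (see [quantile_enclosure()] / [lambda_enclosure()]).
#'
#' @param problem a [beta_problem()].
#' @param x_cand positive candidate for \eqn{x_{1-\alpha}}, or `NULL` for
#'   wide mode.
#' @param lam_cand positive candidate for \eqn{\lambda}, or `NULL` for wide
#'   mode.
#' @param eps_x,eps_lambda relative inflation radii (default 1e-6).
#' @param rel_tol,max_iter Newton controls, see [newton_iterate()].
#' @return An object of class `"power_solution"` with components
#'   `x_result` and `lambda_result` ([newton_result]s), the `problem`, and
#'   the inflation parameters.
#' @examples
#' pr <- beta_problem(0.5, 1, alpha = 0.05, beta_err = 0.10)
#' solve_power(pr, x_cand = 0.9025, lam_cand = 46.1803)
#' @export
solve_power <- function(problem, x_cand = NULL, lam_cand = NULL,
                        eps_x = 1e-6, eps_lambda = 1e-6,
                        rel_tol = 1e-13, max_iter = 100L) {
  stopifnot(inherits(problem, "beta_problem"))
  x0 <- if (!is.null(x_cand)) inflate_candidate(x_cand, eps_x)
  if (!is.null(x0) && (lower(x0) < 0 || upper(x0) > 1))
    x0 <- interval_intersect(x0, interval(0, 1))
  xr <- quantile_enclosure(problem$a, problem$b, problem$alpha, x0 = x0,
                           rel_tol = rel_tol, max_iter = max_iter)
  if (xr$status == "UNIQUE") {
    lam0 <- if (!is.null(lam_cand)) inflate_candidate(lam_cand, eps_lambda)
    lr <- lambda_enclosure(problem$a, problem$b, problem$beta_err,
                           x_enc = xr$enclosure, lam0 = lam0,
                           rel_tol = rel_tol, max_iter = max_iter)
  } else {
    lr <- new_newton_result("FAILED", empty_interval(), 0L, NULL,
                            "skipped: quantile step did not verify")
  }
  structure(list(problem = problem, x_result = xr, lambda_result = lr,
                 x_cand = x_cand, lam_cand = lam_cand,
                 eps_x = eps_x, eps_lambda = eps_lambda),
            class = "power_solution")
}

#' @export
print.power_solution <- function(x, digits = 13L, ...) {
  p <- x$problem
  cat(sprintf("Verified power analysis: a = %g, b = %d, alpha = %g, beta = %g\n",
              p$a, p$b, p$alpha, p$beta_err))
  .show_step <- function(label, r, cand, eps) {
    cat(sprintf("  %-10s %s", label, r$status))
    if (!is.null(cand)) cat(sprintf("  (candidate %g, eps %g)", cand, eps))
    cat("\n")
    if (!is_empty_interval(r$enclosure))
      cat("    enclosure ", format(r$enclosure, digits = digits), "\n",
          sep = "")
    if (nzchar(r$message)) cat("    ", r$message, "\n", sep = "")
  }
  .show_step("quantile", x$x_result, x$x_cand, x$eps_x)
  .show_step("lambda", x$lambda_result, x$lam_cand, x$eps_lambda)
  invisible(x)
}

#' @export
summary.power_solution <- function(object, ...) {
  map <- c(UNIQUE = "VERIFIED", EMPTY = "REJECTED", FAILED = "FAILED")
  xs <- map[[object$x_result$status]]
  ls <- if (object$x_result$status != "UNIQUE") "SKIPPED"
        else map[[object$lambda_result$status]]
  structure(list(solution = object, x_status = xs, lambda_status = ls),
            class = "summary.power_solution")
}

#' @export
print.summary.power_solution <- function(x, ...) {
  cat(sprintf("quantile: %s, lambda: %s\n", x$x_status, x$lambda_status))
  print(x$solution)
  invisible(x)
}

#' @export
coef.power_solution <- function(object, ...) {
  g <- function(r) if (r$status == "UNIQUE") mid(r$enclosure) else NA_real_
  c(x = g(object$x_result), lambda = g(object$lambda_result))
}
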
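#' One verified power-analysis problem instance
#'
#' Bundles the shape parameters of the beta form of the noncentral-F power
#' problem: `a = nu1/2`, `b = nu2/2` (so `b` must be a positive integer,
#' i.e. the denominator degrees of freedom must be even), the allowed type I
#' error `alpha` and the prescribed type II error `beta_err`.  A positive
#' noncentrality solving the power equation exists only when
#' `beta_err < 1 - alpha`.
#'
#' The closed-form cdf evaluation is exact for any `a > 0` but the parameters
#' of practical interest are roughly `a <= 25`, `b <= 500`,
#' `0.01 <= alpha, beta_err <= 0.99`; outside that range a warning is issued
#' (performance and verification may degrade, enclosures remain valid).
#'
#' @param a positive real, numerator shape (`nu1/2`).
#' @param b positive integer, denominator shape (`nu2/2`).
#' @param alpha type I error probability in (0,1).
#' @param beta_err type II error probability in (0,1), `< 1 - alpha`.
#' @return An object of class `"beta_problem"`.
#' @export
beta_problem <- function(a, b, alpha, beta_err) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("a must be a positive real")
  .check_b(b)
  for (p in list(alpha = alpha, beta_err = beta_err))
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
      stop("alpha and beta_err must lie strictly in (0,1)")
  if (beta_err >= 1 - alpha)
    stop("no positive noncentrality exists when beta_err >= 1 - alpha ",
         "(the cdf at lambda = 0 already equals 1 - alpha)")
  if (a > 25 || b > 500 || alpha < 0.01 || alpha > 0.99 ||
      beta_err < 0.01 || beta_err > 0.99)
    warning("parameters outside the range of practical interest ",
            "(a <= 25, b <= 500, 0.01 <= alpha, beta_err <= 0.99); ",
            "results remain rigorous but verification may fail")
  structure(list(a = as.double(a), b = as.integer(b),
                 alpha = as.double(alpha), beta_err = as.double(beta_err)),
            class = "beta_problem")
}

#' @export
print.beta_problem <- function(x, ...) {
  cat(sprintf("<beta_problem> a = %g, b = %d, alpha = %g, beta = %g\n",
              x$a, x$b, x$alpha, x$beta_err))
  invisible(x)
}

.check_b <- function(b) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) ||
      b < 1 || b != floor(b))
    stop("b must be a positive integer (even denominator degrees of freedom)")
  invisible(as.integer(b))
}

.check_a <- function(a) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("a must be a positive real")
  invisible(as.double(a))
}

.check_unit_interval <- function(v, what) {
  if (anyNA(v)) stop(what, " must be a non-empty interval")
  if (v[1L] < 0 || v[2L] > 1)
    stop(what, " must lie within [0, 1]")
  invisible(v)
}

#' Central beta cdf with guaranteed enclosure
#'
#' Evaluates the incomplete beta function ratio \eqn{I_x(a,b)} for integer
#' `b` through its closed form
#' \deqn{I_x(a,b) = x^a \Big(1 + \sum_{n=1}^{b-1} \prod_{m=1}^{n}
#'       \frac{a+m-1}{m} (1-x)^n\Big),}
#' carried out entirely in outwardly rounded interval arithmetic.  The inner
#' products are updated incrementally (never via explicit factorials), which
#' keeps the evaluation overflow-safe up to large `b`.  The result is
#' intersected with \eqn{[0,1]}, which can only sharpen a valid enclosure.
#'
#' @param x evaluation point: numeric scalar in \eqn{[0,1]}, an
#'   `"interval"` within \eqn{[0,1]}, or a `"dint"` to additionally obtain
#'   the derivative enclosure with respect to `x`.
#' @param a positive real shape.
#' @param b positive integer shape.
#' @return An `"interval"` enclosing \eqn{I_x(a,b)} (a `"dint"` if `x` was
#'   one).
#' @examples
#' central_beta_cdf(0.776393, 1, 2)   # encloses 0.95
#' central_beta_cdf(interval(0.9025), 0.5, 1)
#' @export
central_beta_cdf <- function(x, a, b) {
  .check_a(a); b <- .check_b(b)
  av <- c(a, a)
  if (inherits(x, "dint")) {
    v <- unclass(x)
    .check_unit_interval(v[1:2], "x")
    return(new_dint(.Call(C_central_beta_dx, v, av, b)))
  }
  v <- .iv(if (is_interval(x)) x else as_interval(x))
  .check_unit_interval(v, "x")
  new_interval(.Call(C_central_beta, v, av, b))
}

#' Noncentral beta cdf with guaranteed enclosure
#'
#' Evaluates the cdf of the noncentral beta distribution with integer second
#' shape parameter through the finite closed form
#' \deqn{I_x(a,b;\lambda) = e^{-(\lambda/2)(1-x)} \sum_{i=0}^{b-1}
#'       \frac{((\lambda/2)(1-x))^i}{i!}\, I_{x}(a+i,\, b-i),}
#' in outwardly rounded interval arithmetic.  Terms are generated by the
#' recurrence \eqn{t_i = t_{i-1} z / i} with \eqn{z = (\lambda/2)(1-x)}
#' (factorials and powers are never formed explicitly, so the evaluation
#' cannot overflow at large `b` or `lambda`), and the `i = 0` term is the
#' central cdf itself, avoiding `0^0` at `x = 1` or `lambda = 0`.
#' At `lambda = 0` the result reduces to [central_beta_cdf()] up to rounding.
#'
#' Exactly one of `x` and `lambda` may be a `"dint"` (the differentiation
#' variable); the other enters as a plain (possibly thick) interval.
#'
#' @inheritParams central_beta_cdf
#' @param lambda noncentrality parameter, `>= 0`: numeric scalar,
#'   `"interval"`, or `"dint"`.
#' @return An `"interval"` enclosing \eqn{I_x(a,b;\lambda)} (a `"dint"` if
#'   `x` or `lambda` was one).
#' @examples
#' noncentral_beta_cdf(0.8640, 5, 5, 54)   # encloses 0.4563026
#' noncentral_beta_cdf(0.5, 2, 3, 0)       # equals the central cdf
#' @export
noncentral_beta_cdf <- function(x, a, b, lambda) {
  .check_a(a); b <- .check_b(b)
  av <- c(a, a)
  x_d <- inherits(x, "dint"); l_d <- inherits(lambda, "dint")
  if (x_d && l_d)
    stop("only one of x and lambda may be the differentiation variable")

  if (l_d) {
    lv <- unclass(lambda)
    if (lv[1L] < 0) stop("lambda must be non-negative")
    xv <- .iv(if (is_interval(x)) x else as_interval(x))
    .check_unit_interval(xv, "x")
    return(new_dint(.Call(C_noncentral_beta_dlam, lv, xv, av, b)))
  }

  if (x_d) {
    xv <- unclass(x)
    .check_unit_interval(xv[1:2], "x")
    lam <- as_interval(lambda)
    if (lower(lam) < 0) stop("lambda must be non-negative")
    # differentiate with respect to x by composing differential-interval
    # operations; the Poisson-type weights depend on x through z
    z <- dint_constant(lam / 2) * (dint_constant(interval(1)) - x)
    t_i <- dint_constant(interval(1))
    s <- new_dint(.Call(C_central_beta_dx, xv, av, b))
    if (b >= 2L) {
      for (i in seq_len(b - 1L)) {
        t_i <- t_i * z / dint_constant(interval(i))
        # shift the shape in interval arithmetic so a + i stays an enclosure
        ai <- .Call(C_iv_add, av, as.double(c(i, i)))
        s <- s + t_i * new_dint(.Call(C_central_beta_dx, xv, ai, b - i))
      }
    }
    r <- exp(-z) * s
    rv <- unclass(r)
    clamped <- interval_intersect(new_interval(rv[1:2]), interval(0, 1))
    return(dint(clamped, new_interval(rv[3:4])))
  }

  xv <- .iv(if (is_interval(x)) x else as_interval(x))
  .check_unit_interval(xv, "x")
  lv <- .iv(if (is_interval(lambda)) lambda else as_interval(lambda))
  if (anyNA(lv) || lv[1L] < 0) stop("lambda must be non-negative")
  new_interval(.Call(C_noncentral_beta, xv, av, b, lv))
}

#' Map noncentral-F arguments to the beta scale
#'
#' The noncentral-F cdf with `nu1`, `nu2` degrees of freedom equals the
#' noncentral beta cdf with shapes `a = nu1/2`, `b = nu2/2` at
#' `x = nu1 w / (nu1 w + nu2)`.  The method requires `b` integral, i.e.
#' even `nu2`; an odd `nu2` raises an error of class
#' `"ncfcheck_odd_nu2"`.
#'
#' @param nu1 positive numerator degrees of freedom.
#' @param nu2 positive *even* integer denominator degrees of freedom.
#' @param w evaluation point on the F scale, `>= 0`: numeric scalar or
#'   `"interval"`.
#' @return A list with components `a`, `b` (numerics) and `x` (an
#'   `"interval"` computed with outward rounding, within \eqn{[0,1)}).
#' @examples
#' f_to_beta(10, 10, 1)   # a = 5, b = 5, x = [0.5, 0.5]
#' @export
f_to_beta <- function(nu1, nu2, w) {
  if (!is.numeric(nu1) || length(nu1) != 1L || !is.finite(nu1) || nu1 <= 0)
    stop("nu1 must be a positive real")
  if (!is.numeric(nu2) || length(nu2) != 1L || !is.finite(nu2) ||
      nu2 <= 0 || nu2 != floor(nu2) || (nu2 %% 2) != 0)
    stop(errorCondition(
      paste0("nu2 = ", format(nu2), " is not a positive even integer; ",
             "the closed-form method needs b = nu2/2 integral"),
      class = "ncfcheck_odd_nu2"))
  wv <- as_interval(w)
  if (lower(wv) < 0) stop("w must be non-negative")
  n1 <- interval(nu1)
  num <- n1 * wv
  x <- num / (num + interval(nu2))
  list(a = nu1 / 2, b = nu2 / 2, x = x)
}

#' Noncentral F cdf with guaranteed enclosure
#'
#' @inheritParams f_to_beta
#' @param lambda noncentrality parameter, `>= 0` (numeric, `"interval"`, or
#'   `"dint"`).
#' @return An `"interval"` (or `"dint"`) enclosing
#'   \eqn{F(w; \nu_1, \nu_2, \lambda)}.
#' @examples
#' noncentral_f_cdf(1, 10, 10, 0)   # central F cdf at 1 = 0.5
#' @export
noncentral_f_cdf <- function(w, nu1, nu2, lambda) {
  m <- f_to_beta(nu1, nu2, w)
  noncentral_beta_cdf(m$x, m$a, m$b, lambda)
}
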
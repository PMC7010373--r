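#' Closed real intervals with outwardly rounded arithmetic
#'
#' `interval(lo, hi)` constructs a closed interval \eqn{[lo, hi]} whose
#' arithmetic is carried out with outward rounding: every operation returns
#' an interval that is mathematically guaranteed to contain the exact
#' real-arithmetic result, whatever rounding the intermediate floating-point
#' computations incurred.  Endpoints may be `-Inf`/`Inf` (unbounded
#' intervals); the empty interval is a first-class value (see
#' [empty_interval()]) and propagates through arithmetic.
#'
#' Supported operations via the usual operators: `+`, `-`, `*`, `/`, `^`
#' (integer exponents use the tighter parity rule; general exponents require
#' a positive exponent and non-negative base), and `exp()`, `log()`,
#' `sqrt()`.  Division by an interval containing zero and `log` of an
#' interval reaching zero are domain errors.
#'
#' @param lo,hi numeric scalars, `lo <= hi`; `hi` defaults to `lo` (a point
#'   interval).
#' @return An object of class `"interval"`: a length-2 numeric `c(lo, hi)`.
#' @examples
#' x <- interval(1, 2)
#' x + interval(3, 4)        # exactly [4, 6]
#' interval(0.1) + interval(0.2)  # a thin interval enclosing 3/10
#' exp(interval(0, 1))       # encloses [1, e]
#' @export
interval <- function(lo, hi = lo) {
  if (!is.numeric(lo) || length(lo) != 1L || !is.numeric(hi) || length(hi) != 1L)
    stop("interval endpoints must be numeric scalars")
  lo <- as.double(lo); hi <- as.double(hi)
  if (is.nan(lo) || is.nan(hi) || is.na(lo) || is.na(hi))
    stop("interval endpoints must not be NA/NaN (use empty_interval())")
  if (lo > hi)
    stop("interval lower bound exceeds upper bound")
  new_interval(c(lo, hi))
}

new_interval <- function(x) {
  structure(as.double(x), names = NULL, class = "interval")
}

#' The empty interval
#'
#' @return The empty interval; arithmetic on it stays empty, intersections
#'   may produce it.
#' @export
empty_interval <- function() new_interval(c(NA_real_, NA_real_))

#' @rdname empty_interval
#' @param x an `"interval"`.
#' @export
is_empty_interval <- function(x) is.na(unclass(x)[1L])

#' @export
is_interval <- function(x) inherits(x, "interval")

#' Coerce to an interval
#'
#' Numeric scalars become point intervals; length-2 numerics become
#' `[x[1], x[2]]`.
#' @param x object to coerce.
#' @export
as_interval <- function(x) {
  if (is_interval(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(interval(x))
  if (is.numeric(x) && length(x) == 2L) return(interval(x[1L], x[2L]))
  stop("cannot coerce to interval")
}

#' @export
lower <- function(x) unclass(x)[1L]

#' @export
upper <- function(x) unclass(x)[2L]

.iv <- function(x) {
  # internal: plain c(lo, hi) from interval / numeric scalar
  if (is_interval(x)) return(unclass(x))
  if (is.numeric(x) && length(x) == 1L) return(c(x, x))
  stop("expected an interval or a numeric scalar")
}

# ------------------------------------------------------------------
# group generics shared by intervals and differential intervals.
# One function serves as the Ops method for both classes so that mixed
# interval/dint expressions dispatch cleanly (R uses the method when the
# two methods are identical).

ops_carrier <- function(e1, e2) {
  g <- .Generic
  if (missing(e2)) {
    if (g == "+") return(e1)
    if (g == "-") {
      if (inherits(e1, "dint")) return(new_dint(.Call(C_di_neg, unclass(e1))))
      return(new_interval(.Call(C_iv_neg, .iv(e1))))
    }
    stop(sprintf("unary '%s' is not defined for intervals", g))
  }
  if (!g %in% c("+", "-", "*", "/", "^"))
    stop(sprintf("operation '%s' is not defined for intervals", g))

  if (inherits(e1, "dint") || inherits(e2, "dint")) {
    if (g == "^") {
      # a constant exponent uses the derivative rule c * f^(c-1) * f',
      # valid for bases touching zero; a genuine dint exponent needs f > 0
      cst <- .pow_constant_exponent(e2)
      f <- .as_dint(e1)
      if (!is.null(cst))
        return(new_dint(.Call(C_di_pow_const, unclass(f), cst)))
      return(new_dint(.Call(C_di_pow_gen, unclass(f), unclass(.as_dint(e2)))))
    }
    f <- unclass(.as_dint(e1)); h <- unclass(.as_dint(e2))
    r <- switch(g,
      "+" = .Call(C_di_add, f, h),
      "-" = .Call(C_di_sub, f, h),
      "*" = .Call(C_di_mul, f, h),
      "/" = {
        if (.contains0(h[1:2])) stop("interval division by an interval containing zero")
        .Call(C_di_div, f, h)
      })
    return(new_dint(r))
  }

  x <- .iv(e1); y <- .iv(e2)
  r <- switch(g,
    "+" = .Call(C_iv_add, x, y),
    "-" = .Call(C_iv_sub, x, y),
    "*" = .Call(C_iv_mul, x, y),
    "/" = .Call(C_iv_div, x, y),
    "^" = {
      .check_pow_domain(x, y)
      .Call(C_iv_pow, x, y)
    })
  new_interval(r)
}

.contains0 <- function(v) !is.na(v[1L]) && v[1L] <= 0 && v[2L] >= 0

.check_pow_domain <- function(x, y) {
  if (is.na(y[1L]) || is.na(x[1L])) return(invisible())
  integral <- y[1L] == y[2L] && is.finite(y[1L]) && y[1L] == floor(y[1L])
  if (integral) {
    if (y[1L] < 0 && .contains0(x))
      stop("negative integer power of an interval containing zero")
    return(invisible())
  }
  if (y[1L] <= 0)
    stop("interval power with non-integer exponent requires a positive exponent")
  if (x[1L] < 0)
    stop("interval power with non-integer exponent requires a non-negative base")
  invisible()
}

# constant exponent (numeric scalar, point interval, or zero-derivative
# point dint) as a double, else NULL
.pow_constant_exponent <- function(e) {
  if (is.numeric(e) && length(e) == 1L && !inherits(e, "dint")) return(as.double(e))
  if (is_interval(e)) {
    v <- unclass(e)
    if (!is.na(v[1L]) && v[1L] == v[2L]) return(v[1L])
    return(NULL)
  }
  if (inherits(e, "dint")) {
    v <- unclass(e)
    if (v[1L] == v[2L] && v[3L] == 0 && v[4L] == 0) return(v[1L])
  }
  NULL
}

#' @export
Ops.interval <- ops_carrier

math_carrier <- function(x, ...) {
  g <- .Generic
  if (inherits(x, "dint")) {
    v <- unclass(x)
    r <- switch(g,
      exp = .Call(C_di_exp, v),
      log = {
        if (v[1L] <= 0) stop("log of an interval with non-positive lower bound")
        .Call(C_di_log, v)
      },
      sqrt = .Call(C_di_pow_const, v, 0.5),
      stop(sprintf("'%s' is not defined for differential intervals", g)))
    return(new_dint(r))
  }
  v <- .iv(x)
  r <- switch(g,
    exp = .Call(C_iv_exp, v),
    log = .Call(C_iv_log, v),
    sqrt = .Call(C_iv_pow, v, c(0.5, 0.5)),
    stop(sprintf("'%s' is not defined for intervals", g)))
  new_interval(r)
}

#' @export
Math.interval <- math_carrier

# the dint methods are the *same* functions, so mixed interval/dint
# expressions dispatch without an "incompatible methods" warning

#' @export
Ops.dint <- ops_carrier

#' @export
Math.dint <- math_carrier

# ------------------------------------------------------------------
# metrics

.check_nonempty <- function(x) {
  if (is_empty_interval(x)) stop("metric of an empty interval")
  invisible(x)
}

#' Interval metrics
#'
#' `mid()` is a machine float inside the interval; `wid()` is the width
#' `hi - lo` rounded up; `rad()` half the width; `mag()` the magnitude
#' (largest absolute value in the interval); `mig()` the mignitude (smallest
#' absolute value, 0 when the interval contains 0).
#'
#' @param x a non-empty `"interval"` (`mid` additionally requires bounded
#'   endpoints).
#' @return A numeric scalar.
#' @examples
#' mid(interval(1, 3)); wid(interval(1, 3)); mig(interval(-4, 2))
#' @export
mid <- function(x) {
  .check_nonempty(x)
  v <- .iv(x)
  if (!all(is.finite(v))) stop("midpoint of an unbounded interval")
  m <- 0.5 * v[1L] + 0.5 * v[2L]
  if (!is.finite(m)) m <- v[1L] + 0.5 * (v[2L] - v[1L])
  min(max(m, v[1L]), v[2L])
}

#' @rdname mid
#' @export
wid <- function(x) {
  .check_nonempty(x)
  v <- .iv(x)
  if (v[1L] == v[2L]) return(0)
  .Call(C_iv_sub, c(v[2L], v[2L]), c(v[1L], v[1L]))[2L]
}

#' @rdname mid
#' @export
rad <- function(x) 0.5 * wid(x)

#' @rdname mid
#' @export
mag <- function(x) {
  .check_nonempty(x)
  v <- .iv(x)
  max(abs(v[1L]), abs(v[2L]))
}

#' @rdname mid
#' @export
mig <- function(x) {
  .check_nonempty(x)
  v <- .iv(x)
  if (.contains0(v)) return(0)
  min(abs(v[1L]), abs(v[2L]))
}

# ------------------------------------------------------------------
# set operations

#' Interval set operations
#'
#' `interval_intersect()` returns the exact set intersection (possibly
#' empty); `interval_hull()` the tightest interval containing both
#' arguments; `in_interval(v, x)` tests membership of a point;
#' `interior_subset(x, y)` tests whether `x` lies in the interior of `y`
#' (strict inequalities at every finite end of `y`).
#'
#' @param x,y objects of class `"interval"`.
#' @param v a numeric scalar.
#' @export
interval_intersect <- function(x, y) {
  a <- .iv(x); b <- .iv(y)
  if (anyNA(a) || anyNA(b)) return(empty_interval())
  lo <- max(a[1L], b[1L]); hi <- min(a[2L], b[2L])
  if (lo > hi) return(empty_interval())
  new_interval(c(lo, hi))
}

#' @rdname interval_intersect
#' @export
interval_hull <- function(x, y) {
  a <- .iv(x); b <- .iv(y)
  if (anyNA(a)) return(if (anyNA(b)) empty_interval() else new_interval(b))
  if (anyNA(b)) return(new_interval(a))
  new_interval(c(min(a[1L], b[1L]), max(a[2L], b[2L])))
}

#' @rdname interval_intersect
#' @export
in_interval <- function(v, x) {
  a <- .iv(x)
  if (anyNA(a)) return(FALSE)
  a[1L] <= v && v <= a[2L]
}

#' @rdname interval_intersect
#' @export
interior_subset <- function(x, y) {
  a <- .iv(x); b <- .iv(y)
  if (anyNA(a)) return(TRUE)   # the empty set is inside any interior
  if (anyNA(b)) return(FALSE)
  lo_ok <- b[1L] < a[1L] || (is.infinite(b[1L]) && b[1L] < 0)
  hi_ok <- a[2L] < b[2L] || (is.infinite(b[2L]) && b[2L] > 0)
  lo_ok && hi_ok
}

#' Epsilon inflation
#'
#' Widens an interval relatively by `eps` and absolutely by at least one
#' unit in the last place per side, so that the result strictly contains the
#' input in its interior.  Used to give the interval Newton uniqueness test
#' room around near-point enclosures.
#'
#' @param x a non-empty `"interval"`.
#' @param eps positive relative inflation.
#' @export
epsilon_inflate <- function(x, eps) {
  .check_nonempty(x)
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("eps must be a positive scalar")
  v <- .iv(x)
  lo <- .Call(C_nextafter, v[1L] - eps * abs(v[1L]), FALSE)
  hi <- .Call(C_nextafter, v[2L] + eps * abs(v[2L]), TRUE)
  new_interval(c(lo, hi))
}

# ------------------------------------------------------------------

#' @export
format.interval <- function(x, digits = 17L, ...) {
  if (is_empty_interval(x)) return("[empty]")
  v <- .iv(x)
  sprintf("[%s, %s]", format(v[1L], digits = digits),
          format(v[2L], digits = digits))
}

#' @export
print.interval <- function(x, digits = 17L, ...) {
  cat("<interval> ", format(x, digits = digits), "\n", sep = "")
  if (!is_empty_interval(x) && all(is.finite(.iv(x))))
    cat("  mid ", format(mid(x), digits = digits),
        "  wid ", format(wid(x), digits = 3L), "\n", sep = "")
  invisible(x)
}
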
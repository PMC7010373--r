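#' Result of an interval Newton iteration
#'
#' @description
#' `newton_result` objects carry the three verified outcomes of the interval
#' Newton method:
#' \describe{
#'   \item{`"UNIQUE"`}{the final enclosure provably contains exactly one zero
#'     of the function (an operator step mapped an iterate into its own
#'     interior);}
#'   \item{`"EMPTY"`}{the initial interval provably contains no zero (an
#'     iterate intersection became empty);}
#'   \item{`"FAILED"`}{existence/uniqueness could not be verified; the last
#'     enclosure (which still contains every zero of the function in the
#'     initial interval) is reported.}
#' }
#' @name newton_result
NULL

new_newton_result <- function(status, enclosure, iterations, trace = NULL,
                              message = "") {
  structure(list(status = status, enclosure = enclosure,
                 iterations = iterations, trace = trace, message = message),
            class = "newton_result")
}

#' @export
print.newton_result <- function(x, digits = 17L, ...) {
  cat(sprintf("<newton_result> status %s after %d iteration(s)\n",
              x$status, x$iterations))
  if (!is_empty_interval(x$enclosure))
    cat("  enclosure ", format(x$enclosure, digits = digits), "\n", sep = "")
  if (nzchar(x$message)) cat("  ", x$message, "\n", sep = "")
  invisible(x)
}

#' Univariate interval Newton operator
#'
#' Computes \eqn{N(f, f'; x, \tilde x) = \tilde x - f(\tilde x) / f'(x)} in
#' interval arithmetic, where the value enclosure \eqn{f(\tilde x)} is taken
#' at the point `xt` and the derivative enclosure \eqn{f'(x)} over the whole
#' interval `x` (both obtained by evaluating `f` on differential intervals).
#' Every zero of the true function inside `x` lies in the returned interval;
#' an empty intersection of the result with `x` therefore proves absence of
#' zeros.
#'
#' If the derivative enclosure contains zero the operator cannot divide; a
#' condition of class `"ncfcheck_straddle"` is signalled (callers such as
#' [newton_iterate()] fall back to bisection).
#'
#' @param f a function taking and returning a `"dint"`.
#' @param x a non-empty bounded `"interval"`.
#' @param xt a machine float inside `x` (defaults to the midpoint).
#' @return An `"interval"` (possibly empty after intersection by the
#'   caller).
#' @examples
#' f <- function(u) u * u - dint_constant(interval(2))
#' newton_operator(f, interval(1, 2), 1.5)   # contains sqrt(2)
#' @export
newton_operator <- function(f, x, xt = mid(x)) {
  .check_nonempty(x)
  if (!in_interval(xt, x)) stop("xt must lie inside x")
  dfx <- f(dint_variable(x))
  fd <- dint_der(dfx)
  if (in_interval(0, fd))
    stop(errorCondition(
      "derivative enclosure contains zero (Newton operator undefined)",
      class = "ncfcheck_straddle"))
  ft <- dint_val(f(dint_variable(interval(xt))))
  interval(xt) - ft / fd
}

#' Interval Newton iteration with verified outcomes
#'
#' Iterates \eqn{x^{(k+1)} = x^{(k)} \cap N(f, f'; x^{(k)}, \check x^{(k)})}
#' from `x0`.  An empty intersection proves that `x0` contains no zero
#' (status `"EMPTY"`).  Once the enclosure width converges (relative width
#' below `rel_tol`, or no further shrinkage), uniqueness is verified by
#' applying one operator step to an epsilon-inflated enclosure and testing
#' the strict interior-containment criterion; on success the status is
#' `"UNIQUE"` and the enclosure contains exactly one zero.  Anything else is
#' `"FAILED"` (never an exception), with the last enclosure.
#'
#' When the derivative enclosure over an iterate contains zero, the interval
#' is bisected and both halves are processed recursively, within a total
#' budget of `max_bisect` subdivisions; sub-results are combined (`"UNIQUE"`
#' only when exactly one half verified a zero and the rest were provably
#' empty).  Unbounded iterates fail.
#'
#' @param f function taking and returning a `"dint"`.
#' @param x0 non-empty initial `"interval"`.
#' @param rel_tol relative width tolerance for convergence (default 1e-13).
#' @param max_iter maximum Newton iterations per branch (default 100).
#' @param max_bisect total bisection budget on derivative straddles
#'   (default 64).
#' @param trace if `TRUE`, record per-iteration enclosures.
#' @return A [newton_result] object.
#' @examples
#' f <- function(u) u * u - dint_constant(interval(2))
#' newton_iterate(f, interval(1, 2))   # UNIQUE, encloses sqrt(2)
#' @export
newton_iterate <- function(f, x0, rel_tol = 1e-13, max_iter = 100L,
                           max_bisect = 64L, trace = FALSE) {
  .check_nonempty(x0)
  if (rel_tol <= 0) stop("rel_tol must be positive")
  st <- new.env(parent = emptyenv())
  st$bisections <- 0L
  st$iterations <- 0L
  st$trace <- if (trace) list() else NULL
  r <- .newton_branch(f, x0, rel_tol, max_iter, as.integer(max_bisect), st)
  new_newton_result(r$status, r$enclosure, st$iterations, st$trace,
                    r$message)
}

.newton_branch <- function(f, x, rel_tol, max_iter, max_bisect, st) {
  res <- function(status, enc, msg = "") {
    list(status = status, enclosure = enc, message = msg)
  }
  for (k in seq_len(max_iter)) {
    if (!all(is.finite(.iv(x))))
      return(res("FAILED", x, "unbounded iterate"))
    st$iterations <- st$iterations + 1L
    dfx <- tryCatch(f(dint_variable(x)), error = function(e) e)
    if (inherits(dfx, "error"))
      return(res("FAILED", x, paste("evaluation error:",
                                    conditionMessage(dfx))))
    fv <- dint_val(dfx); fd <- dint_der(dfx)
    if (is_empty_interval(fv)) return(res("EMPTY", empty_interval()))
    if (!in_interval(0, fv)) return(res("EMPTY", empty_interval()))
    if (in_interval(0, fd))
      return(.newton_bisect(f, x, rel_tol, max_iter, max_bisect, st))

    xt <- mid(x)
    ft <- tryCatch(dint_val(f(dint_variable(interval(xt)))),
                   error = function(e) e)
    if (inherits(ft, "error"))
      return(res("FAILED", x, paste("evaluation error:",
                                    conditionMessage(ft))))
    nx <- interval(xt) - ft / fd
    xn <- interval_intersect(x, nx)
    if (!is.null(st$trace)) st$trace[[length(st$trace) + 1L]] <- xn
    if (is_empty_interval(xn)) return(res("EMPTY", empty_interval()))

    w_old <- wid(x); w_new <- wid(xn)
    converged <- w_new <= rel_tol * max(mag(xn), .Machine$double.xmin) ||
      w_new >= w_old
    x <- xn
    if (converged) return(.newton_verify(f, xn, st))
  }
  res("FAILED", x, "iteration limit reached without convergence")
}

# uniqueness via one operator step on an epsilon-inflated enclosure and the
# strict interior-containment test; retried once with a 100x larger inflation
.newton_verify <- function(f, xn, st) {
  for (eps in c(1e-10, 1e-8)) {
    y <- epsilon_inflate(xn, eps)
    dfy <- tryCatch(f(dint_variable(y)), error = function(e) e)
    if (inherits(dfy, "error")) next
    fdy <- dint_der(dfy)
    if (in_interval(0, fdy)) next
    yt <- mid(y)
    fyt <- dint_val(f(dint_variable(interval(yt))))
    ny <- interval(yt) - fyt / fdy
    if (interior_subset(ny, y)) {
      enc <- interval_intersect(ny, xn)
      if (is_empty_interval(enc)) enc <- interval_intersect(ny, y)
      return(list(status = "UNIQUE", enclosure = enc, message = ""))
    }
  }
  list(status = "FAILED", enclosure = xn,
       message = "width converged but uniqueness verification failed")
}

.newton_bisect <- function(f, x, rel_tol, max_iter, max_bisect, st) {
  if (st$bisections >= max_bisect)
    return(list(status = "FAILED", enclosure = x,
                message = "derivative straddles zero; bisection budget exhausted"))
  st$bisections <- st$bisections + 1L

  # pick a split point whose function value enclosure excludes zero, so the
  # two halves cannot both claim the same boundary root
  w <- wid(x)
  cand <- mid(x) + c(0, 0.25, -0.25) * w
  m <- cand[1L]
  for (cm in cand) {
    if (!in_interval(cm, x)) next
    fv <- tryCatch(dint_val(f(dint_variable(interval(cm)))),
                   error = function(e) NULL)
    if (!is.null(fv) && !in_interval(0, fv)) { m <- cm; break }
  }
  v <- .iv(x)
  left  <- .newton_branch(f, interval(v[1L], m), rel_tol, max_iter,
                          max_bisect, st)
  right <- .newton_branch(f, interval(m, v[2L]), rel_tol, max_iter,
                          max_bisect, st)
  parts <- list(left, right)
  statuses <- vapply(parts, `[[`, "", "status")
  if (all(statuses == "EMPTY"))
    return(list(status = "EMPTY", enclosure = empty_interval(), message = ""))
  uni <- parts[statuses == "UNIQUE"]
  if (length(uni) == 1L && !any(statuses == "FAILED"))
    return(uni[[1L]])
  hull <- Reduce(interval_hull,
                 lapply(parts[statuses != "EMPTY"], `[[`, "enclosure"))
  msg <- if (length(uni) > 1L) "multiple verified zeros in the interval"
         else "verification failed in a subinterval"
  list(status = "FAILED", enclosure = hull, message = msg)
}
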
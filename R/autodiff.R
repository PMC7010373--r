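#' Interval differential numbers (forward-mode derivatives)
#'
#' A differential interval is a pair (value enclosure, derivative enclosure):
#' evaluating an expression built from `+`, `-`, `*`, `/`, `^`, `exp`, `log`,
#' `sqrt` on a differential interval seeded as the *variable* yields an
#' enclosure of the function value over the input interval together with an
#' enclosure of the first derivative over that interval — the derivative
#' extension the interval Newton operator needs.  Real constants embed with a
#' zero derivative.
#'
#' `^` with a constant exponent `c` uses the rule `c * f^(c-1) * f'` (valid
#' for bases touching zero); a genuinely varying exponent uses
#' `f^g (g' log f + g f'/f)` and requires `f > 0`.
#'
#' @param val value enclosure: an `"interval"` or numeric scalar.
#' @param der derivative enclosure: an `"interval"` or numeric scalar.
#' @return An object of class `"dint"`.
#' @examples
#' x <- dint_variable(interval(2))
#' x * x               # value [4,4], derivative [4,4]
#' dint_der(exp(dint_variable(interval(0, 1))))  # contains [1, e]
#' @export
dint <- function(val, der) {
  v <- .iv(as_interval(val)); d <- .iv(as_interval(der))
  new_dint(c(v, d))
}

new_dint <- function(x) structure(as.double(x), names = NULL, class = "dint")

#' @rdname dint
#' @param x value interval (for `dint_variable`), value interval or numeric
#'   (for `dint_constant`), or a `"dint"` (for the accessors).
#' @export
dint_variable <- function(x) dint(x, interval(1))

#' @rdname dint
#' @export
dint_constant <- function(x) dint(x, interval(0))

#' @rdname dint
#' @export
dint_val <- function(x) {
  stopifnot(inherits(x, "dint"))
  new_interval(unclass(x)[1:2])
}

#' @rdname dint
#' @export
dint_der <- function(x) {
  stopifnot(inherits(x, "dint"))
  new_interval(unclass(x)[3:4])
}

#' @export
is_dint <- function(x) inherits(x, "dint")

.as_dint <- function(x) {
  if (inherits(x, "dint")) return(x)
  dint_constant(as_interval(x))
}

#' @export
format.dint <- function(x, digits = 17L, ...) {
  sprintf("(%s; %s)", format(dint_val(x), digits = digits),
          format(dint_der(x), digits = digits))
}

#' @export
print.dint <- function(x, digits = 17L, ...) {
  cat("<differential interval>\n  value      ",
      format(dint_val(x), digits = digits),
      "\n  derivative ", format(dint_der(x), digits = digits), "\n", sep = "")
  invisible(x)
}
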
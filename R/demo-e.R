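#' Enclosing Euler's number: interval arithmetic as automatic error analysis
#'
#' Evaluates \eqn{f(n) = (1+1/n)^n} and \eqn{g(n) = (1-1/n)^{-n}} at
#' \eqn{n = 10^k} in outwardly rounded interval arithmetic.  In exact
#' arithmetic \eqn{f(n) < e < g(n)} with both sides converging to \eqn{e};
#' in plain floating point the computed values violate these bounds badly
#' for large \eqn{k}, while the interval evaluation always satisfies
#' \eqn{\underline f(n) \le e \le \overline g(n)} and signals the
#' catastrophic cancellation through wide enclosures instead of silently
#' wrong digits.
#'
#' @param k_max largest exponent (default 17).
#' @return A data frame with columns `k`, `f_lo`, `f_hi`, `g_lo`, `g_hi`,
#'   `float_f`, `float_g` (the plain floating-point values for contrast) and
#'   attribute `"e"` holding a 50-digit-accurate double of Euler's number.
#' @examples
#' d <- e_enclosure_demo(8)
#' all(d$f_lo <= attr(d, "e") & attr(d, "e") <= d$g_hi)
#' @export
e_enclosure_demo <- function(k_max = 17L) {
  stopifnot(k_max >= 1L, k_max <= 22L)  # 10^k exactly representable
  one <- interval(1)
  rows <- lapply(seq_len(k_max), function(k) {
    n <- 10^k
    ni <- interval(n)
    f <- (one + one / ni)^ni
    g <- one / ((one - one / ni)^ni)
    data.frame(k = k,
               f_lo = lower(f), f_hi = upper(f),
               g_lo = lower(g), g_hi = upper(g),
               float_f = (1 + 1 / n)^n,
               float_g = (1 - 1 / n)^(-n))
  })
  out <- do.call(rbind, rows)
  # e to 50 digits, rounded to the nearest double
  attr(out, "e") <- 2.71828182845904523536028747135266249775724709369996
  out
}
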
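#' Reference grids for the upper-0.05 quantile and the noncentrality
#'
#' Loads the published reference grids shipped with the package: the upper
#' \eqn{\alpha = 0.05} quantiles of the central beta distribution and the
#' noncentrality parameters giving type II error \eqn{\beta = 0.10}, over
#' the parameter range of practical interest
#' (\eqn{a \in \{0.5, 1, 1.5, 2, 2.5, 3, 5, 10, 25\}},
#' \eqn{b \in \{1,\ldots,15, 20, 30, 40, 50, 100, 250, 500\}}), printed to 6
#' significant digits with the last digit rounded to nearest.  These are the
#' standard minimal-detectable-difference tables for general ANOVA models in
#' their beta-scale form; the package's acceptance tests recompute every
#' entry from scratch.
#'
#' @return A list of two data frames, `quantiles` and `noncentrality`, each
#'   in long format with columns `a`, `b`, `value`.
#' @export
reference_power_tables <- function() {
  rd <- function(f) {
    path <- system.file("extdata", f, package = "ncfcheck", mustWork = TRUE)
    w <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
    avals <- as.numeric(sub("^a", "", names(w)[-1L]))
    long <- do.call(rbind, lapply(seq_along(avals), function(j) {
      data.frame(a = avals[j], b = w$b, value = w[[j + 1L]])
    }))
    long[order(long$a, long$b), , drop = FALSE]
  }
  list(quantiles = rd("beta_quantiles_alpha05.tsv"),
       noncentrality = rd("noncentrality_alpha05_beta10.tsv"))
}
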
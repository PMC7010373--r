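#' Read candidate records from a plain text file
#'
#' Each non-comment line holds one record of six whitespace-separated
#' fields.  In the `"beta"` dialect these are
#' `a b alpha beta x_cand lambda_cand`; in the `"f"` dialect
#' `nu1 nu2 alpha beta x_cand lambda_cand`, which is mapped to the beta
#' scale via `a = nu1/2`, `b = nu2/2` (so `nu2` must be even — an odd `nu2`
#' marks that record invalid rather than aborting the batch).  Lines starting
#' with `#` and blank lines are ignored.
#'
#' @param path path to the input file.
#' @param dialect `"beta"` (default) or `"f"`.
#' @return A data frame with columns `id` (input line number), `a`, `b`,
#'   `alpha`, `beta_err`, `x_cand`, `lam_cand`, `valid` (logical) and
#'   `note` (per-record parse diagnostics such as an odd `nu2`).
#' @export
parse_input_file <- function(path, dialect = c("beta", "f")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  recs <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(fields) != 6L)
      stop(sprintf("line %d: expected 6 fields, found %d", i, length(fields)))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("line %d: non-numeric field '%s'", i,
                   fields[which(is.na(vals))[1L]]))
    if (any(!is.finite(vals)) || any(vals <= 0))
      stop(sprintf("line %d: all fields must be finite and positive", i))
    valid <- TRUE; note <- ""
    if (dialect == "f") {
      if (vals[2L] != floor(vals[2L]) || (vals[2L] %% 2) != 0) {
        valid <- FALSE
        note <- sprintf("odd or non-integer nu2 = %s: method needs nu2 even",
                        fields[2L])
      }
      vals[1L] <- vals[1L] / 2
      vals[2L] <- vals[2L] / 2
    }
    if (valid && (vals[2L] < 1 || vals[2L] != floor(vals[2L]))) {
      valid <- FALSE
      note <- sprintf("b = %s is not a positive integer", format(vals[2L]))
    }
    recs[[j]] <- data.frame(id = i, a = vals[1L], b = vals[2L],
                            alpha = vals[3L], beta_err = vals[4L],
                            x_cand = vals[5L], lam_cand = vals[6L],
                            valid = valid, note = note,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(recs, list(make.row.names = FALSE)))
}

#' Cross-check a batch of candidate records
#'
#' Runs [solve_power()] independently on every record and maps the Newton
#' statuses to verdicts: `VERIFIED` (unique solution enclosed — the software
#' under test is at least as accurate as the inflation radius), `REJECTED`
#' (the inflated interval provably contains no solution — it is not),
#' `FAILED` (no conclusion), and `SKIPPED` for the lambda step whenever the
#' quantile step did not verify.  A failure in one record never aborts the
#' batch.
#'
#' @param records data frame as returned by [parse_input_file()] (extra
#'   columns are ignored; `valid`/`note` are optional).
#' @param eps_x,eps_lambda relative inflation radii (default 1e-6).
#' @param rel_tol,max_iter Newton controls.
#' @param wide if `TRUE`, ignore the candidate columns and compute both
#'   values from scratch with wide initial intervals.
#' @param verbose if `TRUE`, log per-record timing to standard error.
#' @return A data frame of verdicts with one row per record: `id`, the
#'   problem parameters, `x_status`, `x_lo`, `x_hi`, `lambda_status`,
#'   `lambda_lo`, `lambda_hi`, `message`.
#' @export
crosscheck <- function(records, eps_x = 1e-6, eps_lambda = 1e-6,
                       rel_tol = 1e-13, max_iter = 100L, wide = FALSE,
                       verbose = FALSE) {
  n <- nrow(records)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    if (!is.null(r$valid) && !isTRUE(r$valid)) {
      out[[i]] <- .verdict_row(r$id, r, "FAILED", empty_interval(),
                               "SKIPPED", empty_interval(),
                               if (is.null(r$note)) "invalid record" else r$note)
      next
    }
    t0 <- proc.time()[["elapsed"]]
    sol <- tryCatch({
      pr <- withCallingHandlers(
        beta_problem(r$a, r$b, r$alpha, r$beta_err),
        warning = function(w) invokeRestart("muffleWarning"))
      solve_power(pr,
                  x_cand = if (wide) NULL else r$x_cand,
                  lam_cand = if (wide) NULL else r$lam_cand,
                  eps_x = eps_x, eps_lambda = eps_lambda,
                  rel_tol = rel_tol, max_iter = max_iter)
    }, error = function(e) e)
    if (verbose)
      message(sprintf("record %s: %.3f s", r$id,
                      proc.time()[["elapsed"]] - t0))
    if (inherits(sol, "error")) {
      out[[i]] <- .verdict_row(r$id, r, "FAILED", empty_interval(),
                               "SKIPPED", empty_interval(),
                               conditionMessage(sol))
      next
    }
    map <- c(UNIQUE = "VERIFIED", EMPTY = "REJECTED", FAILED = "FAILED")
    xs <- map[[sol$x_result$status]]
    x_enc <- if (xs == "REJECTED") inflate_candidate(r$x_cand, eps_x)
             else sol$x_result$enclosure
    if (xs != "VERIFIED") {
      ls <- "SKIPPED"; l_enc <- empty_interval()
    } else {
      ls <- map[[sol$lambda_result$status]]
      l_enc <- if (ls == "REJECTED") inflate_candidate(r$lam_cand, eps_lambda)
               else sol$lambda_result$enclosure
    }
    msg <- trimws(paste(sol$x_result$message, sol$lambda_result$message))
    out[[i]] <- .verdict_row(r$id, r, xs, x_enc, ls, l_enc, msg)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.verdict_row <- function(id, r, xs, x_enc, ls, l_enc, msg) {
  xe <- .iv(if (is_interval(x_enc)) x_enc else empty_interval())
  le <- .iv(if (is_interval(l_enc)) l_enc else empty_interval())
  data.frame(id = id, a = r$a, b = r$b, alpha = r$alpha,
             beta_err = r$beta_err,
             x_status = xs, x_lo = xe[1L], x_hi = xe[2L],
             lambda_status = ls, lambda_lo = le[1L], lambda_hi = le[2L],
             message = if (is.null(msg) || is.na(msg)) "" else msg,
             stringsAsFactors = FALSE)
}

#' Count correct significant digits of a candidate value
#'
#' Returns the largest `k <= max_digits` such that the candidate and the
#' midpoint of the verified enclosure agree when both are rounded to `k`
#' significant digits (0 if they differ already at one digit).  The
#' enclosure must itself be unambiguous at `max_digits` significant digits
#' (both bounds round identically), otherwise an error is raised.
#'
#' @param candidate numeric scalar produced by the software under test.
#' @param verified an `"interval"` enclosing the correct value.
#' @param max_digits maximum digits to compare (default 7).
#' @return Integer in `0:max_digits`.
#' @examples
#' count_correct_sigdigits(0.4563021, interval(0.4563026), max_digits = 7)
#' @export
count_correct_sigdigits <- function(candidate, verified, max_digits = 7L) {
  verified <- as_interval(verified)
  .check_nonempty(verified)
  v <- .iv(verified)
  if (!all(is.finite(v))) stop("verified enclosure must be bounded")
  if (signif(v[1L], max_digits) != signif(v[2L], max_digits))
    stop("verified enclosure is too wide to be rounded unambiguously to ",
         max_digits, " significant digits")
  m <- mid(verified)
  agree <- vapply(seq_len(max_digits),
                  function(d) signif(candidate, d) == signif(m, d), logical(1L))
  if (!any(agree)) return(0L)
  max(which(agree))
}

#' Generate a candidate input file emulating software under test
#'
#' For every row of `grid` the true values of the quantile and the
#' noncentrality parameter are computed from scratch (wide mode), their
#' enclosure midpoints are taken as the "software under test" output, and an
#' error model is applied:
#' \describe{
#'   \item{`"exact"`}{midpoints written as-is (cross-checking then verifies
#'     every record);}
#'   \item{`"perturb"`}{the lambda candidate is multiplied by
#'     \eqn{1 \pm u}, `u` drawn uniformly from `[delta/2, delta]` with random
#'     sign, the quantile kept exact (cross-checking at an inflation radius
#'     well below `delta` then rejects every lambda);}
#'   \item{`"overflow-bogus"`}{the lambda candidate is replaced by a grossly
#'     wrong value (scaled by one to two orders of magnitude), emulating a
#'     silent overflow.}
#' }
#' Output is deterministic given `seed`.
#'
#' @param grid data frame with columns `a`, `b`, `alpha`, `beta_err`.
#' @param path output file path.
#' @param error_model one of `"exact"`, `"perturb"`, `"overflow-bogus"`.
#' @param delta relative perturbation size for `"perturb"` (default 1e-3).
#' @param seed integer seed fixing the randomness.
#' @return `path`, invisibly.
#' @export
generate_fixtures <- function(grid, path, error_model = c("exact", "perturb",
                                                          "overflow-bogus"),
                              delta = 1e-3, seed = 1L) {
  error_model <- match.arg(error_model)
  stopifnot(all(c("a", "b", "alpha", "beta_err") %in% names(grid)))
  rng <- .local_rng(seed)
  lines <- character(nrow(grid) + 2L)
  lines[1L] <- sprintf("# candidate values, error model '%s'%s",
                       error_model,
                       if (error_model == "perturb")
                         sprintf(" (delta = %g)", delta) else "")
  lines[2L] <- "# a b alpha beta x_cand lambda_cand"
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    pr <- beta_problem(g$a, g$b, g$alpha, g$beta_err)
    sol <- solve_power(pr)
    if (sol$x_result$status != "UNIQUE" ||
        sol$lambda_result$status != "UNIQUE")
      stop(sprintf("wide-mode solve failed for a = %g, b = %g", g$a, g$b))
    xc <- mid(sol$x_result$enclosure)
    lc <- mid(sol$lambda_result$enclosure)
    if (error_model == "perturb") {
      u <- rng(1) * delta / 2 + delta / 2          # in [delta/2, delta]
      s <- if (rng(1) < 0.5) -1 else 1
      lc <- lc * (1 + s * u)
    } else if (error_model == "overflow-bogus") {
      lc <- lc * 10^(1 + rng(1))                    # 1 to 2 decades off
    }
    lines[i + 2L] <- sprintf("%.17g %.17g %.17g %.17g %.17g %.17g",
                             g$a, g$b, g$alpha, g$beta_err, xc, lc)
  }
  writeLines(lines, path)
  invisible(path)
}

# deterministic uniform(0,1) stream that does not disturb the global RNG
.local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", env$state, globalenv())
    u <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    u
  }
}

#' Format verdicts as a tab-separated report
#'
#' Produces a TSV with header
#' `id a b alpha beta x_status x_lo x_hi lambda_status lambda_lo lambda_hi
#' message`.  Enclosure bounds are printed in scientific notation with
#' `digits` significant digits, rounded *outward* (lower bounds down, upper
#' bounds up), so the printed interval still encloses the computed one.
#'
#' @param verdicts data frame from [crosscheck()].
#' @param digits significant digits for the printed bounds (default 12).
#' @return A character vector of lines (header first).
#' @export
format_report <- function(verdicts, digits = 12L) {
  hdr <- paste(c("id", "a", "b", "alpha", "beta", "x_status", "x_lo", "x_hi",
                 "lambda_status", "lambda_lo", "lambda_hi", "message"),
               collapse = "\t")
  if (is.null(verdicts) || nrow(verdicts) == 0L) return(hdr)
  rows <- vapply(seq_len(nrow(verdicts)), function(i) {
    v <- verdicts[i, ]
    paste(c(v$id, format(v$a), format(v$b), format(v$alpha),
            format(v$beta_err), v$x_status,
            .fmt_directed(v$x_lo, digits, up = FALSE),
            .fmt_directed(v$x_hi, digits, up = TRUE),
            v$lambda_status,
            .fmt_directed(v$lambda_lo, digits, up = FALSE),
            .fmt_directed(v$lambda_hi, digits, up = TRUE),
            v$message), collapse = "\t")
  }, character(1L))
  c(hdr, rows)
}

# print x in scientific notation with `digits` significant digits, rounded
# toward -Inf (up = FALSE) or +Inf (up = TRUE)
.fmt_directed <- function(x, digits, up) {
  if (is.na(x)) return("NA")
  if (x == 0) return(sprintf("%.*e", digits - 1L, 0))
  if (is.infinite(x)) return(if (x > 0) "Inf" else "-Inf")
  s <- sprintf("%.*e", digits - 1L, x)
  v <- as.numeric(s)
  if ((up && v < x) || (!up && v > x)) {
    step <- 10^(floor(log10(abs(v))) - digits + 1L)
    v2 <- if (up) v + step else v - step
    s <- sprintf("%.*e", digits - 1L, v2)
    v3 <- as.numeric(s)
    if ((up && v3 < x) || (!up && v3 > x))
      s <- sprintf("%.*e", digits - 1L, if (up) v2 + step else v2 - step)
  }
  s
}
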
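test_that("input files parse with comments, dialects and per-record errors", {
  tf <- withr::local_tempfile()
  writeLines(c("# header comment",
               "",
               "0.5 1 0.05 0.10 0.9025 46.1803",
               "10 10 0.05 0.10 0.8 55",
               "10 7 0.05 0.10 0.8 55"), tf)
  rb <- parse_input_file(tf, dialect = "beta")
  expect_identical(nrow(rb), 3L)
  expect_identical(rb$id, c(3L, 4L, 5L))
  expect_identical(rb$a[1], 0.5)

  rf <- parse_input_file(tf, dialect = "f")
  expect_identical(rf$a, c(0.25, 5, 5))
  expect_identical(rf$b[2], 5)
  expect_false(rf$valid[1])          # nu2 = 1 is odd
  expect_false(rf$valid[3])          # nu2 = 7 is odd: record-level, no abort
  expect_match(rf$note[3], "even")
  expect_true(rf$valid[2])

  tf2 <- withr::local_tempfile()
  writeLines("0.5 1 0.05 0.10 0.9025", tf2)
  expect_error(parse_input_file(tf2), "line 1.*6 fields")
  tf3 <- withr::local_tempfile()
  writeLines(c("# ok", "0.5 one 0.05 0.10 0.9 46"), tf3)
  expect_error(parse_input_file(tf3), "line 2")
})

test_that("cross-checking issues the documented verdicts per record", {
  recs <- data.frame(id = 1:3, a = c(0.5, 0.5, 1), b = c(1, 1, 1),
                     alpha = 0.05, beta_err = 0.10,
                     x_cand = c(0.9025, 0.9025, 0.95),
                     lam_cand = c(46.18034458679990,
                                  46.18034458679990 * 1.01,  # 1 percent off
                                  90.0516719442),
                     valid = TRUE, note = "")
  v <- crosscheck(recs)
  expect_identical(v$x_status, rep("VERIFIED", 3))
  expect_identical(v$lambda_status, c("VERIFIED", "REJECTED", "VERIFIED"))
  # record failures never abort the batch
  recs2 <- rbind(recs,
                 data.frame(id = 4, a = 1, b = 1, alpha = 0.05,
                            beta_err = 0.96,   # ill-posed: beta >= 1 - alpha
                            x_cand = 0.95, lam_cand = 1,
                            valid = TRUE, note = ""))
  v2 <- crosscheck(recs2)
  expect_identical(nrow(v2), 4L)
  expect_identical(v2$x_status[4], "FAILED")
  expect_identical(v2$lambda_status[4], "SKIPPED")
})

test_that("shuffling input records permutes output rows identically", {
  recs <- data.frame(id = 1:4, a = c(0.5, 1, 2, 5), b = c(1, 2, 3, 5),
                     alpha = 0.05, beta_err = 0.10,
                     x_cand = NA_real_, lam_cand = NA_real_)
  # fill candidates from wide solves
  for (i in seq_len(nrow(recs))) {
    s <- solve_power(beta_problem(recs$a[i], recs$b[i], 0.05, 0.10))
    recs$x_cand[i] <- mid(s$x_result$enclosure)
    recs$lam_cand[i] <- mid(s$lambda_result$enclosure)
  }
  v1 <- crosscheck(recs)
  perm <- c(3L, 1L, 4L, 2L)
  v2 <- crosscheck(recs[perm, ])
  expected <- v1[perm, ]
  rownames(v2) <- rownames(expected) <- NULL
  expect_identical(v2, expected)
})

test_that("significant-digit counting reproduces every published count", {
  for (i in seq_len(nrow(NCBETA_REF))) {
    enc <- noncentral_beta_cdf(NCBETA_REF$x[i], NCBETA_REF$a[i],
                               NCBETA_REF$b[i], NCBETA_REF$lambda[i])
    expect_identical(count_correct_sigdigits(ALGO_TAB5$frick[i], enc),
                     ALGO_TAB5$frick_digits[i])
    expect_identical(count_correct_sigdigits(ALGO_TAB5$chatta[i], enc),
                     ALGO_TAB5$chatta_digits[i])
  }
  expect_error(count_correct_sigdigits(0.5, interval(0.4, 0.6)), "too wide")
})

test_that("reports round outward and reparse to enclosing intervals", {
  recs <- data.frame(id = 1L, a = 0.5, b = 1, alpha = 0.05, beta_err = 0.10,
                     x_cand = 0.9025, lam_cand = 46.1803)
  v <- crosscheck(recs)
  rep_lines <- format_report(v, digits = 12)
  expect_identical(length(rep_lines), 2L)
  expect_match(rep_lines[1], "^id\ta\tb\talpha\tbeta\tx_status")
  f <- strsplit(rep_lines[2], "\t")[[1]]
  expect_identical(f[6], "VERIFIED")
  expect_true(as.numeric(f[7]) <= v$x_lo && v$x_hi <= as.numeric(f[8]))
  expect_true(as.numeric(f[10]) <= v$lambda_lo &&
                v$lambda_hi <= as.numeric(f[11]))
  # directed decimal rounding
  expect_identical(ncfcheck:::.fmt_directed(1/3, 4, up = FALSE), "3.333e-01")
  expect_identical(ncfcheck:::.fmt_directed(1/3, 4, up = TRUE), "3.334e-01")
  expect_identical(ncfcheck:::.fmt_directed(-1/3, 4, up = TRUE), "-3.333e-01")
  # empty verdict list: header only
  expect_identical(format_report(v[0, ]), format_report(v)[1])
})

test_that("fixture generation is deterministic and models behave as stated", {
  grid <- data.frame(a = c(0.5, 2), b = c(1, 3), alpha = 0.05,
                     beta_err = 0.10)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  generate_fixtures(grid, f1, "exact", seed = 99)
  generate_fixtures(grid, f2, "exact", seed = 99)
  expect_identical(readLines(f1), readLines(f2))

  v <- crosscheck(parse_input_file(f1))
  expect_true(all(v$x_status == "VERIFIED"))
  expect_true(all(v$lambda_status == "VERIFIED"))

  f3 <- withr::local_tempfile()
  generate_fixtures(grid, f3, "perturb", delta = 1e-3, seed = 7)
  v3 <- crosscheck(parse_input_file(f3))
  expect_true(all(v3$x_status == "VERIFIED"))
  expect_true(all(v3$lambda_status == "REJECTED"))

  f4 <- withr::local_tempfile()
  generate_fixtures(grid, f4, "overflow-bogus", seed = 7)
  v4 <- crosscheck(parse_input_file(f4))
  expect_true(all(v4$lambda_status == "REJECTED"))
})

test_that("the command-line tool runs end to end", {
  script <- system.file("exec", "ncfcheck", package = "ncfcheck")
  if (!nzchar(script))
    script <- file.path(find.package("ncfcheck"), "exec", "ncfcheck")
  expect_true(file.exists(script))
  tf <- withr::local_tempfile()
  writeLines(c("# two records", "0.5 1 0.05 0.10 0.9025 46.1803"), tf)
  out <- suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"), c(shQuote(script), "crosscheck",
                                           shQuote(tf)),
    stdout = TRUE, stderr = FALSE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0L)
  expect_match(out[1], "^id\t")
  expect_match(out[2], "VERIFIED")
})
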
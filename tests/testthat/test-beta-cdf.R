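test_that("central beta cdf reproduces closed-form and reference values", {
  expect_encloses(central_beta_cdf(0.95, 1, 1), 0.95)   # I_x(1,1) = x
  r <- central_beta_cdf(0.776393, 1, 2)
  expect_encloses(r, CBETA_REF$value[1], slack = 1e-13)
  expect_lt(abs(mid(r) - 0.95), 1e-6)
  expect_encloses(central_beta_cdf(0.9025, 0.5, 1), 0.95, slack = 1e-13)
  expect_encloses(central_beta_cdf(0.3, 2.5, 7), CBETA_REF$value[2],
                  slack = 1e-13)
})

test_that("central beta cdf encloses an independent implementation", {
  set.seed(11)
  for (rep in 1:200) {
    a <- runif(1, 0.3, 25)
    b <- sample(1:20, 1)
    x <- runif(1)
    r <- central_beta_cdf(x, a, b)
    v <- stats::pbeta(x, a, b)
    expect_encloses(r, v, slack = 1e-12 + 1e-12 * abs(v))
  }
})

test_that("noncentral cdf at lambda = 0 reduces to the central cdf", {
  set.seed(12)
  for (rep in 1:20) {
    a <- runif(1, 0.5, 10); b <- sample(1:30, 1); x <- runif(1)
    nc <- noncentral_beta_cdf(x, a, b, 0)
    ce <- central_beta_cdf(x, a, b)
    ov <- interval_intersect(nc, ce)
    expect_false(is_empty_interval(ov))
    expect_lt(wid(nc), 1e-12)
  }
})

test_that("noncentral beta cdf reproduces frozen high-precision references", {
  for (i in seq_len(nrow(NCBETA_REF))) {
    r <- noncentral_beta_cdf(NCBETA_REF$x[i], NCBETA_REF$a[i],
                             NCBETA_REF$b[i], NCBETA_REF$lambda[i])
    expect_encloses(r, NCBETA_REF$value[i])
    expect_identical(signif(mid(r), 7), signif(NCBETA_REF$value[i], 7))
  }
  # b = 1 closed form e^{-(lambda/2)(1-x)} x^a
  r <- noncentral_beta_cdf(0.9025, 0.5, 1, 46.1803)
  expect_encloses(r, 0.10000021736088574, slack = 1e-14)
  expect_identical(signif(mid(r), 5), 0.1)
})

test_that("noncentral cdf encloses the Poisson-mixture oracle", {
  set.seed(13)
  for (rep in 1:150) {
    a <- runif(1, 0.5, 25)
    b <- sample(1:100, 1)
    x <- runif(1)
    lam <- runif(1, 0, 500)
    r <- noncentral_beta_cdf(x, a, b, lam)
    o <- oracle_ncbeta(x, a, b, lam)
    expect_encloses(r, o$value, slack = o$err)
  }
})

test_that("endpoint identities and monotonicity hold", {
  expect_encloses(noncentral_beta_cdf(0, 2, 3, 10), 0)
  expect_encloses(noncentral_beta_cdf(1, 2, 3, 10), 1)
  expect_encloses(central_beta_cdf(0, 0.5, 4), 0)
  expect_encloses(central_beta_cdf(1, 0.5, 4), 1)
  # increasing in x, decreasing in lambda (via midpoints)
  xs <- seq(0.1, 0.9, by = 0.2)
  mids <- vapply(xs, function(x) mid(noncentral_beta_cdf(x, 3, 7, 20)),
                 numeric(1))
  expect_true(all(diff(mids) > 0))
  lams <- c(0, 5, 20, 80, 320)
  midl <- vapply(lams, function(l) mid(noncentral_beta_cdf(0.6, 3, 7, l)),
                 numeric(1))
  expect_true(all(diff(midl) < 0))
})

test_that("incremental recurrences agree with literal direct evaluation", {
  # direct scheme: explicit powers, factorials and products, double precision
  direct_central <- function(x, a, b) {
    s <- 1
    for (n in seq_len(b - 1)) {
      s <- s + prod((a + seq_len(n) - 1) / seq_len(n)) * (1 - x)^n
    }
    x^a * s
  }
  direct_noncentral <- function(x, a, b, lam) {
    z <- (lam / 2) * (1 - x)
    s <- 0
    for (i in 0:(b - 1))
      s <- s + z^i / factorial(i) * direct_central(x, a + i, b - i)
    exp(-z) * s
  }
  set.seed(14)
  for (rep in 1:50) {
    a <- runif(1, 0.5, 10); b <- sample(1:15, 1)
    x <- runif(1, 0.05, 0.95); lam <- runif(1, 0, 60)
    mc <- mid(central_beta_cdf(x, a, b))
    expect_lt(abs(mc - direct_central(x, a, b)), 1e-12 * max(mc, 1e-3))
    mn <- mid(noncentral_beta_cdf(x, a, b, lam))
    expect_lt(abs(mn - direct_noncentral(x, a, b, lam)),
              1e-12 * max(mn, 1e-3))
  }
})

test_that("evaluation stays finite and valid at the extremes of the range", {
  # large b and lambda: explicit factorials would overflow long before this
  r <- noncentral_beta_cdf(0.0638108, 25, 500, 383)
  expect_true(all(is.finite(unclass(r))))
  expect_true(lower(r) >= 0 && upper(r) <= 1)
  o <- oracle_ncbeta(0.0638108, 25, 500, 383)
  expect_encloses(r, o$value, slack = o$err)
  # the corner that overflows naive methods
  r2 <- noncentral_beta_cdf(0.99795, 25, 1, 2196.78)
  o2 <- oracle_ncbeta(0.99795, 25, 1, 2196.78)
  expect_encloses(r2, o2$value, slack = o2$err)
})

test_that("differentiation variables give consistent value enclosures", {
  x <- 0.62; a <- 3.5; b <- 9; lam <- 33
  plain <- noncentral_beta_cdf(x, a, b, lam)
  via_x <- noncentral_beta_cdf(dint_variable(interval(x)), a, b, lam)
  via_l <- noncentral_beta_cdf(x, a, b, dint_variable(interval(lam)))
  for (d in list(via_x, via_l)) {
    ov <- interval_intersect(dint_val(d), plain)
    expect_false(is_empty_interval(ov))
  }
  # derivative signs: increasing in x, decreasing in lambda
  expect_gt(lower(dint_der(via_x)), 0)
  expect_lt(upper(dint_der(via_l)), 0)
  expect_error(noncentral_beta_cdf(dint_variable(interval(x)), a, b,
                                   dint_variable(interval(lam))),
               "only one")
})

test_that("F to beta mapping enforces even denominator degrees of freedom", {
  m <- f_to_beta(10, 10, 1)
  expect_identical(c(m$a, m$b), c(5, 5))
  expect_encloses(m$x, 0.5)
  m2 <- f_to_beta(1, 2, 0)
  expect_identical(c(m2$a, m2$b), c(0.5, 1))
  expect_encloses(m2$x, 0)
  expect_error(f_to_beta(10, 7, 1), class = "ncfcheck_odd_nu2")

  # composition agrees with the central F cdf at lambda = 0
  set.seed(15)
  for (rep in 1:20) {
    nu1 <- sample(1:30, 1); nu2 <- 2 * sample(1:25, 1)
    w <- runif(1, 0, 5)
    r <- noncentral_f_cdf(w, nu1, nu2, 0)
    v <- stats::pf(w, nu1, nu2)
    expect_encloses(r, v, slack = 1e-12 + 1e-12 * abs(v))
  }
  expect_encloses(noncentral_f_cdf(0, 3, 4, 12), 0)
})

test_that("parameter and domain violations are rejected", {
  expect_error(central_beta_cdf(0.5, 1, 2.5), "positive integer")
  expect_error(central_beta_cdf(0.5, 1, 0), "positive integer")
  expect_error(central_beta_cdf(1.5, 1, 2), "within")
  expect_error(noncentral_beta_cdf(0.5, 1, 2, -1), "non-negative")
  expect_error(central_beta_cdf(0.5, -1, 2), "positive real")
})
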
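test_that("exact endpoint arithmetic stays exact", {
  expect_identical(unclass(interval(1, 2) + interval(3, 4)), c(4, 6))
  expect_identical(unclass(interval(-1, 2) * interval(3, 4)), c(-4, 8))
  expect_identical(unclass(interval(1, 2) - interval(0.5)), c(0.5, 1.5))
  expect_identical(unclass(interval(1, 3) / interval(2)), c(0.5, 1.5))
})

test_that("inexact arithmetic rounds outward and encloses the real result", {
  s <- interval(0.1) + interval(0.2)
  expect_true(wid(s) > 0)
  expect_true(in_interval(0.3, s))          # the real number 3/10
  expect_true(wid(s) < 1e-15)

  r <- interval(4, 9)^interval(0.5)
  expect_true(lower(r) <= 2 && upper(r) >= 3)
  expect_true(2 - lower(r) < 1e-14 && upper(r) - 3 < 1e-14)
})

test_that("elementary functions enclose their ranges", {
  e0 <- exp(interval(0))
  expect_true(in_interval(1, e0))
  expect_true(wid(e0) <= 4 * .Machine$double.eps)

  e1 <- exp(interval(0, 1))
  expect_true(lower(e1) <= 1 && upper(e1) >= E_REF)
  expect_true(upper(e1) - E_REF < 1e-14)

  expect_true(in_interval(0, log(interval(1))))
  expect_error(log(interval(0, 1)), "non-positive")
})

test_that("metrics follow their definitions", {
  x <- interval(1, 3)
  expect_identical(c(mid(x), wid(x), rad(x), mag(x), mig(x)),
                   c(2, 2, 1, 3, 1))
  expect_identical(c(mag(interval(-4, 2)), mig(interval(-4, 2))), c(4, 0))
  expect_identical(c(mag(interval(-4, -1)), mig(interval(-4, -1))), c(4, 1))
  expect_true(in_interval(mid(interval(0.1, 0.3)), interval(0.1, 0.3)))
  expect_error(mid(interval(0, Inf)), "unbounded")
  expect_error(wid(empty_interval()), "empty")
})

test_that("set operations are exact, interior test is strict", {
  expect_identical(unclass(interval_intersect(interval(1, 3), interval(2, 5))),
                   c(2, 3))
  expect_true(is_empty_interval(interval_intersect(interval(1, 2),
                                                   interval(3, 4))))
  expect_identical(unclass(interval_hull(interval(1, 2), interval(4, 5))),
                   c(1, 5))
  expect_true(interior_subset(interval(1.4, 1.5), interval(1, 2)))
  expect_false(interior_subset(interval(1, 1.5), interval(1, 2)))
  expect_true(in_interval(1, interval(1, 2)))
  expect_false(in_interval(0.999, interval(1, 2)))
})

test_that("the empty interval propagates and domain errors are raised", {
  expect_true(is_empty_interval(empty_interval() + interval(1)))
  expect_true(is_empty_interval(empty_interval() * empty_interval()))
  expect_error(interval(1, 2) / interval(-1, 1), "containing zero")
  expect_error(interval(-2, -1)^interval(0.5), "non-negative base")
  expect_error(interval(1, 2)^interval(-1, 1), "exponent")
})

test_that("overflow widens to infinity instead of wrapping", {
  big <- interval(1e308)
  r <- big + big
  expect_identical(upper(r), Inf)
  expect_true(lower(r) <= 1.7976931348623157e308)
  r2 <- big * big
  expect_identical(upper(r2), Inf)
})

test_that("integer powers use the parity rule", {
  expect_identical(unclass(interval(-2, 3)^interval(2)), c(0, 9))
  expect_identical(unclass(interval(-2, 3)^interval(3)), c(-8, 27))
  expect_identical(unclass(interval(-3, -2)^interval(2)), c(4, 9))
  expect_identical(unclass(interval(0, 2)^interval(0)), c(1, 1))
})

test_that("epsilon inflation strictly contains its input", {
  for (x in list(interval(1), interval(0), interval(-3.5, -3.4),
                 interval(1e-300))) {
    y <- epsilon_inflate(x, 1e-6)
    expect_true(interior_subset(x, y))
  }
})

test_that("sampled real results lie inside interval results (containment)", {
  set.seed(42)
  ops <- list(`+`, `-`, `*`)
  for (rep in 1:200) {
    x <- rand_interval(); y <- rand_interval()
    op_i <- sample.int(3L, 1L)
    r <- ops[[op_i]](x, y)
    u <- runif(5, lower(x), upper(x)); v <- runif(5, lower(y), upper(y))
    w <- ops[[op_i]](u, v)
    slack <- 4e-16 * pmax(abs(w), 1)
    expect_true(all(lower(r) - slack <= w & w <= upper(r) + slack))
  }
})

test_that("interval operations are inclusion isotone", {
  set.seed(43)
  shrink <- function(x) {
    p <- sort(runif(2, lower(x), upper(x)))
    interval(p[1], p[2])
  }
  ops <- list(`+`, `-`, `*`)
  for (rep in 1:200) {
    x <- rand_interval(); y <- rand_interval()
    xs <- shrink(x); ys <- shrink(y)
    for (op in ops) {
      big <- op(x, y); small <- op(xs, ys)
      expect_true(lower(big) <= lower(small) && upper(small) <= upper(big))
    }
  }
})

test_that("multiplication is subdistributive over addition", {
  set.seed(44)
  for (rep in 1:200) {
    x <- rand_interval(); y <- rand_interval(); z <- rand_interval()
    lhs <- x * (y + z)
    rhs <- x * y + x * z
    expect_true(lower(rhs) <= lower(lhs) && upper(lhs) <= upper(rhs))
  }
})
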
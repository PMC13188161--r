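test_that("continuous Hill hits its anchor points and stays monotone", {
  p <- continuous_hill_params(a = 0.3, b = 2, c = 40, g = 1.7)
  expect_equal(hill_continuous(0, p), p$a)
  expect_equal(hill_continuous(p$c, p), p$a + p$b / 2)
  expect_equal(hill_continuous(3, list(a = 0, b = 1, c = 1, g = 2)), 0.9)
  expect_equal(hill_continuous(1e12, p), p$a + p$b, tolerance = 1e-6)

  doses <- c(0, 10^seq(-2, 6, length.out = 200))
  y <- hill_continuous(doses, p)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= p$a & y <= p$a + p$b))
  # decreasing when b < 0, bounded by [a + b, a]
  pn <- continuous_hill_params(a = 1, b = -0.8, c = 10, g = 1)
  yn <- hill_continuous(doses, pn)
  expect_true(all(diff(yn) < 0))
  expect_true(all(yn <= pn$a & yn >= pn$a + pn$b))
})

test_that("continuous Hill rejects invalid inputs", {
  expect_error(continuous_hill_params(0, 1, c = -1, g = 1), "c")
  expect_error(continuous_hill_params(0, 1, c = 1, g = 0), "g")
  expect_error(hill_continuous(-1, list(a = 0, b = 1, c = 1, g = 1)), "dose")
  expect_error(hill_continuous(1, list(a = 0, b = 1, c = -2, g = 1)))
})

test_that("dichotomous Hill satisfies the stated parameter semantics", {
  p <- dichotomous_hill_params(v = 0.8, q = 0.1, h = 1, r = 2)
  # background limit vq, maximum v, midpoint v(1+q)/2 at M = h
  expect_equal(hill_dichotomous(-50, p), p$v * p$q, tolerance = 1e-12)
  expect_equal(hill_dichotomous(50, p), p$v, tolerance = 1e-12)
  expect_equal(hill_dichotomous(p$h, p), p$v * (1 + p$q) / 2)
  expect_equal(
    hill_dichotomous(0, dichotomous_hill_params(1, 0, 0, 1)), 0.5)

  M <- seq(-6, 8, length.out = 300)
  y <- hill_dichotomous(M, p)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= p$v * p$q & y <= p$v))
  expect_true(all(y >= 0 & y <= 1))
  # decreasing when r < 0
  pd <- dichotomous_hill_params(v = 0.8, q = 0.1, h = 1, r = -2)
  expect_true(all(diff(hill_dichotomous(M, pd)) < 0))
})

test_that("printed orientation reverses the role of the bounds", {
  p <- dichotomous_hill_params(v = 0.7, q = 0.2, h = 0.5, r = 1.5)
  lo <- hill_dichotomous(-60, p, orientation = "printed")
  hi <- hill_dichotomous(60, p, orientation = "printed")
  expect_equal(lo, p$v, tolerance = 1e-12)
  expect_equal(hi, p$v * p$q, tolerance = 1e-12)
})

test_that("dichotomous Hill rejects out-of-domain parameters", {
  expect_error(dichotomous_hill_params(v = 0, q = 0.1, h = 0, r = 1), "v")
  expect_error(dichotomous_hill_params(v = 0.5, q = 1, h = 0, r = 1), "q")
  expect_error(hill_dichotomous(0, list(v = 1.2, q = 0, h = 0, r = 1)))
})
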
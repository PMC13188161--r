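test_that("PSIS-LOO and WAIC match the frozen reference implementation", {
  # expected values computed once with Python arviz.psislw + scipy
  # logsumexp (PSIS-LOO) and numpy (WAIC, sample-variance penalty) on this
  # exact seeded matrix
  withr::with_seed(123, {
    ll <- matrix(stats::rnorm(500 * 20, mean = -2, sd = 1.3), 500, 20)
  })
  lo <- suppressWarnings(psis_loo(ll))
  expect_equal(lo$estimate, -56.6376533435, tolerance = 1e-6)
  expect_equal(lo$p_eff, 33.4717847539, tolerance = 1e-6)
  expect_equal(lo$se, 0.3748104192, tolerance = 1e-6)
  expect_equal(lo$pareto_k[1:5],
               c(0.4094001748, 0.2601569663, 0.3633063772,
                 0.4726713059, 0.4727770784), tolerance = 1e-6)
  expect_equal(max(lo$pareto_k), 0.7253375171, tolerance = 1e-6)
  wa <- waic(ll)
  expect_equal(wa$estimate, -56.8864485689, tolerance = 1e-6)
  expect_equal(wa$p_eff, 33.7205799793, tolerance = 1e-6)
  expect_equal(wa$se, 0.3931932376, tolerance = 1e-6)
})

test_that("point-mass posteriors give zero penalty and equal elpds", {
  ll_row <- c(-1.3, -0.2, -2.5, -0.9)
  ll <- matrix(rep(ll_row, each = 200), 200, 4)
  wa <- waic(ll)
  expect_equal(wa$estimate, sum(ll_row))
  expect_equal(wa$p_eff, 0)
  lo <- suppressWarnings(psis_loo(ll))
  expect_equal(lo$estimate, sum(ll_row))
  expect_equal(lo$estimate, wa$estimate)
})

test_that("duplicating every observation doubles the elpd", {
  withr::with_seed(5, ll <- matrix(stats::rnorm(300 * 6, -1, 0.4), 300, 6))
  expect_equal(waic(cbind(ll, ll))$estimate, 2 * waic(ll)$estimate)
})

test_that("PSIS-LOO tracks exact leave-one-out on a conjugate model", {
  # normal mean with known variance 1, prior N(0, 10^2), n = 8:
  # both the posterior and every leave-one-out predictive are exact
  withr::with_seed(21, {
    y <- stats::rnorm(8, 1.2, 1)
    tau2 <- 100
    post_var <- 1 / (1 / tau2 + length(y))
    post_mean <- post_var * sum(y)
    draws <- stats::rnorm(4000, post_mean, sqrt(post_var))
    ll <- vapply(y, function(yi) {
      stats::dnorm(yi, draws, 1, log = TRUE)
    }, numeric(length(draws)))
    lo <- suppressWarnings(psis_loo(ll))
    exact <- sum(vapply(seq_along(y), function(i) {
      v_i <- 1 / (1 / tau2 + length(y) - 1)
      m_i <- v_i * sum(y[-i])
      stats::dnorm(y[i], m_i, sqrt(1 + v_i), log = TRUE)
    }, numeric(1)))
    expect_lt(abs(lo$estimate - exact), 2 * lo$se)
    # in-sample lpd exceeds the LOO estimate (LOO penalizes)
    lpd <- sum(apply(ll, 2, function(x) {
      m <- max(x); m + log(mean(exp(x - m)))
    }))
    expect_lt(lo$estimate, lpd)
    # WAIC agrees with LOO within combined SE on this well-behaved model
    wa <- waic(ll)
    expect_lt(abs(wa$estimate - lo$estimate), wa$se + lo$se)
  })
})

test_that("comparison sign convention and paired SE are honored", {
  withr::with_seed(9, {
    ll_f <- matrix(stats::rnorm(400 * 10, -2, 0.5), 400, 10)
    ll_h <- ll_f + matrix(stats::rnorm(400 * 10, 0.3, 0.1), 400, 10)
  })
  cmp <- suppressWarnings(compare_models(ll_f, ll_h))
  tab <- cmp$table
  lo_f <- suppressWarnings(psis_loo(ll_f))
  lo_h <- suppressWarnings(psis_loo(ll_h))
  expect_equal(tab$diff[tab$method == "loo"],
               lo_h$estimate - lo_f$estimate)
  dp <- lo_h$pointwise - lo_f$pointwise
  expect_equal(tab$diff_se[tab$method == "loo"],
               sqrt(length(dp) * stats::var(dp)))
  expect_identical(tab$preferred[tab$method == "loo"], "hierarchical")

  # a model compared with itself: diff 0, SE 0
  self <- suppressWarnings(compare_models(ll_f, ll_f))
  expect_equal(self$table$diff, c(0, 0))
  expect_equal(self$table$diff_se, c(0, 0))

  expect_error(suppressWarnings(compare_models(ll_f, ll_h[, 1:5])),
               "observation")
})

test_that("non-finite entries are rejected with the offending observation", {
  ll <- matrix(stats::rnorm(400), 100, 4)
  ll[3, 3] <- -Inf
  expect_error(waic(ll), "3")
  expect_error(psis_loo(ll), "3")
  expect_error(waic(ll[1:50, ]), "draws")
  expect_error(waic(matrix(stats::rnorm(200), 200, 1)), "observations")
})
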
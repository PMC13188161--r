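test_that("summary-to-log transform matches lognormal moments and inverts", {
  expect_equal(unlist(transform_summary_to_log(1, 0)),
               c(log_mean = 0, log_sd = 0))
  tr <- transform_summary_to_log(1, 1)
  expect_equal(tr$log_mean, -0.5 * log(2), tolerance = 1e-10)
  expect_equal(tr$log_sd, sqrt(log(2)), tolerance = 1e-10)
  # numeric anchors from evaluating the moment-matching formulas
  expect_equal(tr$log_mean, -0.34657359, tolerance = 1e-7)
  expect_equal(tr$log_sd, 0.83255461, tolerance = 1e-7)

  # sampling check: the transform reproduces natural-scale moments
  withr::with_seed(11, {
    y <- stats::rlnorm(4e5, tr$log_mean, tr$log_sd)
    expect_equal(mean(y), 1, tolerance = 0.02)
    expect_equal(stats::sd(y), 1, tolerance = 0.03)
  })

  # algebraic round trip on a random grid
  withr::with_seed(2, {
    mn <- stats::runif(50, 0.01, 50)
    sd <- stats::runif(50, 0, 20)
    tr <- transform_summary_to_log(mn, sd)
    back <- transform_log_to_summary(tr$log_mean, tr$log_sd)
    expect_equal(back$mean_natural, mn, tolerance = 1e-10)
    expect_equal(back$sd_natural, sd, tolerance = 1e-10)
  })
  expect_error(transform_summary_to_log(0, 1), "mean")
})

test_that("summarized upstream log-likelihood equals per-individual sums", {
  g1 <- tibble::tibble(log_mean = 0, log_sd = 0, n = 1)
  expect_equal(loglik_ke_up(g1, M = 0, sigma1 = 1), -0.5 * log(2 * pi))
  expect_equal(loglik_ke_up(g1, M = 0, sigma1 = 1), -0.91893853,
               tolerance = 1e-7)

  # brute-force oracle: sum of normal log densities of the individuals
  withr::with_seed(33, {
    for (rep in 1:50) {
      n <- sample(2:12, 1)
      M <- stats::rnorm(1)
      sigma1 <- stats::runif(1, 0.2, 2)
      ylog <- stats::rnorm(n, M, sigma1)
      groups <- tibble::tibble(log_mean = mean(ylog),
                               log_sd = stats::sd(ylog), n = n)
      oracle <- sum(stats::dnorm(ylog, M, sigma1, log = TRUE))
      expect_equal(loglik_ke_up(groups, M, sigma1), oracle,
                   tolerance = 1e-8)
    }
  })

  # additivity: two identical groups double the single-group value
  g <- tibble::tibble(log_mean = 0.4, log_sd = 0.3, n = 5)
  one <- loglik_ke_up(g, M = 0.2, sigma1 = 0.5)
  two <- loglik_ke_up(dplyr::bind_rows(g, g), M = c(0.2, 0.2), sigma1 = 0.5)
  expect_equal(two, 2 * one)

  expect_error(loglik_ke_up(g, M = 0.2, sigma1 = 0), "sigma1")
  expect_error(
    loglik_ke_up(tibble::tibble(log_mean = 0, log_sd = 0, n = 0), 0, 1),
    "n")
})

test_that("downstream log-likelihood equals Bernoulli sums", {
  p_eq <- function(p) {
    # parameters engineered to give probability p at M = 0
    dichotomous_hill_params(v = 2 * p, q = 0, h = 0, r = 1)
  }
  expect_equal(loglik_ke_down(0, 10, 0, p_eq(0.2)), 10 * log(0.8))
  expect_equal(loglik_ke_down(4, 4, 0, p_eq(0.5)), 4 * log(0.5))

  withr::with_seed(7, {
    th <- random_theta2(10)
    for (i in 1:10) {
      pars <- dichotomous_hill_params(th$v[i], th$q[i], th$h[i], th$r[i])
      M <- stats::rnorm(1)
      p <- hill_dichotomous(M, pars)
      x <- 3; n2 <- 7
      oracle <- sum(stats::dbinom(c(rep(1, x), rep(0, n2 - x)), 1, p,
                                  log = TRUE))
      expect_equal(loglik_ke_down(x, n2, M, pars), oracle,
                   tolerance = 1e-10)
    }
  })

  # boundary: pinned probability contradicting counts is -Inf, flagged
  pin <- dichotomous_hill_params(v = 1, q = 0, h = 0, r = 1)
  expect_warning(ll <- loglik_ke_down(3, 5, 1000, pin), "pinned")
  expect_identical(ll, -Inf)
  expect_error(loglik_ke_down(6, 5, 0, pin), "cases")
})
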
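test_that("closed-form extra-risk inversion matches a bisection oracle", {
  expect_equal(invert_extra_risk(dichotomous_hill_params(1, 0, 0, 1),
                                 bmr = 0.5), 1)
  th <- random_theta2(200, seed = 17)
  for (i in seq_len(nrow(th))) {
    pars <- dichotomous_hill_params(th$v[i], th$q[i], th$h[i], th$r[i])
    L <- invert_extra_risk(pars, bmr = 0.05)
    p0 <- pars$v * pars$q
    extra <- function(logL) {
      (hill_dichotomous(logL, pars) - p0) / (1 - p0) - 0.05
    }
    root <- stats::uniroot(extra, c(pars$h - 60 / pars$r,
                                    pars$h + 60 / pars$r),
                           tol = 1e-13)$root
    expect_equal(log(L), root, tolerance = 1e-10)
  }
})

test_that("inversion is monotone in the benchmark response", {
  pars <- dichotomous_hill_params(0.8, 0.1, 1.2, 2)
  bmrs <- seq(0.01, 0.6, by = 0.01)
  L <- vapply(bmrs, function(b) invert_extra_risk(pars, b), numeric(1))
  expect_true(all(diff(L) > 0))
  # small bmr approaches the background (L -> 0)
  expect_lt(invert_extra_risk(pars, 1e-8), 1e-3)
})

test_that("unattainable benchmark responses are refused", {
  pars <- dichotomous_hill_params(0.3, 0.1, 0, 1)
  max_extra <- (0.3 - 0.03) / (1 - 0.03)
  expect_error(invert_extra_risk(pars, bmr = max_extra + 0.01),
               "unattainable")
  expect_error(invert_extra_risk(dichotomous_hill_params(1, 0, 0, -1),
                                 0.05), "r > 0")
  expect_error(invert_extra_risk(pars, bmr = 0), "bmr")
})

test_that("posterior BML summaries behave on degenerate draws", {
  draws <- tibble::tibble(v = rep(0.8, 500), q = 0.05, h = 1, r = 2)
  res <- posterior_bml(draws, bmr = 0.05)
  expect_equal(res$natural[["BML"]], res$natural[["BMLL"]])
  expect_equal(res$natural[["BML"]], res$natural[["BMLU"]])
  expect_equal(res$natural[["ratio"]], 1)
  truth <- invert_extra_risk(dichotomous_hill_params(0.8, 0.05, 1, 2), 0.05)
  expect_equal(res$natural[["BML"]], truth)
  # log-scale draws equal the log of natural draws, draw by draw
  expect_equal(res$draws$log_bml, log(res$draws$bml))
})

test_that("posterior BML covers the truth on stochastic draws", {
  withr::with_seed(23, {
    n <- 4000
    draws <- tibble::tibble(
      v = stats::plogis(stats::rnorm(n, stats::qlogis(0.7), 0.2)),
      q = stats::plogis(stats::rnorm(n, stats::qlogis(0.08), 0.3)),
      h = stats::rnorm(n, 1, 0.15),
      r = exp(stats::rnorm(n, log(2), 0.1))
    )
  })
  res <- posterior_bml(draws, bmr = bmr_spec(0.05))
  truth <- invert_extra_risk(dichotomous_hill_params(0.7, 0.08, 1, 2), 0.05)
  expect_gt(truth, res$natural[["BMLL"]])
  expect_lt(truth, res$natural[["BMLU"]])
  expect_gte(res$natural[["ratio"]], 1)
  expect_true(res$natural[["BMLL"]] <= res$natural[["BML"]])
  expect_true(res$natural[["BML"]] <= res$natural[["BMLU"]])
  td <- tidy(res)
  expect_identical(td$scale, c("natural", "log"))

  # mostly-unattainable draws fail loudly
  bad <- tibble::tibble(v = rep(0.06, 500), q = 0.5, h = 0, r = 1)
  expect_error(posterior_bml(bad, bmr = 0.05), "unattainable")
})

test_that("reliability check applies the 1-3 ratio rule", {
  mk <- function(ratio) {
    structure(list(natural = c(BML = ratio, BMLL = 1, BMLU = ratio + 1,
                               ratio = ratio)),
              class = "bml_result")
  }
  expect_true(reliability_check(mk(1.12))$reliable)
  expect_true(reliability_check(mk(1))$reliable)
  expect_false(reliability_check(mk(3.5))$reliable)
  cmp <- reliability_check(mk(1.12), mk(1.91))
  expect_identical(cmp$preferred, "first")
})
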
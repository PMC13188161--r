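test_that("seeded fits are exactly reproducible", {
  ds <- tiny_dataset(41)
  model <- build_qaop_model(ds, "flat")
  mc <- fast_mcmc(seed = 5, warmup = 200, sampling = 200)
  f1 <- quiet_fit(model, mc)
  f2 <- quiet_fit(model, mc)
  expect_identical(f1$unconstrained, f2$unconstrained)
  expect_identical(f1$draws, f2$draws)
  # a different seed moves the draws
  f3 <- quiet_fit(model, fast_mcmc(seed = 6, warmup = 200, sampling = 200))
  expect_false(identical(f1$unconstrained, f3$unconstrained))
})

test_that("initialization failures are reported, not sampled through", {
  ds <- tiny_dataset(42)
  model <- build_qaop_model(ds, "flat")
  bad <- rep(NaN, model$n_par)
  expect_error(fit_qaop(model, fast_mcmc(), init = list(bad, bad)),
               "initialization")
})

test_that("with the likelihood muted the posterior reproduces the prior", {
  ds <- tiny_dataset(43)
  model <- build_qaop_model(ds, "flat")
  model$spec$has_up[] <- 0L
  model$spec$has_down[] <- 0L
  fit <- quiet_fit(model, fast_mcmc(seed = 2, warmup = 500, sampling = 2500))
  v <- fit$draws$v
  # v ~ beta(2, 2) a priori: compare quantiles within Monte-Carlo error
  expect_equal(mean(v), 0.5, tolerance = 0.04)
  expect_equal(unname(stats::quantile(v, c(0.25, 0.75))),
               stats::qbeta(c(0.25, 0.75), 2, 2), tolerance = 0.06)
  # r ~ normal(0, 2) a priori
  expect_equal(mean(fit$draws$r), 0, tolerance = 0.25)
  expect_equal(stats::sd(fit$draws$r), 2, tolerance = 0.3)
  # sigma2 ~ half-Cauchy(0, 1) a priori: median 1, lower quartile tan(pi/8)
  expect_equal(unname(stats::quantile(fit$draws$sigma2, 0.5)), 1,
               tolerance = 0.15)
  expect_equal(unname(stats::quantile(fit$draws$sigma2, 0.25)),
               tan(pi / 8), tolerance = 0.15)
})

test_that("pointwise log-likelihood matches re-evaluation at single draws", {
  ds <- tiny_dataset(44)
  model <- build_qaop_model(ds, "hierarchical")
  fit <- quiet_fit(model, fast_mcmc(seed = 3, warmup = 300, sampling = 300))
  ll <- extract_pointwise_loglik(fit)
  expect_identical(dim(ll), c(nrow(fit$draws), model$spec$J))

  sp <- model$spec
  chem <- model$chemicals
  ki <- sp$chem + 1L
  d <- fit$draws
  withr::with_seed(1, idx <- sample(nrow(d), 5))
  for (s in idx) {
    for (j in seq_len(sp$J)) {
      M <- d[[paste0("M[", j, "]")]][s]
      expected <- 0
      if (sp$has_up[j] == 1) {
        s1 <- d[[paste0("sigma1[", chem[ki[j]], "]")]][s]
        expected <- expected + loglik_ke_up(
          tibble::tibble(log_mean = sp$m[j], log_sd = sp$s[j], n = sp$n1[j]),
          M, s1)
      }
      if (sp$has_down[j] == 1) {
        pars <- dichotomous_hill_params(
          d[[paste0("v[", chem[ki[j]], "]")]][s],
          d[[paste0("q[", chem[ki[j]], "]")]][s],
          d[[paste0("h[", chem[ki[j]], "]")]][s],
          d$r[s])
        expected <- expected + loglik_ke_down(sp$X[j], sp$n2[j], M, pars)
      }
      expect_equal(ll[s, j], expected, tolerance = 1e-8)
    }
  }
  # column sums reproduce each draw's total likelihood contribution
  split_ll <- extract_pointwise_loglik(fit, unit = "split")
  expect_equal(rowSums(split_ll), rowSums(ll), tolerance = 1e-8)
})

test_that("prior predictive spans the incidence range inside [0, 1]", {
  ds <- tiny_dataset(45)
  model <- build_qaop_model(ds, "flat")
  pp <- prior_predictive(model, n_draws = 100, seed = 7)
  expect_true(all(pp$incidence >= 0 & pp$incidence <= 1))
  expect_gt(max(pp$incidence), 0.7)
  expect_lt(min(pp$incidence), 0.3)
  expect_true(all(is.finite(pp$ke_up_mean)))
  # identical seeds reproduce the simulation
  pp2 <- prior_predictive(model, n_draws = 100, seed = 7)
  expect_identical(pp, pp2)
})

test_that("non-centered prior draws reproduce the random-effect moments", {
  # additive-scale variant: v_k = mu_v + sigma_v * z with z ~ N(0, 1)
  withr::with_seed(31, {
    mu_v <- 0.6; sigma_v <- 0.05
    z <- stats::rnorm(20000)
    v_k <- mu_v + sigma_v * z
    expect_equal(mean(v_k), mu_v, tolerance = 0.005)
    expect_equal(stats::sd(v_k), sigma_v, tolerance = 0.005)
  })
  cfg <- sim_config(K = 200, G = 3, n_up = 4, n_down = 20,
                    sigma_v = 0.05, sigma_q = 0.01, sigma_h = 0.2,
                    re_factor = 1)
  ds <- generate_qaop_data(cfg, seed = 19)
  th <- attr(ds, "truth")$theta2
  expect_equal(mean(th$v), cfg$mu_v, tolerance = 0.02)
  expect_equal(stats::sd(th$v), cfg$sigma_v, tolerance = 0.02)
  # correlation is attenuated a little by domain truncation
  expect_lt(abs(stats::cor(th$v, th$q) - cfg$rho), 0.15)
  expect_gt(stats::cor(th$v, th$q), 0)
})
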
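test_that("generation is exactly reproducible and internally consistent", {
  cfg <- tiny_config()
  a <- generate_qaop_data(cfg, seed = 8)
  b <- generate_qaop_data(cfg, seed = 8)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "truth")$theta2, attr(b, "truth")$theta2)
  expect_false(identical(as.data.frame(a),
                         as.data.frame(generate_qaop_data(cfg, seed = 9))))
  # summaries are consistent with their generating individuals: at large
  # group size they converge to the lognormal moments of (M_j, sigma1)
  big <- generate_qaop_data(tiny_config(n_up = 4000), seed = 3)
  tr <- attr(big, "truth")
  expected <- transform_log_to_summary(tr$M, tr$config$sigma1)
  expect_equal(big$ke_up_mean, expected$mean_natural, tolerance = 0.05)
  expect_equal(big$ke_up_sd, expected$sd_natural, tolerance = 0.1)
})

test_that("zero random-effect scales collapse to one shared curve", {
  cfg <- sim_config(re_factor = 0)
  ds <- generate_qaop_data(cfg, seed = 14)
  th <- attr(ds, "truth")$theta2
  expect_equal(stats::sd(th$v), 0)
  expect_equal(stats::sd(th$q), 0)
  expect_equal(stats::sd(th$h), 0)
  expect_lt(attr(ds, "truth")$achieved_f, 0.1)
})

test_that("achieved f is monotone in the random-effect factor", {
  fs <- vapply(c(0, 1, 4), function(fac) {
    mean(vapply(1:6, function(s) {
      attr(generate_qaop_data(sim_config(re_factor = fac), seed = s),
           "truth")$achieved_f
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("heterogeneity tuning reaches its target within tolerance", {
  tuned <- tune_heterogeneity(sim_config(), target_f = 0.2,
                              tolerance = 0.02, seed = 5, batch = 8)
  expect_lte(abs(attr(tuned, "achieved_f") - 0.2), 0.02)
  expect_gt(tuned$re_factor, 0)
  tr <- attr(tuned, "trace")
  expect_true(nrow(tr) >= 2)
  # the 'none' target is met near zero scales
  low <- tune_heterogeneity(sim_config(), target_f = "none",
                            tolerance = 0.02, seed = 5, batch = 8)
  expect_lte(abs(attr(low, "achieved_f") - 0.05), 0.02)
  # absurd targets fail loudly
  expect_error(tune_heterogeneity(sim_config(), target_f = 40,
                                  seed = 5, batch = 2, max_factor = 2),
               "unattainable")
})

test_that("out-of-domain random-effect draws are resampled then rejected", {
  cfg <- sim_config(sigma_v = 1e6, re_factor = 1)
  expect_error(generate_qaop_data(cfg, seed = 2), "domain")
})

test_that("a single-iteration study passes through one comparison", {
  st <- run_simulation_study(levels = "large", iterations = 1,
                             mcmc = fast_mcmc(seed = 4, warmup = 300,
                                              sampling = 400),
                             config = tiny_config(), seed = 11,
                             exclude_failed = FALSE)
  expect_identical(nrow(st$per_iteration), 1L)
  expect_true(all(c("loo_diff", "waic_diff", "loo_prefers_hier") %in%
                    names(st$per_iteration)))
  expect_identical(nrow(st$aggregate), 1L)
  expect_true(st$aggregate$prop_hier_loo %in% c(0, 1))
})
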
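test_that("hand-computable effect sizes are reproduced", {
  toy <- tibble::tibble(chemical_id = c("A", "A", "B", "B"),
                        y = c(0, 1, 2, 3))
  es <- cohens_f(toy, response = "y", adjust = "none")
  expect_equal(es$SSB, 4)
  expect_equal(es$SST, 5)
  expect_equal(es$f2, 4)
  expect_equal(es$f, 2)
  expect_identical(es$level, "large")

  # equal chemical means: SSB = 0, f = 0
  flat <- tibble::tibble(chemical_id = rep(c("A", "B"), each = 3),
                         y = rep(c(1, 2, 3), 2))
  expect_equal(cohens_f(flat, response = "y", adjust = "none")$f, 0)
})

test_that("f is affine-invariant and matches one-way ANOVA", {
  withr::with_seed(12, {
    d <- tibble::tibble(
      chemical_id = rep(letters[1:4], each = 6),
      y = stats::rnorm(24, rep(c(0, 0.5, 1, 2), each = 6), 1)
    )
    f0 <- cohens_f(d, response = "y", adjust = "none")$f
    d2 <- dplyr::mutate(d, y = 3.7 * .data$y - 11)
    expect_equal(cohens_f(d2, response = "y", adjust = "none")$f, f0,
                 tolerance = 1e-12)
    # textbook one-way ANOVA oracle
    fit <- stats::aov(y ~ chemical_id, data = d)
    ss <- summary(fit)[[1]][["Sum Sq"]]
    expect_equal(f0, sqrt(ss[1] / ss[2]), tolerance = 1e-12)
  })
})

test_that("a chemical sitting at the global mean cannot raise f", {
  withr::with_seed(30, {
    d <- tibble::tibble(
      chemical_id = rep(c("A", "B"), each = 5),
      y = stats::rnorm(10, rep(c(-1, 1), each = 5), 0.5)
    )
    f0 <- cohens_f(d, response = "y", adjust = "none")
    mu <- f0$global_mean
    d3 <- dplyr::bind_rows(d, tibble::tibble(chemical_id = "C",
                                             y = rep(mu, 5)))
    f1 <- cohens_f(d3, response = "y", adjust = "none")
    expect_equal(f1$SSB, f0$SSB, tolerance = 1e-9)
    expect_lte(f1$f, f0$f + 1e-9)
  })
})

test_that("degenerate within-variance flags infinite f instead of crashing", {
  d <- tibble::tibble(chemical_id = rep(c("A", "B"), each = 2),
                      y = c(1, 1, 2, 2))
  es <- cohens_f(d, response = "y", adjust = "none")
  expect_true(es$infinite)
  expect_identical(es$f, Inf)
})

test_that("classification respects the conventional thresholds", {
  expect_identical(classify_heterogeneity(c(0.05, 0.1, 0.2, 0.5)),
                   c("none", "small", "medium", "large"))
  expect_identical(classify_heterogeneity(0.1999), "small")
  expect_identical(classify_heterogeneity(0.4), "large")
  expect_error(classify_heterogeneity(-0.1), ">= 0")
  expect_identical(heterogeneity_target_f(c("none", "large")), c(0.05, 0.5))
  expect_error(heterogeneity_target_f("huge"), "unknown")
})

test_that("the incidence path uses individual-level sufficient statistics", {
  # two chemicals, one group each, equal proportions: f ~ 0 after the
  # binomial within-group term enters SST
  d <- tibble::tibble(
    chemical_id = c("A", "B"), dose = c(1, 1),
    ke_up_n = 5, ke_up_mean = c(1, 1), ke_up_sd = c(0.1, 0.1),
    ke_down_n = c(20, 20), ke_down_cases = c(5, 10)
  )
  es <- cohens_f(d, adjust = "none")
  # expansion oracle: individual 0/1 outcomes
  y <- c(rep(1, 5), rep(0, 15), rep(1, 10), rep(0, 10))
  g <- rep(c("A", "B"), each = 20)
  fit <- stats::aov(y ~ g)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  expect_equal(es$f, sqrt(ss[1] / ss[2]), tolerance = 1e-9)
})
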
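# independent R-side assembly of the flat model's joint log density,
# mirroring the written-out model: Eq.-style likelihoods + latent normal
# + priors + change-of-variable terms
flat_density_oracle <- function(model, par) {
  sp <- model$spec
  pr <- sp$priors
  K <- sp$K; J <- sp$J
  stopifnot(sp$s1mode == 1)
  i <- 0
  take <- function(n) { out <- par[i + seq_len(n)]; i <<- i + n; out }
  a <- take(K); b <- take(K); lc <- take(K); lg <- take(1)
  ls1 <- take(K); ls2 <- take(1); t <- take(J)
  xi_v <- take(1); xi_q <- take(1); h <- take(1); r <- take(1)
  cc <- exp(lc); g <- exp(lg); s1 <- exp(ls1); s2 <- exp(ls2)
  v <- stats::plogis(xi_v); q <- stats::plogis(xi_q)

  ki <- sp$chem + 1L
  f1 <- vapply(seq_len(J), function(j) {
    hill_continuous(sp$dose[j],
                    list(a = a[ki[j]], b = b[ki[j]], c = cc[ki[j]], g = g))
  }, numeric(1))
  M <- f1 + s2 * t

  lp <- 0
  up <- which(sp$has_up == 1)
  lp <- lp + loglik_ke_up(
    tibble::tibble(log_mean = sp$m[up], log_sd = sp$s[up], n = sp$n1[up]),
    M[up], s1[ki[up]])
  pars2 <- dichotomous_hill_params(v, q, h, r)
  for (j in which(sp$has_down == 1)) {
    lp <- lp + loglik_ke_down(sp$X[j], sp$n2[j], M[j], pars2)
  }
  lp <- lp + sum(stats::dnorm(t, log = TRUE))
  # priors with change-of-variable terms for log- and logit-scale sampling
  lp <- lp + sum(stats::dnorm(a, pr$a0, pr$a_sd, log = TRUE))
  lp <- lp + sum(stats::dnorm(b, pr$b0, pr$b_sd, log = TRUE))
  lp <- lp + sum(stats::dnorm(cc, pr$c0, pr$c_sd, log = TRUE) + lc)
  lp <- lp + stats::dnorm(g, pr$g0, pr$g_sd, log = TRUE) + lg
  half_cauchy <- function(x, scale) log(2 / pi) + log(scale) -
    log(scale^2 + x^2)
  lp <- lp + sum(half_cauchy(s1, pr$scale_sigma1) + ls1)
  lp <- lp + half_cauchy(s2, pr$scale_sigma2) + ls2
  lp <- lp + stats::dbeta(v, pr$v_a, pr$v_b, log = TRUE) +
    log(v) + log(1 - v)
  lp <- lp + stats::dbeta(q, pr$q_a, pr$q_b, log = TRUE) +
    log(q) + log(1 - q)
  lp <- lp + stats::dnorm(h, pr$h_mean, pr$h_sd, log = TRUE)
  lp <- lp + stats::dnorm(r, pr$r_mean, pr$r_sd, log = TRUE)
  lp
}

test_that("flat joint density matches an independently assembled oracle", {
  ds <- tiny_dataset(5)
  model <- build_qaop_model(ds, "flat")
  withr::with_seed(8, {
    for (rep in 1:5) {
      par <- stats::rnorm(model$n_par, 0, 0.5)
      expect_equal(qaop_log_posterior(model, par)$lp,
                   flat_density_oracle(model, par), tolerance = 1e-9)
    }
  })
})

test_that("gradients match finite differences for all model variants", {
  ds <- tiny_dataset(6)
  variants <- list(
    list(structure = "flat", orientation = "corrected"),
    list(structure = "flat", orientation = "printed"),
    list(structure = "hierarchical", orientation = "corrected"),
    list(structure = "hierarchical", orientation = "corrected",
         variance = variance_spec("free_per_group"))
  )
  withr::with_seed(13, {
    for (vt in variants) {
      model <- do.call(build_qaop_model, c(list(ds), vt))
      par <- stats::rnorm(model$n_par, 0, 0.4)
      got <- qaop_log_posterior(model, par, gradient = TRUE)
      num <- vapply(seq_len(model$n_par), function(i) {
        e <- 1e-6
        up <- dn <- par
        up[i] <- up[i] + e; dn[i] <- dn[i] - e
        (qaop_log_posterior(model, up)$lp -
           qaop_log_posterior(model, dn)$lp) / (2 * e)
      }, numeric(1))
      expect_lt(max(abs(got$grad - num) / pmax(1, abs(num))), 1e-5)
    }
  })
})

test_that("degenerate hierarchy reproduces the flat likelihood", {
  ds <- tiny_dataset(7)
  mf <- build_qaop_model(ds, "flat")
  mh <- build_qaop_model(ds, "hierarchical")
  K <- mf$spec$K; J <- mf$spec$J
  withr::with_seed(4, {
    shared <- stats::rnorm(3 * K + 2 + K + J, 0, 0.3)  # theta1 + latents
    v <- 0.7; q <- 0.12; h <- 0.9; r <- 1.8
    par_f <- c(shared, stats::qlogis(v), stats::qlogis(q), h, r)
    # hierarchical: scales ~ 0, z arbitrary -> same per-chemical theta2
    par_h <- c(shared, stats::qlogis(v), stats::qlogis(q),
               log(1e-12), log(1e-12), 0, h, log(1e-12), r,
               stats::rnorm(3 * K))
    ll_f <- qaop_pointwise(matrix(par_f, 1), mf$spec)
    ll_h <- qaop_pointwise(matrix(par_h, 1), mh$spec)
    expect_equal(ll_h, ll_f, tolerance = 1e-9)
  })
})

test_that("rows without downstream data contribute dose-response only", {
  ds <- tiny_dataset(9)
  ds$ke_down_cases[2] <- NA
  ds$ke_down_n[2] <- NA
  model <- build_qaop_model(validate_qaop_data(ds), "flat")
  expect_identical(model$spec$has_down[2], 0L)
  par <- rep(0.1, model$n_par)
  pw <- qaop_pointwise(matrix(par, 1), model$spec)
  # row 2 equals its upstream-only log likelihood
  sp <- model$spec
  i <- 0
  K <- sp$K
  a <- par[1:K]; b <- par[K + 1:K]; cc <- exp(par[2 * K + 1:K])
  g <- exp(par[3 * K + 1]); s1 <- exp(par[3 * K + 1 + 1:K])
  s2 <- exp(par[4 * K + 2]); t <- par[4 * K + 2 + 1:sp$J]
  k2 <- sp$chem[2] + 1L
  M2 <- hill_continuous(sp$dose[2],
                        list(a = a[k2], b = b[k2], c = cc[k2], g = g)) +
    s2 * t[2]
  up_only <- loglik_ke_up(
    tibble::tibble(log_mean = sp$m[2], log_sd = sp$s[2], n = sp$n1[2]),
    M2, s1[k2])
  expect_equal(pw[1, 2], up_only, tolerance = 1e-9)
})

test_that("datasets violating the bridging requirement are rejected", {
  ds <- tiny_dataset(3)
  ds2 <- ds
  ds2$ke_up_mean[ds2$chemical_id == "chem02"] <- NA
  expect_error(validate_qaop_data(ds2), "anchored|upstream")
})
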
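#' MCMC sampler configuration
#'
#' Defaults are a desk-scale schedule (4 chains, 1,000 warmup and 2,000
#' sampling iterations per chain); `full = TRUE` switches to the
#' full-length schedule of 10,000 warmup and 50,000 sampling iterations.
#'
#' @param chains Number of chains (>= 2, required for R-hat).
#' @param warmup,sampling Iterations per chain.
#' @param seed Integer seed; chain `i` uses `seed + i - 1`.
#' @param adapt_delta Target acceptance statistic of the step-size
#'   adaptation.
#' @param max_treedepth Maximum NUTS tree depth.
#' @param thin Thinning interval.
#' @param full Use the full-length schedule?
#' @return A list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(chains = 4, warmup = 1000, sampling = 2000,
                        seed = 1, adapt_delta = 0.9, max_treedepth = 10,
                        thin = 1, full = FALSE) {
  if (full) { warmup <- 10000; sampling <- 50000 }
  if (chains < 2) stop("need >= 2 chains for R-hat", call. = FALSE)
  structure(list(chains = chains, warmup = warmup, sampling = sampling,
                 seed = as.integer(seed), adapt_delta = adapt_delta,
                 max_treedepth = max_treedepth, thin = thin),
            class = "mcmc_config")
}

# default initialization on the unconstrained scale, jittered per chain
default_init <- function(model, jitter = 0.3) {
  sp <- model$spec
  K <- sp$K; J <- sp$J
  pr <- sp$priors
  s1_len <- switch(as.character(sp$s1mode), "0" = 1L, "1" = K, "2" = J)
  base <- c(pr$a0, pr$b0, log(pr$c0), log(pr$g0),
            rep(log(0.5), s1_len), log(0.3), rep(0, J))
  th2 <- if (sp$hierarchical == 1) {
    c(0, stats::qlogis(0.2), log(0.3), log(0.3), 0, 1, log(0.3), 1,
      rep(0, 3 * K))
  } else {
    c(0, stats::qlogis(0.2), 1, 1)
  }
  ini <- c(base, th2)
  ini + stats::runif(length(ini), -jitter, jitter)
}

#' Fit a qAOP model by the built-in NUTS sampler
#'
#' Runs Hamiltonian Monte Carlo with No-U-Turn trajectories, dual-averaging
#' step-size adaptation and windowed diagonal mass-matrix estimation on the
#' model's unconstrained parameterization, then transforms the draws back
#' to the natural scale. Convergence is assessed by split R-hat (< 1.01),
#' effective sample size (> 400) and the post-warmup divergence count; a
#' fit failing the gates is still returned, with `diagnostics$pass =
#' FALSE` and a warning, never silently.
#'
#' Runs are deterministic: the same model, configuration and seed
#' reproduce the draws bit for bit.
#'
#' @param model A `qaop_model` from [build_qaop_model()], or a data frame
#'   (then `...` is passed to [build_qaop_model()]).
#' @param mcmc An [mcmc_config()].
#' @param init Optional list of unconstrained initial vectors, one per
#'   chain.
#' @param ... Passed to [build_qaop_model()] when `model` is a data frame.
#' @return A list of class `"qaop_fit"`: `draws` (tibble of named
#'   constrained draws with `.chain`/`.iteration` columns), `unconstrained`
#'   (matrix), `diagnostics`, `model`, `mcmc`, and sampler metadata.
#' @export
fit_qaop <- function(model, mcmc = mcmc_config(), init = NULL, ...) {
  if (is.data.frame(model)) model <- build_qaop_model(model, ...)
  stopifnot(inherits(model, "qaop_model"), inherits(mcmc, "mcmc_config"))

  P <- model$n_par
  if (is.null(init)) {
    init <- withr::with_seed(mcmc$seed, {
      lapply(seq_len(mcmc$chains), function(i) default_init(model))
    })
  }
  for (i in seq_along(init)) {
    lp0 <- qaop_log_density(init[[i]], model$spec, gradient = FALSE)$lp
    if (!is.finite(lp0)) {
      stop("non-finite log density at initialization of chain ", i,
           "; parameter vector: ",
           paste(signif(init[[i]], 3), collapse = ", "), call. = FALSE)
    }
  }

  runs <- lapply(seq_len(mcmc$chains), function(i) {
    qaop_nuts(model$spec, init[[i]], mcmc$warmup, mcmc$sampling,
              seed = mcmc$seed + i - 1L, adapt_delta = mcmc$adapt_delta,
              max_treedepth = mcmc$max_treedepth, thin = mcmc$thin)
  })

  n_keep <- nrow(runs[[1]]$draws)
  unc <- do.call(rbind, lapply(runs, `[[`, "draws"))
  colnames(unc) <- par_layout(model)
  lp <- unlist(lapply(runs, `[[`, "lp"))
  divergences <- sum(vapply(runs, `[[`, numeric(1), "divergences"))

  constrained <- constrain_draws(model, unc)
  constrained$lp <- lp
  constrained$.chain <- rep(seq_len(mcmc$chains), each = n_keep)
  constrained$.iteration <- rep(seq_len(n_keep), mcmc$chains)

  # diagnostics on the sampled (unconstrained) parameters + lp
  diag_names <- c(colnames(unc), "lp")
  arr <- array(NA_real_, dim = c(n_keep, mcmc$chains, length(diag_names)),
               dimnames = list(NULL, NULL, diag_names))
  for (i in seq_len(mcmc$chains)) {
    rows <- (i - 1) * n_keep + seq_len(n_keep)
    arr[, i, seq_len(ncol(unc))] <- unc[rows, ]
    arr[, i, length(diag_names)] <- lp[rows]
  }
  diagnostics <- compute_diagnostics(arr, divergences)
  if (!diagnostics$pass) {
    warning(sprintf(
      "MCMC gates failed (max R-hat %.3f, min ESS %.0f, %d divergences); ",
      diagnostics$max_rhat, diagnostics$min_ess, divergences),
      "inspect `$diagnostics` before using this fit", call. = FALSE)
  }

  structure(list(
    draws = constrained,
    unconstrained = unc,
    diagnostics = diagnostics,
    model = model,
    mcmc = mcmc,
    step_size = vapply(runs, `[[`, numeric(1), "step_size"),
    n_grad_evals = vapply(runs, `[[`, numeric(1), "n_grad_evals")
  ), class = "qaop_fit")
}

# map unconstrained draws to named natural-scale draws
constrain_draws <- function(model, unc) {
  sp <- model$spec
  K <- sp$K; J <- sp$J
  chem <- model$chemicals
  s1_len <- switch(as.character(sp$s1mode), "0" = 1L, "1" = K, "2" = J)
  pos <- 0
  take <- function(n) {
    cols <- unc[, pos + seq_len(n), drop = FALSE]
    pos <<- pos + n
    cols
  }
  out <- list()
  a <- take(K); b <- take(K); cc <- exp(take(K))
  g <- exp(take(1)); s1 <- exp(take(s1_len)); s2 <- exp(take(1))
  t <- take(J)
  for (k in seq_len(K)) {
    out[[paste0("a[", chem[k], "]")]] <- a[, k]
    out[[paste0("b[", chem[k], "]")]] <- b[, k]
    out[[paste0("c[", chem[k], "]")]] <- cc[, k]
  }
  out[["g"]] <- g[, 1]
  if (s1_len == 1) {
    out[["sigma1"]] <- s1[, 1]
  } else if (s1_len == K) {
    for (k in seq_len(K)) out[[paste0("sigma1[", chem[k], "]")]] <- s1[, k]
  } else {
    for (j in seq_len(J)) out[[paste0("sigma1[g", j, "]")]] <- s1[, j]
  }
  out[["sigma2"]] <- s2[, 1]
  # latent group means
  ki <- sp$chem + 1L
  for (j in seq_len(J)) {
    w <- if (sp$dose[j] == 0) 0 else {
      stats::plogis(g[, 1] * (log(sp$dose[j]) - log(cc[, ki[j]])))
    }
    out[[paste0("M[", j, "]")]] <- a[, ki[j]] + b[, ki[j]] * w +
      s2[, 1] * t[, j]
  }
  if (sp$hierarchical == 1) {
    alpha_v <- take(1)[, 1]; alpha_q <- take(1)[, 1]
    sv <- exp(take(1)[, 1]); sq <- exp(take(1)[, 1])
    rho <- tanh(take(1)[, 1])
    mu_h <- take(1)[, 1]; sh <- exp(take(1)[, 1]); r <- take(1)[, 1]
    uv <- take(K); uq <- take(K); zh <- take(K)
    logistic <- sp$re_scale == 0
    out[["mu_v"]] <- if (logistic) stats::plogis(alpha_v) else alpha_v
    out[["mu_q"]] <- if (logistic) stats::plogis(alpha_q) else alpha_q
    out[["sigma_v"]] <- sv
    out[["sigma_q"]] <- sq
    out[["rho_vq"]] <- rho
    out[["mu_h"]] <- mu_h
    out[["sigma_h"]] <- sh
    out[["r"]] <- r
    for (k in seq_len(K)) {
      zv <- uv[, k]
      zq <- rho * uv[, k] + sqrt(1 - rho^2) * uq[, k]
      if (logistic) {
        out[[paste0("v[", chem[k], "]")]] <- stats::plogis(alpha_v + sv * zv)
        out[[paste0("q[", chem[k], "]")]] <- stats::plogis(alpha_q + sq * zq)
      } else {
        out[[paste0("v[", chem[k], "]")]] <- alpha_v + sv * zv
        out[[paste0("q[", chem[k], "]")]] <- alpha_q + sq * zq
      }
      out[[paste0("h[", chem[k], "]")]] <- mu_h + sh * zh[, k]
    }
  } else {
    out[["v"]] <- stats::plogis(take(1)[, 1])
    out[["q"]] <- stats::plogis(take(1)[, 1])
    out[["h"]] <- take(1)[, 1]
    out[["r"]] <- take(1)[, 1]
  }
  tibble::as_tibble(out)
}

#' @export
print.qaop_fit <- function(x, ...) {
  cat(sprintf("qAOP %s fit: %d chains x %d draws (%d parameters)\n",
              x$model$structure, x$mcmc$chains,
              nrow(x$draws) / x$mcmc$chains, x$model$n_par))
  print(x$diagnostics)
  invisible(x)
}

#' Pointwise log-likelihood matrix of a fit
#'
#' Returns the draws-by-observations matrix of per-observation
#' log-likelihood values that feeds the elpd estimators. The default
#' observation unit is one dose-group record, its upstream and downstream
#' contributions summed (the qAOP evaluates the sum of the two
#' log-likelihoods); `unit = "split"` keeps the upstream and downstream
#' contributions as separate observations instead.
#'
#' @param fit A `qaop_fit`.
#' @param unit `"group"` (default) or `"split"`.
#' @return A numeric matrix, draws in rows; column order follows the
#'   dataset record order.
#' @export
extract_pointwise_loglik <- function(fit, unit = c("group", "split")) {
  stopifnot(inherits(fit, "qaop_fit"))
  unit <- match.arg(unit)
  ll <- qaop_pointwise(unname(fit$unconstrained), fit$model$spec)
  if (unit == "group") return(ll)
  # recompute separated contributions in R from the constrained draws
  sp <- fit$model$spec
  d <- fit$draws
  chem <- fit$model$chemicals
  ki <- sp$chem + 1L
  cols <- list()
  for (j in which(sp$has_up == 1)) {
    M <- d[[paste0("M[", j, "]")]]
    s1 <- switch(as.character(sp$s1mode),
                 "0" = d$sigma1,
                 "1" = d[[paste0("sigma1[", chem[ki[j]], "]")]],
                 "2" = d[[paste0("sigma1[g", j, "]")]])
    n1 <- sp$n1[j]
    cols[[paste0("up", j)]] <-
      -n1 / 2 * log(2 * pi) - n1 * log(s1) -
      (n1 * (sp$m[j] - M)^2 + (n1 - 1) * sp$s[j]^2) / (2 * s1^2)
  }
  for (j in which(sp$has_down == 1)) {
    M <- d[[paste0("M[", j, "]")]]
    if (sp$hierarchical == 1) {
      v <- d[[paste0("v[", chem[ki[j]], "]")]]
      q <- d[[paste0("q[", chem[ki[j]], "]")]]
      h <- d[[paste0("h[", chem[ki[j]], "]")]]
    } else {
      v <- d$v; q <- d$q; h <- d$h
    }
    r <- d$r
    s <- if (sp$orientation == 0) stats::plogis(r * (M - h)) else
      stats::plogis(r * M - h)
    p <- if (sp$orientation == 0) v * (q + (1 - q) * s) else
      v * (1 - (1 - q) * s)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    cols[[paste0("down", j)]] <-
      sp$X[j] * log(p) + (sp$n2[j] - sp$X[j]) * log1p(-p)
  }
  do.call(cbind, cols)
}

#' Prior predictive simulation
#'
#' Draws parameters from the model's priors and simulates upstream
#' summaries and downstream counts at the model's design points,
#' supporting the iterative prior-predictive tuning workflow: inspect
#' whether the simulated incidences span the observed range without
#' excessive concentration.
#'
#' @param model A `qaop_model`.
#' @param n_draws Number of prior draws.
#' @param seed Integer seed.
#' @return A tibble with one row per draw and design point: `draw`,
#'   `chemical_id`, `dose`, `M`, `ke_up_mean`, `ke_up_sd`, `incidence`.
#' @export
prior_predictive <- function(model, n_draws = 200, seed = 1) {
  stopifnot(inherits(model, "qaop_model"))
  sp <- model$spec
  pr <- sp$priors
  K <- sp$K; J <- sp$J
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_draws), function(sdx) {
      a <- stats::rnorm(K, pr$a0, pr$a_sd)
      b <- stats::rnorm(K, pr$b0, pr$b_sd)
      cc <- abs(stats::rnorm(K, pr$c0, pr$c_sd))
      g <- abs(stats::rnorm(1, pr$g0, pr$g_sd))
      s1 <- abs(stats::rcauchy(1, 0, pr$scale_sigma1))
      s2 <- abs(stats::rcauchy(1, 0, pr$scale_sigma2))
      if (sp$hierarchical == 1) {
        mu_v <- msm_trunc_norm(pr$muv_mean, pr$muv_sd, 0, 1)
        mu_q <- msm_trunc_norm(pr$muq_mean, pr$muq_sd, 0, 1)
        sv <- abs(stats::rcauchy(1, 0, pr$scale_sv))
        sq <- abs(stats::rcauchy(1, 0, pr$scale_sq))
        sh <- abs(stats::rcauchy(1, 0, pr$scale_sh))
        rho <- 2 * stats::rbeta(1, pr$lkj_eta, pr$lkj_eta) - 1
        mu_h <- stats::rnorm(1, pr$muh_mean, pr$muh_sd)
        r <- stats::rnorm(1, pr$r_mean, pr$r_sd)
        uv <- stats::rnorm(K); uq <- stats::rnorm(K)
        zq <- rho * uv + sqrt(1 - rho^2) * uq
        if (sp$re_scale == 0) {
          v <- stats::plogis(stats::qlogis(mu_v) + sv * uv)
          q <- stats::plogis(stats::qlogis(mu_q) + sq * zq)
        } else {
          v <- pmin(pmax(mu_v + sv * uv, 1e-3), 1)
          q <- pmin(pmax(mu_q + sq * zq, 0), 0.99)
        }
        h <- mu_h + sh * stats::rnorm(K)
      } else {
        v <- rep(stats::rbeta(1, pr$v_a, pr$v_b), K)
        q <- rep(stats::rbeta(1, pr$q_a, pr$q_b), K)
        h <- rep(stats::rnorm(1, pr$h_mean, pr$h_sd), K)
        r <- stats::rnorm(1, pr$r_mean, pr$r_sd)
      }
      ki <- sp$chem + 1L
      w <- ifelse(sp$dose == 0, 0,
                  stats::plogis(g * (log(pmax(sp$dose, 1e-300)) -
                                       log(cc[ki]))))
      M <- stats::rnorm(J, a[ki] + b[ki] * w, s2)
      sg <- stats::plogis(r * (M - h[ki]))
      p <- v[ki] * (q[ki] + (1 - q[ki]) * sg)
      y <- purrr::map(seq_len(J), function(j) {
        exp(stats::rnorm(sp$n1[j], M[j], s1))
      })
      tibble::tibble(
        draw = sdx,
        chemical_id = model$chemicals[ki],
        dose = sp$dose,
        M = M,
        ke_up_mean = purrr::map_dbl(y, mean),
        ke_up_sd = purrr::map_dbl(y, stats::sd),
        incidence = stats::rbinom(J, round(sp$n2), p) / round(sp$n2)
      )
    })
  })
}

# draw one value from a truncated normal by inversion
msm_trunc_norm <- function(mean, sd, lo, hi) {
  u <- stats::runif(1, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Tidy posterior summaries of a qAOP fit
#'
#' @param x A `qaop_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: posterior mean, SD,
#'   5%/95% quantiles, R-hat and ESS where available.
#' @export
tidy.qaop_fit <- function(x, ...) {
  d <- dplyr::select(x$draws, -dplyr::any_of(c(".chain", ".iteration")))
  out <- purrr::map_dfr(names(d), function(nm) {
    v <- d[[nm]]
    tibble::tibble(parameter = nm, mean = mean(v), sd = stats::sd(v),
                   q5 = unname(stats::quantile(v, 0.05)),
                   q95 = unname(stats::quantile(v, 0.95)))
  })
  out
}

#' One-row fit summary
#'
#' @param x A `qaop_fit`.
#' @param ... Unused.
#' @return A one-row tibble: structure, draw counts, diagnostics gates.
#' @export
glance.qaop_fit <- function(x, ...) {
  tibble::tibble(
    structure = x$model$structure,
    chains = x$mcmc$chains,
    draws = nrow(x$draws),
    max_rhat = x$diagnostics$max_rhat,
    min_ess = x$diagnostics$min_ess,
    divergences = x$diagnostics$divergences,
    pass = x$diagnostics$pass
  )
}
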
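#' @keywords internal
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @keywords internal
log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))

#' Fit a generalized Pareto distribution to tail samples
#'
#' Empirical-Bayes profile-likelihood estimator of the generalized Pareto
#' shape `k` and scale `sigma` (Zhang & Stephens 2009), with the weakly
#' informative shape prior used by the standard PSIS implementations
#' (shape shrunk toward 0.5 with prior weight 10).
#'
#' @param x Positive exceedances (will be sorted).
#' @return A list with `k` and `sigma`.
#' @export
gpd_fit <- function(x) {
  x <- sort.int(x)
  n <- length(x)
  if (n < 2) stop("need >= 2 tail samples to fit a generalized Pareto",
                  call. = FALSE)
  prior_bs <- 3
  prior_k <- 10
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[floor(n / 4 + 0.5)]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  # profile log-likelihood of theta with shape maximized out
  k_prof <- vapply(theta, function(th) mean(log1p(-th * x)), numeric(1))
  l_theta <- n * (log(-theta / k_prof) - k_prof - 1)
  w <- exp(l_theta - log_sum_exp(l_theta))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  k <- (n * k + prior_k * 0.5) / (n + prior_k)
  list(k = k, sigma = sigma)
}

#' @keywords internal
gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(sigma * (-log1p(-p)))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smooth one vector of log importance ratios; returns the
# normalized log weights and the Pareto shape diagnostic.
psis_smooth <- function(log_ratios) {
  S <- length(log_ratios)
  x <- log_ratios - max(log_ratios)
  n_tail <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  khat <- Inf
  if (n_tail >= 5 && S - n_tail >= 1) {
    ord <- order(x)
    cutoff <- x[ord[S - n_tail]]  # largest non-tail value
    tail_ids <- which(x > cutoff)
    x_tail <- x[tail_ids]
    if (length(unique(x_tail)) >= 2) {
      exc <- exp(x_tail) - exp(cutoff)
      fit <- gpd_fit(exc)
      khat <- fit$k
      if (is.finite(khat)) {
        m <- length(exc)
        sti <- (seq_len(m) - 0.5) / m
        smoothed <- vapply(sti, gpd_quantile, numeric(1),
                           k = fit$k, sigma = fit$sigma) + exp(cutoff)
        # replace tail values by GPD quantiles, preserving their order
        x[tail_ids[order(x_tail)]] <- log(smoothed)
      }
    }
  }
  x <- pmin(x, 0)  # truncate at the maximum raw ratio
  list(log_weights = x - log_sum_exp(x), khat = khat)
}

#' @keywords internal
check_loglik_matrix <- function(ll) {
  ll <- as.matrix(ll)
  if (nrow(ll) < 100) stop("need >= 100 posterior draws", call. = FALSE)
  if (ncol(ll) < 2) stop("need >= 2 observations", call. = FALSE)
  bad <- which(!apply(is.finite(ll), 2, all))
  if (length(bad) > 0) {
    stop("non-finite log-likelihood entries for observation(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  ll
}

#' Widely Applicable Information Criterion
#'
#' Computes the WAIC estimate of the expected log predictive density from a
#' draws-by-observations pointwise log-likelihood matrix:
#' `elpd_waic = sum_i [log mean_s exp(ll_si) - var_s(ll_si)]`, reported on
#' the elpd scale with its standard error from the pointwise dispersion.
#'
#' @param pointwise_loglik Matrix (posterior draws in rows, observations in
#'   columns) of log-likelihood values, e.g. from
#'   [extract_pointwise_loglik()].
#' @return A list of class `"elpd_result"` with `estimate`, `se`, `p_eff`
#'   (effective parameter count) and `pointwise` contributions.
#' @export
waic <- function(pointwise_loglik) {
  ll <- check_loglik_matrix(pointwise_loglik)
  lpd <- apply(ll, 2, log_mean_exp)
  p_waic <- apply(ll, 2, stats::var)
  pointwise <- lpd - p_waic
  n <- length(pointwise)
  structure(list(
    estimate = sum(pointwise),
    se = sqrt(n * stats::var(pointwise)),
    p_eff = sum(p_waic),
    pointwise = pointwise,
    method = "waic"
  ), class = "elpd_result")
}

#' PSIS-LOO expected log predictive density
#'
#' Approximates leave-one-out cross-validation by Pareto-smoothed
#' importance sampling: per observation, the importance ratios
#' `exp(-ll_si)` have their upper tail replaced by quantiles of a fitted
#' generalized Pareto distribution (tail length `min(0.2 S, 3 sqrt(S))`,
#' weights truncated at the raw maximum), and
#' `elpd_loo_i = log sum_s w_si exp(ll_si)` with normalized smoothed
#' weights. The per-observation Pareto shape `k` diagnoses reliability;
#' observations with `k > 0.7` are flagged.
#'
#' @inheritParams waic
#' @param khat_threshold Flagging threshold for the Pareto shape
#'   (default 0.7).
#' @return A list of class `"elpd_result"` with `estimate`, `se`, `p_eff`,
#'   `pointwise` contributions and `pareto_k` diagnostics.
#' @export
psis_loo <- function(pointwise_loglik, khat_threshold = 0.7) {
  ll <- check_loglik_matrix(pointwise_loglik)
  n <- ncol(ll)
  pointwise <- numeric(n)
  khat <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i])
    pointwise[i] <- log_sum_exp(sm$log_weights + ll[, i])
    khat[i] <- sm$khat
  }
  lpd <- apply(ll, 2, log_mean_exp)
  n_bad <- sum(khat > khat_threshold)
  if (n_bad > 0) {
    warning(sprintf(
      "%d observation(s) with Pareto k > %.2f; PSIS-LOO may be unreliable",
      n_bad, khat_threshold), call. = FALSE)
  }
  structure(list(
    estimate = sum(pointwise),
    se = sqrt(n * stats::var(pointwise)),
    p_eff = sum(lpd - pointwise),
    pointwise = pointwise,
    pareto_k = khat,
    n_flagged = n_bad,
    method = "psis_loo"
  ), class = "elpd_result")
}

#' @export
print.elpd_result <- function(x, ...) {
  lab <- if (x$method == "waic") "elpd_waic" else "elpd_loo"
  cat(sprintf("%s = %.2f (SE %.2f), p_eff = %.2f, n = %d\n",
              lab, x$estimate, x$se, x$p_eff, length(x$pointwise)))
  if (!is.null(x$pareto_k) && x$n_flagged > 0) {
    cat(x$n_flagged, "observation(s) with Pareto k above threshold\n")
  }
  invisible(x)
}

#' Tidy an elpd result
#'
#' @param x An `"elpd_result"` from [waic()] or [psis_loo()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.elpd_result <- function(x, ...) {
  tibble::tibble(method = x$method, elpd = x$estimate, se = x$se,
                 p_eff = x$p_eff, n_obs = length(x$pointwise),
                 n_flagged = if (is.null(x$n_flagged)) NA_integer_
                             else x$n_flagged)
}

#' Compare flat and hierarchical fits by predictive performance
#'
#' Computes the hierarchical-minus-flat difference in elpd by both PSIS-LOO
#' and WAIC; positive differences support the hierarchical model. The
#' difference standard error is the paired SE from the pointwise difference
#' vector. Both fits must be on the identical dataset with identical
#' observation units.
#'
#' @param flat,hierarchical `qaop_fit` objects (see [fit_qaop()]) or
#'   draws-by-observations log-likelihood matrices.
#' @return A list of class `"qaop_comparison"` with a `table` tibble
#'   (method, elpd per model, diff, diff SE, preferred model) and the
#'   underlying `elpd_result` objects.
#' @export
compare_models <- function(flat, hierarchical) {
  get_ll <- function(x) {
    if (inherits(x, "qaop_fit")) extract_pointwise_loglik(x) else as.matrix(x)
  }
  ll_f <- get_ll(flat)
  ll_h <- get_ll(hierarchical)
  if (ncol(ll_f) != ncol(ll_h)) {
    stop("fits have different observation sets (",
         ncol(ll_f), " vs ", ncol(ll_h), ")", call. = FALSE)
  }
  res <- list(
    loo = list(flat = psis_loo(ll_f), hierarchical = psis_loo(ll_h)),
    waic = list(flat = waic(ll_f), hierarchical = waic(ll_h))
  )
  row_for <- function(method) {
    f <- res[[method]]$flat
    h <- res[[method]]$hierarchical
    dp <- h$pointwise - f$pointwise
    n <- length(dp)
    diff <- sum(dp)
    tibble::tibble(
      method = method,
      elpd_flat = f$estimate,
      elpd_hierarchical = h$estimate,
      diff = diff,
      diff_se = sqrt(n * stats::var(dp)),
      preferred = if (diff > 0) "hierarchical" else "flat"
    )
  }
  structure(list(
    table = dplyr::bind_rows(row_for("loo"), row_for("waic")),
    results = res
  ), class = "qaop_comparison")
}

#' @export
print.qaop_comparison <- function(x, ...) {
  cat("Flat vs hierarchical predictive performance",
      "(positive diff favors hierarchical):\n")
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tidy a model comparison
#'
#' @param x A `"qaop_comparison"` from [compare_models()].
#' @param ... Unused.
#' @return The comparison table as a tibble (one row per metric).
#' @export
tidy.qaop_comparison <- function(x, ...) x$table
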
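# MCMC convergence diagnostics: split R-hat and effective sample size
# (Geyer initial-monotone-sequence estimator on split chains).

autocov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  npad <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, rep(0, npad - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / npad
  ac / n  # biased autocovariance, lag 0 .. n-1
}

split_chains <- function(mat) {
  # iterations x chains -> halve each chain
  n <- nrow(mat)
  half <- floor(n / 2)
  do.call(cbind, lapply(seq_len(ncol(mat)), function(j) {
    cbind(mat[seq_len(half), j], mat[(n - half + 1):n, j])
  }))
}

#' Split R-hat for one parameter
#'
#' @param mat Iterations-by-chains matrix of draws.
#' @return The split potential-scale-reduction statistic.
#' @export
rhat <- function(mat) {
  mat <- as.matrix(mat)
  sm <- split_chains(mat)
  n <- nrow(sm)
  m <- ncol(sm)
  if (n < 4) return(NA_real_)
  means <- colMeans(sm)
  vars <- apply(sm, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(ifelse(B <= 0, 1, Inf))
  sqrt((W * (n - 1) / n + B / n) / W)
}

#' Effective sample size for one parameter
#'
#' Combined-chain ESS using per-chain FFT autocovariances and Geyer's
#' initial monotone positive sequence, on split chains.
#'
#' @param mat Iterations-by-chains matrix of draws.
#' @return The effective sample size.
#' @export
ess <- function(mat) {
  mat <- as.matrix(mat)
  sm <- split_chains(mat)
  n <- nrow(sm)
  m <- ncol(sm)
  if (n < 4) return(NA_real_)
  acov <- apply(sm, 2, autocov_fft)
  chain_var <- apply(sm, 2, stats::var)
  mean_var <- mean(chain_var)           # W
  means <- colMeans(sm)
  var_plus <- mean_var * (n - 1) / n + (if (m > 1) stats::var(means) else 0)
  if (var_plus <= 0) return(NA_real_)
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  max_t <- 2 * floor((n - 2) / 2)
  tau <- 1
  prev <- Inf
  t <- 1
  while (t + 1 <= max_t) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    prev <- pair
    tau <- tau + 2 * pair
    t <- t + 2
  }
  n * m / tau
}

#' Convergence diagnostics for a qAOP fit
#'
#' Computes split R-hat and effective sample size for every sampled
#' parameter plus the log posterior, together with the divergence count.
#' The fit passes when all R-hat values fall below `rhat_threshold`
#' (default 1.01, operationalizing "close to 1") and all ESS exceed
#' `ess_threshold` (default 400) with no post-warmup divergences.
#'
#' @param draws_array Iterations x chains x parameters array.
#' @param divergences Total post-warmup divergence count.
#' @param rhat_threshold,ess_threshold Gate thresholds.
#' @return A list of class `"qaop_diagnostics"`: per-parameter tibble and
#'   pass/fail flags.
#' @export
compute_diagnostics <- function(draws_array, divergences = 0,
                                rhat_threshold = 1.01, ess_threshold = 400) {
  pn <- dimnames(draws_array)[[3]]
  tab <- purrr::map_dfr(seq_along(pn), function(i) {
    mat <- draws_array[, , i, drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
    tibble::tibble(parameter = pn[i], rhat = rhat(mat), ess = ess(mat))
  })
  rhat_ok <- all(is.na(tab$rhat) | tab$rhat < rhat_threshold)
  ess_ok <- all(is.na(tab$ess) | tab$ess > ess_threshold)
  structure(list(
    parameters = tab,
    divergences = divergences,
    max_rhat = max(tab$rhat, na.rm = TRUE),
    min_ess = min(tab$ess, na.rm = TRUE),
    rhat_ok = rhat_ok, ess_ok = ess_ok,
    divergence_ok = divergences == 0,
    pass = rhat_ok && ess_ok,
    rhat_threshold = rhat_threshold, ess_threshold = ess_threshold
  ), class = "qaop_diagnostics")
}

#' @export
print.qaop_diagnostics <- function(x, ...) {
  cat(sprintf(
    "MCMC diagnostics: max R-hat %.4f (gate < %.3f: %s), min ESS %.0f ",
    x$max_rhat, x$rhat_threshold, ifelse(x$rhat_ok, "ok", "FAIL"),
    x$min_ess))
  cat(sprintf("(gate > %d: %s), %d divergence(s)\n",
              x$ess_threshold, ifelse(x$ess_ok, "ok", "FAIL"),
              x$divergences))
  invisible(x)
}
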
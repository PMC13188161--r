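#' Transform natural-scale summary statistics to the log scale
#'
#' Converts a group mean and standard deviation reported on the natural
#' scale of a lognormal endpoint into the mean and standard deviation of the
#' log responses, by lognormal moment matching:
#' `log_sd = sqrt(log(1 + (sd / mean)^2))` and
#' `log_mean = log(mean) - log_sd^2 / 2`. The transform is exact when the
#' underlying responses are lognormal, and [transform_log_to_summary()] is
#' its algebraic inverse.
#'
#' @param mean_natural Positive group mean(s) on the natural scale.
#' @param sd_natural Non-negative group SD(s) on the natural scale.
#' @return A [tibble::tibble] with columns `log_mean` and `log_sd`.
#' @export
#' @examples
#' transform_summary_to_log(1, 1)
transform_summary_to_log <- function(mean_natural, sd_natural) {
  if (any(mean_natural <= 0)) {
    stop("natural-scale mean must be > 0 to transform to the log scale",
         call. = FALSE)
  }
  if (any(sd_natural < 0)) stop("`sd_natural` must be >= 0", call. = FALSE)
  log_var <- log1p((sd_natural / mean_natural)^2)
  tibble::tibble(
    log_mean = log(mean_natural) - log_var / 2,
    log_sd = sqrt(log_var)
  )
}

#' @rdname transform_summary_to_log
#' @param log_mean,log_sd Log-scale mean(s) and SD(s).
#' @export
transform_log_to_summary <- function(log_mean, log_sd) {
  if (any(log_sd < 0)) stop("`log_sd` must be >= 0", call. = FALSE)
  m <- exp(log_mean + log_sd^2 / 2)
  tibble::tibble(
    mean_natural = m,
    sd_natural = m * sqrt(expm1(log_sd^2))
  )
}

#' Summarized-data log-likelihood of the upstream key event
#'
#' Log-likelihood of lognormal individual responses evaluated through the
#' sufficient statistics of each dose group: with `N = sum(n)` individuals,
#' log-scale group means `m`, SDs `s` and latent group means `M`,
#' \deqn{LL = -\frac{N}{2}\log(2\pi) - \sum_j \Big[\frac{n_j}{2}\log\sigma_1^2
#'   + \frac{n_j (m_j - M_j)^2 + (n_j - 1) s_j^2}{2\sigma_1^2}\Big].}
#' It equals the sum of per-individual normal log-densities of the log
#' responses whenever `m` and `s` are their sample mean and SD.
#'
#' @param groups Data frame with one row per dose group and columns
#'   `log_mean`, `log_sd` and `n` (group size); obtain `log_mean`/`log_sd`
#'   from natural-scale summaries with [transform_summary_to_log()].
#' @param M Numeric vector of latent group means, one per row of `groups`.
#' @param sigma1 Within-group SD on the log scale; either a scalar or a
#'   vector with one value per group.
#' @return The scalar log-likelihood.
#' @export
loglik_ke_up <- function(groups, M, sigma1) {
  stopifnot(is.data.frame(groups),
            all(c("log_mean", "log_sd", "n") %in% names(groups)))
  n <- groups$n
  if (any(n < 1)) stop("group sizes `n` must be >= 1", call. = FALSE)
  if (any(sigma1 <= 0)) stop("`sigma1` must be > 0", call. = FALSE)
  if (length(M) != nrow(groups)) {
    stop("`M` must have one entry per group", call. = FALSE)
  }
  N <- sum(n)
  m <- groups$log_mean
  s <- groups$log_sd
  -N / 2 * log(2 * pi) -
    sum(n / 2 * log(sigma1^2) +
          (n * (m - M)^2 + (n - 1) * s^2) / (2 * sigma1^2))
}

#' Summarized-data log-likelihood of the downstream key event
#'
#' Binomial log-likelihood of the case count given the event probability
#' implied by the dichotomous Hill curve at latent level `M`, with the
#' binomial coefficient omitted (it is constant in the parameters):
#' `X * log(p) + (n2 - X) * log(1 - p)`.
#'
#' A probability pinned to 0 or 1 that contradicts the observed counts
#' yields `-Inf` with a warning rather than `NaN`.
#'
#' @param cases Case count(s) `X`.
#' @param n2 Group size(s).
#' @param M Latent log upstream level(s).
#' @param params A [dichotomous_hill_params()] object.
#' @param orientation Passed to [hill_dichotomous()].
#' @return The scalar log-likelihood (summed over groups).
#' @export
loglik_ke_down <- function(cases, n2, M, params,
                           orientation = c("corrected", "printed")) {
  orientation <- match.arg(orientation)
  if (any(cases < 0) || any(cases > n2)) {
    stop("`cases` must satisfy 0 <= cases <= n2", call. = FALSE)
  }
  p <- hill_dichotomous(M, params, orientation)
  ll <- numeric(length(p))
  ok_low <- p > 0 | cases == 0
  ok_high <- p < 1 | cases == n2
  bad <- !(ok_low & ok_high)
  if (any(bad)) {
    warning("event probability pinned to 0 or 1 contradicts observed counts; ",
            "log-likelihood is -Inf", call. = FALSE)
  }
  term1 <- ifelse(cases == 0, 0, cases * log(p))
  term2 <- ifelse(cases == n2, 0, (n2 - cases) * log1p(-p))
  ll <- term1 + term2
  ll[bad] <- -Inf
  sum(ll)
}
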
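#' Variance specification for the upstream measurement model
#'
#' Under the lognormal measurement model a constant coefficient of variation
#' on the natural scale is equivalent to a constant SD `sigma1` on the log
#' scale; `"constant_log_sd"` is therefore accepted as an alias of
#' `"constant_cv"`. `"constant_sd"` denotes a constant absolute SD on the
#' natural scale (which implies a dose-dependent `sigma1`), and
#' `"free_per_group"` leaves each group's variance unrestricted.
#'
#' @param mode One of `"constant_cv"`, `"constant_sd"`, `"free_per_group"`
#'   (alias: `"constant_log_sd"` for `"constant_cv"`).
#' @param per_chemical Should `sigma1` be chemical-specific in the fitted
#'   model? Default `TRUE`, matching the chemical-specific dose-response
#'   parametrization.
#' @return A list of class `"variance_spec"`.
#' @export
variance_spec <- function(mode = c("constant_cv", "constant_sd",
                                   "free_per_group", "constant_log_sd"),
                          per_chemical = TRUE) {
  mode <- match.arg(mode)
  if (mode == "constant_log_sd") mode <- "constant_cv"
  structure(list(mode = mode, per_chemical = isTRUE(per_chemical)),
            class = "variance_spec")
}

#' Constant coefficient-of-variation test
#'
#' Compares three nested variance structures for the natural-scale group
#' summaries of the upstream key event — constant CV (`sd ~ mean`, the
#' lognormal default), constant absolute SD, and a saturated free-per-group
#' model — by maximized normal likelihood through the sufficient statistics,
#' with likelihood-ratio tests of each restricted model against the
#' saturated one. A proportionality diagnostic (slope of `log(sd)` on
#' `log(mean)`; near 1 under constant CV, near 0 under constant SD) is
#' reported alongside.
#'
#' A restricted model is deemed adequate when its LR p-value exceeds
#' `alpha`; if both restricted models are adequate the one with the higher
#' likelihood is selected, and if neither is, the free-per-group structure
#' is returned. With fewer than three informative groups (`n >= 2`) the
#' test is untestable and defaults to constant CV with a warning.
#'
#' @param data A data frame accepted by [validate_qaop_data()].
#' @param per_chemical Recorded in the returned [variance_spec()].
#' @param alpha Significance level of the LR adequacy tests (default 0.05).
#' @return A list of class `"cv_test"`: `spec` (the selected
#'   [variance_spec()]), `untestable`, `report` (per-model log-likelihoods,
#'   LR statistics and p-values) and `slope` (proportionality diagnostic).
#' @export
constant_cv_test <- function(data, per_chemical = TRUE, alpha = 0.05) {
  data <- validate_qaop_data(data)
  d <- data |>
    dplyr::filter(!is.na(.data$ke_up_mean), .data$ke_up_n >= 2,
                  .data$ke_up_sd > 0)
  if (nrow(d) < 3) {
    warning("fewer than 3 informative groups: constant-CV test is ",
            "untestable; defaulting to constant CV", call. = FALSE)
    return(structure(list(
      spec = variance_spec("constant_cv", per_chemical),
      untestable = TRUE, report = NULL, slope = NA_real_
    ), class = "cv_test"))
  }
  m <- d$ke_up_mean
  s <- d$ke_up_sd
  n <- d$ke_up_n
  N <- sum(n)
  J <- nrow(d)
  rss <- (n - 1) * s^2  # within-group residual sums, group means free

  ll_normal <- function(sigma2_j) {
    sum(-n / 2 * log(2 * pi * sigma2_j) - rss / (2 * sigma2_j))
  }
  sig2_const <- sum(rss) / N
  ll_const_sd <- ll_normal(rep(sig2_const, J))
  phi2 <- sum(rss / m^2) / N
  ll_const_cv <- ll_normal(phi2 * m^2)
  sig2_free <- rss / n
  if (any(sig2_free == 0)) {
    stop("a group with zero residual variance entered the test", call. = FALSE)
  }
  ll_free <- ll_normal(sig2_free)

  lr_sd <- 2 * (ll_free - ll_const_sd)
  lr_cv <- 2 * (ll_free - ll_const_cv)
  df <- J - 1
  # Bartlett-corrected homogeneity statistics: better calibrated than the
  # raw LR at moderate group sizes; the CV model is homogeneity of the
  # mean-scaled variances
  bartlett_p <- function(s2_j, inflation = 1) {
    dfg <- n - 1
    sp2 <- sum(dfg * s2_j) / sum(dfg)
    M <- sum(dfg) * log(sp2) - sum(dfg * log(s2_j))
    C <- 1 + (sum(1 / dfg) - 1 / sum(dfg)) / (3 * df)
    stats::pchisq(M / (C * inflation), df, lower.tail = FALSE)
  }
  p_sd <- bartlett_p(s^2)
  # scaling by the *sample* mean adds ~2 cv^2 relative variance to each
  # log scaled variance; inflate the reference accordingly
  cv2_hat <- stats::median((s / m)^2)
  p_cv <- bartlett_p((s / m)^2,
                     inflation = 1 + 2 * cv2_hat * mean((n - 1) / n))
  slope <- unname(stats::coef(stats::lm(log(s) ~ log(m)))[2])

  adequate <- c(constant_cv = p_cv >= alpha, constant_sd = p_sd >= alpha)
  lls <- c(constant_cv = ll_const_cv, constant_sd = ll_const_sd)
  if (any(adequate)) {
    mode <- names(which.max(lls[adequate]))
  } else {
    mode <- "free_per_group"
  }
  report <- tibble::tibble(
    model = c("constant_cv", "constant_sd", "free_per_group"),
    loglik = c(ll_const_cv, ll_const_sd, ll_free),
    n_par = c(J + 1, J + 1, 2 * J),
    lr_stat = c(lr_cv, lr_sd, NA_real_),
    p_value = c(p_cv, p_sd, NA_real_)
  )
  structure(list(
    spec = variance_spec(mode, per_chemical),
    untestable = FALSE, report = report, slope = slope
  ), class = "cv_test")
}

#' @export
print.cv_test <- function(x, ...) {
  if (x$untestable) {
    cat("Constant-CV test: untestable (defaulted to constant CV)\n")
  } else {
    cat("Constant-CV test: selected", x$spec$mode, "\n")
    cat(sprintf("log(sd) ~ log(mean) slope: %.3f\n", x$slope))
    print(x$report)
  }
  invisible(x)
}
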
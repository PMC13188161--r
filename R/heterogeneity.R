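#' Cohen's f effect size for cross-chemical heterogeneity
#'
#' Quantifies how much the downstream response varies across chemicals
#' relative to variation within chemicals. With per-chemical means
#' \eqn{\mu_j}, per-chemical sizes \eqn{n_j}, global mean \eqn{\hat\mu}
#' and per-observation responses \eqn{y_i}:
#' \deqn{SSB = \sum_j n_j (\mu_j - \hat\mu)^2, \qquad
#'       SST = \sum_i (y_i - \hat\mu)^2,}
#' and Cohen's f is `sqrt(SSB / (SST - SSB))` (the raw ratio
#' `SSB / SSW` is f squared and is reported alongside).
#'
#' For the default downstream-incidence response the observations are the
#' individual dichotomous outcomes: each dose group contributes
#' `ke_down_n` subjects, so the within-group binomial variability
#' `n * p * (1 - p)` enters SST through its sufficient statistics and the
#' per-chemical sizes are subject counts. When an explicit `response`
#' column is supplied, each row is treated as one observation instead
#' (optionally weighted).
#'
#' By default a shared trend is removed first: the responses are replaced
#' by their residuals from a global isotonic (monotone) fit of response on
#' the log upstream group level (`adjust = "ke_up"`), so that f captures
#' how much the downstream response varies across chemicals relative to
#' its variation along the upstream key event within chemicals — the
#' response-response heterogeneity that distinguishes the flat and
#' hierarchical calibrations. `adjust = "dose"` uses `log1p(dose)` as the
#' trend covariate instead, and `adjust = "none"` computes the unadjusted
#' one-way effect size.
#'
#' @param data A data frame with one row per observation (dose group).
#' @param response Column name (string) of the response; defaults to the
#'   downstream incidence proportion `ke_down_cases / ke_down_n` when both
#'   columns are present and `response` is `NULL`.
#' @param group Column name of the chemical/cluster label
#'   (default `"chemical_id"`).
#' @param covariate Column name of the trend covariate; defaults to
#'   `"ke_up_mean"` (log-transformed) for `adjust = "ke_up"` and `"dose"`
#'   for `adjust = "dose"`.
#' @param weights Optional column name of per-observation weights (e.g.
#'   group sizes). Defaults to `ke_down_n` for the incidence response, else
#'   unweighted.
#' @param adjust `"ke_up"` (default), `"dose"`, or `"none"`; `TRUE`/`FALSE`
#'   are accepted as `"ke_up"`/`"none"`.
#' @return A list of class `"effect_size"` with `f`, `f2`, `SSB`, `SSW`,
#'   `SST`, `level` (see [classify_heterogeneity()]), `per_chemical`
#'   summaries and the global mean. Zero within-chemical variance sets
#'   `f = Inf` with `infinite = TRUE` rather than failing.
#' @export
cohens_f <- function(data, response = NULL, group = "chemical_id",
                     covariate = NULL, weights = NULL,
                     adjust = c("ke_up", "dose", "none")) {
  stopifnot(is.data.frame(data))
  if (is.logical(adjust)) adjust <- if (adjust) "ke_up" else "none"
  adjust <- match.arg(adjust)
  binomial_within <- 0
  if (is.null(response)) {
    if (!all(c("ke_down_cases", "ke_down_n") %in% names(data))) {
      stop("supply `response` or provide ke_down_cases / ke_down_n columns",
           call. = FALSE)
    }
    d <- data |>
      dplyr::filter(!is.na(.data$ke_down_cases), !is.na(.data$ke_down_n))
    y <- d$ke_down_cases / d$ke_down_n
    w <- if (is.null(weights)) d$ke_down_n else d[[weights]]
    # individual-level responses: deviation of each subject's 0/1 outcome
    # from its group proportion, via sufficient statistics
    binomial_within <- sum(d$ke_down_n * y * (1 - y))
  } else {
    d <- data[!is.na(data[[response]]), , drop = FALSE]
    y <- d[[response]]
    w <- if (is.null(weights)) rep(1, length(y)) else d[[weights]]
  }
  labs <- d[[group]]
  if (length(unique(labs)) < 2) {
    stop("need >= 2 chemicals to compute an effect size", call. = FALSE)
  }
  if (adjust != "none") {
    covariate <- covariate %||%
      switch(adjust, ke_up = "ke_up_mean", dose = "dose")
    if (!covariate %in% names(d)) {
      stop("covariate column `", covariate, "` not found for adjustment",
           call. = FALSE)
    }
    x <- switch(adjust,
                ke_up = log(d[[covariate]]),
                dose = log1p(d[[covariate]]))
    ord <- order(x)
    iso <- stats::isoreg(x[ord], y[ord])
    fitted <- numeric(length(y))
    fitted[ord] <- iso$yf
    y <- y - fitted
  }
  mu_hat <- sum(w * y) / sum(w)
  per_chem <- tibble::tibble(chemical_id = labs, y = y, w = w) |>
    dplyr::group_by(.data$chemical_id) |>
    dplyr::summarise(n = sum(.data$w),
                     mean = sum(.data$w * .data$y) / sum(.data$w),
                     .groups = "drop")
  SSB <- sum(per_chem$n * (per_chem$mean - mu_hat)^2)
  SST <- sum(w * (y - mu_hat)^2) + binomial_within
  SSW <- SST - SSB
  infinite <- SSW <= .Machine$double.eps * max(SST, 1)
  f2 <- if (infinite) Inf else SSB / SSW
  f <- sqrt(f2)
  structure(list(
    f = f, f2 = f2, SSB = SSB, SSW = SSW, SST = SST,
    infinite = infinite, adjusted = adjust,
    level = if (is.finite(f)) classify_heterogeneity(f) else "large",
    per_chemical = per_chem, global_mean = mu_hat
  ), class = "effect_size")
}

#' Classify a Cohen's f value into a heterogeneity level
#'
#' Levels follow the conventional effect-size thresholds: `none` for
#' `f < 0.1`, `small` for `0.1 <= f < 0.2`, `medium` for `0.2 <= f < 0.4`
#' and `large` for `f >= 0.4` (boundaries inclusive at the lower edge).
#'
#' @param f Non-negative Cohen's f value(s).
#' @return Character vector of levels, ordered factor-compatible.
#' @export
#' @examples
#' classify_heterogeneity(c(0.05, 0.1, 0.2, 0.5))
classify_heterogeneity <- function(f) {
  if (any(f < 0)) stop("Cohen's f must be >= 0", call. = FALSE)
  cut(f, breaks = c(-Inf, 0.1, 0.2, 0.4, Inf),
      labels = c("none", "small", "medium", "large"),
      right = FALSE) |> as.character()
}

#' Target Cohen's f for a named heterogeneity level
#'
#' The achieved effect sizes of the simulation design: `none = 0.05`,
#' `small = 0.1`, `medium = 0.2`, `large = 0.5`.
#'
#' @param level One or more of `"none"`, `"small"`, `"medium"`, `"large"`.
#' @return Numeric target f value(s).
#' @export
heterogeneity_target_f <- function(level) {
  targets <- c(none = 0.05, small = 0.1, medium = 0.2, large = 0.5)
  bad <- setdiff(level, names(targets))
  if (length(bad) > 0) {
    stop("unknown heterogeneity level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(targets[level])
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's f = %.4f (f^2 = %.4f), level: %s%s\n",
              x$f, x$f2, x$level,
              if (x$adjusted != "none") {
                paste0(" [", x$adjusted, "-adjusted]")
              } else ""))
  cat(sprintf("SSB = %.4g, SSW = %.4g, SST = %.4g over %d chemicals\n",
              x$SSB, x$SSW, x$SST, nrow(x$per_chemical)))
  invisible(x)
}

#' Tidy an effect-size result
#'
#' @param x An `"effect_size"` object from [cohens_f()].
#' @param ... Unused.
#' @return A one-row tibble with `f`, `f2`, `SSB`, `SSW`, `SST`, `level`.
#' @export
tidy.effect_size <- function(x, ...) {
  tibble::tibble(f = x$f, f2 = x$f2, SSB = x$SSB, SSW = x$SSW,
                 SST = x$SST, level = x$level, adjusted = x$adjusted)
}
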
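#' Invert the extra-risk equation for a benchmark level
#'
#' Solves the extra-risk definition
#' \deqn{BMR = \frac{f(BML) - f(0)}{1 - f(0)}}
#' for the natural-scale upstream level `L`, where `f` is the dichotomous
#' Hill response-response curve evaluated at `log(L)` and `f(0)` is its
#' zero-level background `v * q`. The solution is closed form: writing
#' `p* = vq + bmr * (1 - vq)` for the target probability, the logistic term
#' satisfies `e^{r (M - h)} = (p* - vq) / (v - p*)`, so
#' `L = exp(h + log((p* - vq) / (v - p*)) / r)`.
#'
#' @param params A [dichotomous_hill_params()] object with `r` > 0.
#' @param bmr Benchmark response (extra risk), in (0, 1); default 0.05.
#' @return The benchmark level on the natural upstream scale.
#' @export
#' @examples
#' invert_extra_risk(dichotomous_hill_params(1, 0, 0, 1), bmr = 0.5)
invert_extra_risk <- function(params, bmr = 0.05) {
  v <- params$v
  q <- params$q
  if (any(bmr <= 0 | bmr >= 1)) stop("`bmr` must be in (0, 1)", call. = FALSE)
  if (params$r <= 0) {
    stop("extra-risk inversion requires an increasing curve (r > 0)",
         call. = FALSE)
  }
  p0 <- v * q
  max_extra <- (v - p0) / (1 - p0)
  if (any(bmr >= max_extra)) {
    stop(sprintf(
      "bmr = %.4g is unattainable: maximum extra risk is %.4g", max(bmr),
      max_extra), call. = FALSE)
  }
  p_star <- p0 + bmr * (1 - p0)
  M <- params$h + log((p_star - p0) / (v - p_star)) / params$r
  exp(M)
}

#' Benchmark-response specification
#'
#' @param bmr Extra risk in (0, 1); default 0.05 (a 5% extra increase in
#'   downstream incidence).
#' @param lower,upper Posterior quantiles used for BMLL and BMLU; defaults
#'   0.05 and 0.95 (one-sided 95% lower-bound convention).
#' @param central `"mean"` (default) or `"median"` posterior summary
#'   reported as the BML.
#' @return A list of class `"bmr_spec"`.
#' @export
bmr_spec <- function(bmr = 0.05, lower = 0.05, upper = 0.95,
                     central = c("mean", "median")) {
  if (bmr <= 0 || bmr >= 1) stop("`bmr` must be in (0, 1)", call. = FALSE)
  stopifnot(lower > 0, upper < 1, lower < upper)
  structure(list(bmr = bmr, lower = lower, upper = upper,
                 central = match.arg(central)), class = "bmr_spec")
}

#' Posterior benchmark level of the upstream key event
#'
#' Applies [invert_extra_risk()] to every posterior draw of the
#' response-response parameters and summarizes the resulting BML
#' distribution on the natural and log scales. For a flat fit the shared
#' `(v, q, h, r)` are used; for a hierarchical fit the default `source =
#' "central"` uses only the chemical-agnostic parameters
#' `(mu_v, mu_q, mu_h, r)`, and `source = "chemical"` with `chemical =` a
#' cluster id uses that chemical's `(v_k, q_k, h_k, r)`.
#'
#' Draws for which the benchmark response is unattainable (the extra risk
#' exceeds the curve's headroom) or the slope is non-positive are dropped:
#' more than 1% of such draws triggers a warning, more than 50% an error.
#'
#' @param fit A `qaop_fit` object (see [fit_qaop()]), or a data frame of
#'   posterior draws containing columns `v`, `q`, `h`, `r` (or their
#'   `mu_`-prefixed hierarchical counterparts).
#' @param bmr A [bmr_spec()] (or a bare number, taken as the extra risk).
#' @param source `"auto"` (flat draws for flat fits, chemical-agnostic
#'   central draws for hierarchical fits), `"central"`, or `"chemical"`.
#' @param chemical Cluster id when `source = "chemical"`.
#' @return A list of class `"bml_result"` with draws and `BML`, `BMLL`,
#'   `BMLU`, `ratio` (BML/BMLL) on both scales.
#' @export
posterior_bml <- function(fit, bmr = bmr_spec(),
                          source = c("auto", "central", "chemical"),
                          chemical = NULL) {
  source <- match.arg(source)
  if (is.numeric(bmr)) bmr <- bmr_spec(bmr = bmr)
  draws <- if (inherits(fit, "qaop_fit")) fit$draws else tibble::as_tibble(fit)
  model <- if (inherits(fit, "qaop_fit")) fit$model$structure else NULL

  pick <- function(cols) {
    if (!all(cols %in% names(draws))) {
      stop("draws lack required columns: ",
           paste(setdiff(cols, names(draws)), collapse = ", "), call. = FALSE)
    }
    stats::setNames(lapply(cols, function(cl) draws[[cl]]),
                    c("v", "q", "h", "r"))
  }
  th <- if (source == "chemical") {
    if (is.null(chemical)) stop("`chemical` must be given", call. = FALSE)
    pick(c(sprintf("v[%s]", chemical), sprintf("q[%s]", chemical),
           sprintf("h[%s]", chemical), "r"))
  } else if (source == "central" ||
             (source == "auto" && identical(model, "hierarchical"))) {
    pick(c("mu_v", "mu_q", "mu_h", "r"))
  } else {
    pick(c("v", "q", "h", "r"))
  }

  S <- length(th$v)
  p0 <- th$v * th$q
  max_extra <- (th$v - p0) / (1 - p0)
  ok <- th$r > 0 & bmr$bmr < max_extra
  n_bad <- sum(!ok)
  if (n_bad > 0.5 * S) {
    stop(sprintf("benchmark response unattainable in %d/%d draws", n_bad, S),
         call. = FALSE)
  }
  if (n_bad > 0.01 * S) {
    warning(sprintf("benchmark response unattainable in %d/%d draws (dropped)",
                    n_bad, S), call. = FALSE)
  }
  v <- th$v[ok]; q <- th$q[ok]; h <- th$h[ok]; r <- th$r[ok]
  p0 <- p0[ok]
  p_star <- p0 + bmr$bmr * (1 - p0)
  log_bml <- h + log((p_star - p0) / (v - p_star)) / r
  bml_nat <- exp(log_bml)

  central_fun <- if (bmr$central == "mean") mean else stats::median
  summarize_scale <- function(x) {
    c(BML = central_fun(x),
      BMLL = unname(stats::quantile(x, bmr$lower)),
      BMLU = unname(stats::quantile(x, bmr$upper)))
  }
  nat <- summarize_scale(bml_nat)
  lg <- summarize_scale(log_bml)
  structure(list(
    draws = tibble::tibble(bml = bml_nat, log_bml = log_bml),
    natural = c(nat, ratio = unname(nat["BML"] / nat["BMLL"])),
    log = c(lg, ratio = unname(lg["BML"] / lg["BMLL"])),
    bmr = bmr, source = source, chemical = chemical,
    model = model, n_dropped = n_bad
  ), class = "bml_result")
}

#' Empirical reliability check of a benchmark level
#'
#' A BML estimate is considered empirically reliable when the ratio of its
#' central estimate to its lower bound (BML/BMLL, natural scale) falls
#' within 1-3; lower ratios indicate tighter, better-characterized
#' uncertainty. Given two results, the one with the lower ratio is
#' preferred.
#'
#' @param result A `bml_result` from [posterior_bml()].
#' @param other Optional second `bml_result` to compare against.
#' @return A list of class `"bml_reliability"` with the ratio(s), the
#'   reliability flag(s) and, when `other` is given, the preferred result.
#' @export
reliability_check <- function(result, other = NULL) {
  ratio <- unname(result$natural["ratio"])
  out <- list(ratio = ratio, reliable = ratio >= 1 & ratio <= 3)
  if (!is.null(other)) {
    ratio2 <- unname(other$natural["ratio"])
    out$other_ratio <- ratio2
    out$other_reliable <- ratio2 >= 1 & ratio2 <= 3
    out$preferred <- if (ratio <= ratio2) "first" else "second"
  }
  structure(out, class = "bml_reliability")
}

#' @export
print.bml_result <- function(x, ...) {
  cat(sprintf("Benchmark level at BMR = %.3g (extra risk)%s\n", x$bmr$bmr,
              if (!is.null(x$model)) paste0(", ", x$model, " model") else ""))
  tab <- rbind(natural = x$natural, log = x$log)
  print(round(tab, 4))
  if (x$n_dropped > 0) cat(x$n_dropped, "draws dropped (unattainable)\n")
  invisible(x)
}

#' Tidy a benchmark-level result
#'
#' @param x A `bml_result` object.
#' @param ... Unused.
#' @return A tibble with one row per scale (natural, log): BML, BMLL,
#'   BMLU and the BML/BMLL ratio.
#' @export
tidy.bml_result <- function(x, ...) {
  tibble::tibble(
    scale = c("natural", "log"),
    BML = c(x$natural["BML"], x$log["BML"]),
    BMLL = c(x$natural["BMLL"], x$log["BMLL"]),
    BMLU = c(x$natural["BMLU"], x$log["BMLU"]),
    ratio = c(x$natural["ratio"], x$log["ratio"])
  )
}
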
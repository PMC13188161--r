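#' Continuous Hill dose-response parameters
#'
#' Bundles the parameters of the four-parameter continuous Hill curve used
#' for the dose to upstream-key-event relationship, together with the two
#' variance components of the lognormal measurement model: `sigma1`, the
#' within-group standard deviation of log responses, and `sigma2`, the
#' residual standard deviation of the latent group mean around the curve.
#'
#' @param a Background response (log scale of the upstream key event).
#' @param b Maximum change; `b > 0` for increasing trends, `b < 0` for
#'   decreasing.
#' @param c Potency: the dose at which half-maximal change occurs. Must be
#'   positive.
#' @param g Power (steepness) of the sigmoid. Must be positive.
#' @param sigma1 Within-group SD on the log scale (positive).
#' @param sigma2 Residual SD of the latent group mean (non-negative).
#' @return A list of class `"continuous_hill"`.
#' @export
#' @examples
#' p <- continuous_hill_params(a = 0, b = 2, c = 50, g = 1.5)
#' hill_continuous(c(0, 50, 1e6), p)
continuous_hill_params <- function(a, b, c, g, sigma1 = 1, sigma2 = 0) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(g))
  if (c <= 0) stop("continuous Hill potency `c` must be > 0", call. = FALSE)
  if (g <= 0) stop("continuous Hill power `g` must be > 0", call. = FALSE)
  if (sigma1 <= 0) stop("`sigma1` must be > 0", call. = FALSE)
  if (sigma2 < 0) stop("`sigma2` must be >= 0", call. = FALSE)
  structure(list(a = a, b = b, c = c, g = g,
                 sigma1 = sigma1, sigma2 = sigma2),
            class = "continuous_hill")
}

#' Dichotomous Hill response-response parameters
#'
#' Parameters of the dichotomous Hill curve linking the latent log level of
#' the upstream key event to the probability of the downstream key event.
#' `v` is the maximum probability, `q` the background risk ratio (so `v * q`
#' is the background probability), `h` the potency (log upstream level of
#' half-maximal effect) and `r` the power; `r` > 0 gives an increasing
#' trend.
#'
#' @param v Maximum probability, in (0, 1].
#' @param q Background risk ratio, in [0, 1).
#' @param h Potency on the latent log upstream scale.
#' @param r Power (slope); positive for increasing trends.
#' @return A list of class `"dichotomous_hill"`.
#' @export
#' @examples
#' p <- dichotomous_hill_params(v = 0.8, q = 0.05, h = 1, r = 2)
#' hill_dichotomous(c(-10, 1, 10), p)
dichotomous_hill_params <- function(v, q, h, r) {
  stopifnot(is.numeric(v), is.numeric(q), is.numeric(h), is.numeric(r))
  if (v <= 0 || v > 1) stop("`v` must be in (0, 1]", call. = FALSE)
  if (q < 0 || q >= 1) stop("`q` must be in [0, 1)", call. = FALSE)
  structure(list(v = v, q = q, h = h, r = r), class = "dichotomous_hill")
}

#' Continuous Hill function
#'
#' Evaluates `a + b * d^g / (c^g + d^g)`. At dose 0 the value is `a`; as the
#' dose grows it approaches `a + b`; at `d = c` it is exactly `a + b / 2`.
#'
#' @param dose Vector of non-negative doses.
#' @param params A [continuous_hill_params()] object (or a named list with
#'   elements `a`, `b`, `c`, `g`).
#' @return Numeric vector of responses, same length as `dose`.
#' @export
hill_continuous <- function(dose, params) {
  if (any(dose < 0, na.rm = TRUE)) stop("`dose` must be >= 0", call. = FALSE)
  if (params$c <= 0 || params$g <= 0) {
    stop("continuous Hill parameters require c > 0 and g > 0", call. = FALSE)
  }
  # d^g / (c^g + d^g) computed on the log scale to avoid overflow at
  # extreme doses; d = 0 maps to weight 0 for any g > 0.
  w <- ifelse(dose == 0, 0,
              stats::plogis(params$g * (log(dose) - log(params$c))))
  params$a + params$b * w
}

#' Dichotomous Hill function
#'
#' Evaluates the probability of the downstream key event at latent log
#' upstream level `M`. The default (`orientation = "corrected"`) form is
#' `v * (q + e^x) / (1 + e^x)` with `x = r * (M - h)`: the probability runs
#' from the background `v * q` (as `M` falls, for `r` > 0) to the maximum
#' `v`, passing through `v * (1 + q) / 2` at `M = h`. The `"printed"`
#' orientation, `v * (1 + q * e^x) / (1 + e^x)` with `x = r * M - h`, is
#' retained for sensitivity analysis; it reverses the role of the bounds.
#'
#' @param M Vector of latent log upstream levels.
#' @param params A [dichotomous_hill_params()] object.
#' @param orientation `"corrected"` (default) or `"printed"`.
#' @return Vector of probabilities in `[0, 1]`.
#' @export
hill_dichotomous <- function(M, params,
                             orientation = c("corrected", "printed")) {
  orientation <- match.arg(orientation)
  v <- params$v
  q <- params$q
  if (v <= 0 || v > 1 || q < 0 || q >= 1) {
    stop("dichotomous Hill parameters require 0 < v <= 1 and 0 <= q < 1",
         call. = FALSE)
  }
  if (orientation == "corrected") {
    s <- stats::plogis(params$r * (M - params$h))
    v * (q + (1 - q) * s)
  } else {
    s <- stats::plogis(params$r * M - params$h)
    v * (1 - (1 - q) * s)
  }
}
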
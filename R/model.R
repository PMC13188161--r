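#' Build a flat or hierarchical qAOP model
#'
#' Assembles the joint posterior over the chemical-specific dose-response
#' parameters (`a_k`, `b_k`, `c_k`, `sigma1_k`), the global power `g` and
#' residual SD `sigma2`, one latent group mean `M_j` per dose group in the
#' union of the upstream and downstream design points, and the
#' response-response parameters — shared `(v, q, h, r)` for the flat
#' structure, or chemical-specific `(v_k, q_k, h_k)` decomposed into
#' chemical-agnostic centers plus correlated random effects (with shared
#' power `r`) for the hierarchical structure. The dose-response
#' parametrization is identical for both structures, so predictive
#' differences are attributable to the response-response calibration
#' alone.
#'
#' @param data A data frame accepted by [validate_qaop_data()].
#' @param structure `"flat"` or `"hierarchical"`.
#' @param priors A [qaop_priors()] configuration.
#' @param variance A [variance_spec()] (or the result of
#'   [constant_cv_test()]): `constant_cv` keeps one `sigma1` (per chemical
#'   if `per_chemical`), `free_per_group` gives each group its own, and
#'   `constant_sd` (constant natural-scale SD, at odds with the lognormal
#'   model) falls back to free-per-group with a warning.
#' @param orientation Dichotomous Hill orientation, see
#'   [hill_dichotomous()].
#' @param re_scale `"logistic"` (default; random effects additive on the
#'   logit scale, so `v_k`, `q_k` respect their domains by construction) or
#'   `"additive"` (raw natural-scale random effects, draws outside the
#'   domain rejected).
#' @return A list of class `"qaop_model"`.
#' @export
build_qaop_model <- function(data,
                             structure = c("flat", "hierarchical"),
                             priors = qaop_priors(),
                             variance = variance_spec(),
                             orientation = c("corrected", "printed"),
                             re_scale = c("logistic", "additive")) {
  structure_ <- match.arg(structure)
  orientation <- match.arg(orientation)
  re_scale <- match.arg(re_scale)
  data <- validate_qaop_data(data)
  if (inherits(variance, "cv_test")) variance <- variance$spec
  stopifnot(inherits(priors, "qaop_priors"),
            inherits(variance, "variance_spec"))

  chemicals <- unique(data$chemical_id)
  K <- length(chemicals)
  J <- nrow(data)
  chem_idx <- match(data$chemical_id, chemicals)

  has_up <- as.integer(!is.na(data$ke_up_mean))
  has_down <- as.integer(!is.na(data$ke_down_cases))
  m <- s <- rep(0, J)
  up <- has_up == 1
  tr <- transform_summary_to_log(data$ke_up_mean[up], data$ke_up_sd[up])
  m[up] <- tr$log_mean
  s[up] <- tr$log_sd

  s1mode <- switch(variance$mode,
    constant_cv = if (variance$per_chemical) 1L else 0L,
    free_per_group = 2L,
    constant_sd = {
      warning("constant natural-scale SD conflicts with the lognormal ",
              "measurement model; using free per-group sigma1",
              call. = FALSE)
      2L
    })

  # data-derived prior anchors, per chemical
  a0 <- b0 <- c0 <- numeric(K)
  for (k in seq_len(K)) {
    rows <- which(chem_idx == k & up)
    if (length(rows) == 0) {
      a0[k] <- 0; b0[k] <- 1; c0[k] <- 1
      next
    }
    ctrl <- rows[which.min(data$dose[rows])]
    a0[k] <- m[ctrl]
    b0[k] <- max(max(m[rows]) - m[ctrl], 0.5)
    pos <- data$dose[rows][data$dose[rows] > 0]
    c0[k] <- if (length(pos) > 0) stats::median(pos) else 1
  }

  spec <- list(
    K = K, J = J,
    hierarchical = as.integer(structure_ == "hierarchical"),
    orientation = as.integer(orientation == "printed"),
    re_scale = as.integer(re_scale == "additive"),
    s1mode = s1mode,
    chem = chem_idx - 1L,
    dose = data$dose,
    m = m, s = s,
    n1 = ifelse(up, data$ke_up_n, 1),
    X = ifelse(has_down == 1, data$ke_down_cases, 0),
    n2 = ifelse(has_down == 1, data$ke_down_n, 1),
    has_up = has_up, has_down = has_down,
    priors = list(
      a0 = a0, a_sd = priors$a_sd, b0 = b0, b_sd = priors$b_sd,
      c0 = c0, c_sd = pmax(c0, 1) * priors$c_rel_sd,
      g0 = priors$g0, g_sd = priors$g_sd,
      scale_sigma1 = priors$scale_sigma1,
      scale_sigma2 = priors$scale_sigma2,
      v_a = priors$v_a, v_b = priors$v_b,
      q_a = priors$q_a, q_b = priors$q_b,
      h_mean = priors$h_mean, h_sd = priors$h_sd,
      r_mean = priors$r_mean, r_sd = priors$r_sd,
      muv_mean = priors$muv_mean, muv_sd = priors$muv_sd,
      muq_mean = priors$muq_mean, muq_sd = priors$muq_sd,
      scale_sv = priors$scale_sv, scale_sq = priors$scale_sq,
      scale_sh = priors$scale_sh, lkj_eta = priors$lkj_eta,
      muh_mean = priors$muh_mean, muh_sd = priors$muh_sd
    )
  )
  out <- list(
    spec = spec, data = data, chemicals = chemicals,
    structure = structure_, orientation = orientation,
    re_scale = re_scale, variance = variance, priors = priors,
    n_par = qaop_n_par(spec)
  )
  class(out) <- "qaop_model"
  out
}

#' @export
print.qaop_model <- function(x, ...) {
  cat(sprintf("qAOP %s model: %d chemicals, %d dose groups, %d parameters\n",
              x$structure, x$spec$K, x$spec$J, x$n_par))
  invisible(x)
}

#' Evaluate the joint log posterior density of a qAOP model
#'
#' Mostly useful for testing and debugging: evaluates the model's joint
#' log density (likelihood of both key events, latent-mean density, priors
#' and change-of-variable terms) at a point on the unconstrained sampling
#' scale, optionally with its gradient.
#'
#' @param model A `qaop_model`.
#' @param par Numeric vector on the unconstrained scale (length
#'   `model$n_par`).
#' @param gradient Also return the gradient?
#' @return A list with `lp` and (if requested) `grad`.
#' @export
qaop_log_posterior <- function(model, par, gradient = FALSE) {
  stopifnot(inherits(model, "qaop_model"))
  qaop_log_density(par, model$spec, gradient)
}

#' Names and layout of the unconstrained parameter vector
#' @keywords internal
par_layout <- function(model) {
  sp <- model$spec
  K <- sp$K; J <- sp$J
  chem <- model$chemicals
  s1_names <- switch(as.character(sp$s1mode),
    "0" = "log_sigma1",
    "1" = paste0("log_sigma1[", chem, "]"),
    "2" = paste0("log_sigma1[g", seq_len(J), "]"))
  base <- c(paste0("a[", chem, "]"), paste0("b[", chem, "]"),
            paste0("log_c[", chem, "]"), "log_g", s1_names, "log_sigma2",
            paste0("t[", seq_len(J), "]"))
  th2 <- if (sp$hierarchical == 1) {
    c("alpha_v", "alpha_q", "log_sigma_v", "log_sigma_q", "atanh_rho",
      "mu_h", "log_sigma_h", "r",
      paste0("u_v[", chem, "]"), paste0("u_q[", chem, "]"),
      paste0("z_h[", chem, "]"))
  } else {
    c("logit_v", "logit_q", "h", "r")
  }
  c(base, th2)
}
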
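#' Prior configuration for qAOP calibration
#'
#' Weakly informative priors for every model parameter; no uniform priors
#' are used anywhere (uniform priors on benchmark-dose parameters can bias
#' the derived point of departure). Dose-response location priors are
#' normal distributions centered on data-derived anchors computed by
#' [build_qaop_model()] (`a` near the control log response, `b` near the
#' observed maximum change, `c` near the mid dose) with generous scales;
#' scale parameters carry half-Cauchy priors; in the flat model `v` and `q`
#' carry beta priors, while the hierarchical centers `mu_v`, `mu_q` carry
#' normal priors on (0, 1) and the correlation of the `(v, q)` random
#' effects an LKJ prior. Defaults were screened by prior-predictive
#' simulation (see [prior_predictive()]) so that simulated incidences span
#' (0, 1) without piling up at the edges. All hyperparameters can be
#' overridden.
#'
#' @param a_sd,b_sd SDs of the normal priors on the per-chemical Hill
#'   background `a_k` and maximum change `b_k` (log upstream scale).
#' @param c_rel_sd SD of the normal prior on the potency `c_k`, as a
#'   multiple of its data-derived anchor.
#' @param g0,g_sd Mean and SD of the normal prior on the shared power `g`
#'   (sampled on the log scale, so effectively truncated positive).
#' @param scale_sigma1,scale_sigma2 Half-Cauchy scales for the two
#'   variance components.
#' @param v_a,v_b,q_a,q_b Beta prior shapes for the flat-model `v` and `q`.
#' @param h_mean,h_sd,r_mean,r_sd Normal priors for the potency `h` (flat)
#'   and the shared power `r`.
#' @param muv_mean,muv_sd,muq_mean,muq_sd Normal priors for the
#'   hierarchical centers `mu_v`, `mu_q` (on the probability scale).
#' @param scale_sv,scale_sq,scale_sh Half-Cauchy scales of the
#'   random-effect SDs.
#' @param lkj_eta LKJ shape for the `(v, q)` random-effect correlation.
#' @param muh_mean,muh_sd Normal prior for the hierarchical potency center.
#' @return A list of class `"qaop_priors"`.
#' @export
qaop_priors <- function(a_sd = 1.5, b_sd = 1.5, c_rel_sd = 2,
                        g0 = 1.5, g_sd = 1,
                        scale_sigma1 = 1, scale_sigma2 = 1,
                        v_a = 2, v_b = 2, q_a = 2, q_b = 2,
                        h_mean = 0, h_sd = 2, r_mean = 0, r_sd = 2,
                        muv_mean = 0.5, muv_sd = 0.25,
                        muq_mean = 0.5, muq_sd = 0.25,
                        scale_sv = 0.5, scale_sq = 0.5, scale_sh = 0.5,
                        lkj_eta = 2, muh_mean = 0, muh_sd = 2) {
  out <- as.list(environment())
  structure(out, class = "qaop_priors")
}
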
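// Joint log-posterior (with analytic gradient) of the flat and
// hierarchical qAOP models on summarized multi-chemical data, plus a
// self-contained No-U-Turn HMC sampler with dual-averaging step-size and
// windowed diagonal mass-matrix adaptation.
//
// Parameterization (unconstrained sampling scale):
//   a_k, b_k               chemical-specific Hill background / max change
//   log c_k, log g         potency (per chemical) and shared power
//   log sigma1 (1|K|J)     within-group log-scale SD (variance mode)
//   log sigma2             residual SD of the latent group mean
//   t_j                    non-centered latent residuals, M_j = f1 + s2 t_j
//   flat:  logit v, logit q, h, r
//   hier:  logit mu_v, logit mu_q, log s_v, log s_q, atanh(rho),
//          mu_h, log s_h, r, u_v[K], u_q[K], z_h[K]
// In the hierarchical model z_v = u_v, z_q = rho u_v + sqrt(1-rho^2) u_q,
// and (default "logistic" random-effect scale)
//   v_k = invlogit(logit(mu_v) + s_v z_v_k), similarly q_k,
//   h_k = mu_h + s_h z_h_k.
// The "additive" variant applies the random effects on the natural scale
// and rejects draws outside the parameter domains.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>

using Rcpp::NumericVector;
using Rcpp::IntegerVector;
using Rcpp::NumericMatrix;
using Rcpp::List;
using std::vector;

static inline double invlogit(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

struct ModelData {
  int K, J;
  bool hier;
  int orientation;   // 0 corrected, 1 printed
  int re_scale;      // 0 logistic, 1 additive
  int s1mode;        // 0 shared, 1 per chemical, 2 per group
  vector<int> chem;
  vector<double> dose, m, s, n1, X, n2;
  vector<int> has_up, has_down;
  // prior hyperparameters
  vector<double> a0, b0, c0, c_sd;
  double a_sd, b_sd, g0, g_sd, tau_s1, tau_s2;
  double v_a, v_b, q_a, q_b, h_mean, h_sd, r_mean, r_sd;
  double muv_mean, muv_sd, muq_mean, muq_sd;
  double tau_sv, tau_sq, tau_sh, lkj_eta, muh_mean, muh_sd;

  int S1() const { return s1mode == 0 ? 1 : (s1mode == 1 ? K : J); }
  int n_par() const {
    int base = 3 * K + 1 + S1() + 1 + J;
    return base + (hier ? 8 + 3 * K : 4);
  }
};

static ModelData unpack_model(const List& model) {
  ModelData md;
  md.K = Rcpp::as<int>(model["K"]);
  md.J = Rcpp::as<int>(model["J"]);
  md.hier = Rcpp::as<int>(model["hierarchical"]) != 0;
  md.orientation = Rcpp::as<int>(model["orientation"]);
  md.re_scale = Rcpp::as<int>(model["re_scale"]);
  md.s1mode = Rcpp::as<int>(model["s1mode"]);
  md.chem = Rcpp::as<vector<int>>(model["chem"]);
  md.dose = Rcpp::as<vector<double>>(model["dose"]);
  md.m = Rcpp::as<vector<double>>(model["m"]);
  md.s = Rcpp::as<vector<double>>(model["s"]);
  md.n1 = Rcpp::as<vector<double>>(model["n1"]);
  md.X = Rcpp::as<vector<double>>(model["X"]);
  md.n2 = Rcpp::as<vector<double>>(model["n2"]);
  md.has_up = Rcpp::as<vector<int>>(model["has_up"]);
  md.has_down = Rcpp::as<vector<int>>(model["has_down"]);
  List pr = model["priors"];
  md.a0 = Rcpp::as<vector<double>>(pr["a0"]);
  md.b0 = Rcpp::as<vector<double>>(pr["b0"]);
  md.c0 = Rcpp::as<vector<double>>(pr["c0"]);
  md.c_sd = Rcpp::as<vector<double>>(pr["c_sd"]);
  md.a_sd = Rcpp::as<double>(pr["a_sd"]);
  md.b_sd = Rcpp::as<double>(pr["b_sd"]);
  md.g0 = Rcpp::as<double>(pr["g0"]);
  md.g_sd = Rcpp::as<double>(pr["g_sd"]);
  md.tau_s1 = Rcpp::as<double>(pr["scale_sigma1"]);
  md.tau_s2 = Rcpp::as<double>(pr["scale_sigma2"]);
  md.v_a = Rcpp::as<double>(pr["v_a"]);
  md.v_b = Rcpp::as<double>(pr["v_b"]);
  md.q_a = Rcpp::as<double>(pr["q_a"]);
  md.q_b = Rcpp::as<double>(pr["q_b"]);
  md.h_mean = Rcpp::as<double>(pr["h_mean"]);
  md.h_sd = Rcpp::as<double>(pr["h_sd"]);
  md.r_mean = Rcpp::as<double>(pr["r_mean"]);
  md.r_sd = Rcpp::as<double>(pr["r_sd"]);
  md.muv_mean = Rcpp::as<double>(pr["muv_mean"]);
  md.muv_sd = Rcpp::as<double>(pr["muv_sd"]);
  md.muq_mean = Rcpp::as<double>(pr["muq_mean"]);
  md.muq_sd = Rcpp::as<double>(pr["muq_sd"]);
  md.tau_sv = Rcpp::as<double>(pr["scale_sv"]);
  md.tau_sq = Rcpp::as<double>(pr["scale_sq"]);
  md.tau_sh = Rcpp::as<double>(pr["scale_sh"]);
  md.lkj_eta = Rcpp::as<double>(pr["lkj_eta"]);
  md.muh_mean = Rcpp::as<double>(pr["muh_mean"]);
  md.muh_sd = Rcpp::as<double>(pr["muh_sd"]);
  return md;
}

// Indices into the unconstrained parameter vector.
struct Layout {
  int K, J, S1;
  bool hier;
  int a, b, lc, lg, ls1, ls2, t, th2, uv, uq, zh, P;
  explicit Layout(const ModelData& md) {
    K = md.K; J = md.J; S1 = md.S1(); hier = md.hier;
    a = 0; b = a + K; lc = b + K; lg = lc + K;
    ls1 = lg + 1; ls2 = ls1 + S1; t = ls2 + 1; th2 = t + J;
    if (hier) { uv = th2 + 8; uq = uv + K; zh = uq + K; P = zh + K; }
    else { uv = uq = zh = -1; P = th2 + 4; }
  }
};

struct Theta2 {
  vector<double> v, q, h;      // per chemical
  double r;
  // partials of (v_k, q_k, h_k) wrt the underlying unconstrained params
  // are handled in the caller via the stored intermediates below
  vector<double> eta_v, eta_q; // logit-scale linear predictors (logistic)
  vector<double> zv, zq;
  double sv, sq, sh, rho, mu_v, mu_q, mu_h, alpha_v, alpha_q;
};

static const double LOG2PI = 1.8378770664093454836;

// Evaluate log posterior and (optionally) its gradient. Returns -Inf on
// domain violations (additive random effects outside (0,1), or pinned
// probabilities contradicting counts).
static double log_density(const ModelData& md, const vector<double>& par,
                          vector<double>* grad_out,
                          vector<double>* pointwise = nullptr) {
  const Layout L(md);
  const bool wg = grad_out != nullptr;
  vector<double> grad(wg ? L.P : 0, 0.0);
  double lp = 0.0;

  // ---- unpack
  const double* a = &par[L.a];
  const double* b = &par[L.b];
  const double* lc = &par[L.lc];
  double g = std::exp(par[L.lg]);
  vector<double> s1(L.S1);
  for (int i = 0; i < L.S1; ++i) s1[i] = std::exp(par[L.ls1 + i]);
  double s2 = std::exp(par[L.ls2]);
  const double* t = &par[L.t];

  Theta2 th;
  th.v.resize(md.K); th.q.resize(md.K); th.h.resize(md.K);
  if (!md.hier) {
    double v = invlogit(par[L.th2]);
    double q = invlogit(par[L.th2 + 1]);
    double h = par[L.th2 + 2];
    th.r = par[L.th2 + 3];
    for (int k = 0; k < md.K; ++k) { th.v[k] = v; th.q[k] = q; th.h[k] = h; }
  } else {
    th.alpha_v = par[L.th2];
    th.alpha_q = par[L.th2 + 1];
    th.sv = std::exp(par[L.th2 + 2]);
    th.sq = std::exp(par[L.th2 + 3]);
    th.rho = std::tanh(par[L.th2 + 4]);
    th.mu_h = par[L.th2 + 5];
    th.sh = std::exp(par[L.th2 + 6]);
    th.r = par[L.th2 + 7];
    th.zv.resize(md.K); th.zq.resize(md.K);
    th.eta_v.resize(md.K); th.eta_q.resize(md.K);
    double rr = std::sqrt(1.0 - th.rho * th.rho);
    for (int k = 0; k < md.K; ++k) {
      double uv = par[L.uv + k], uq = par[L.uq + k], z_h = par[L.zh + k];
      th.zv[k] = uv;
      th.zq[k] = th.rho * uv + rr * uq;
      th.h[k] = th.mu_h + th.sh * z_h;
      if (md.re_scale == 0) {
        th.eta_v[k] = th.alpha_v + th.sv * th.zv[k];
        th.eta_q[k] = th.alpha_q + th.sq * th.zq[k];
        th.v[k] = invlogit(th.eta_v[k]);
        th.q[k] = invlogit(th.eta_q[k]);
      } else {
        th.v[k] = th.alpha_v + th.sv * th.zv[k];
        th.q[k] = th.alpha_q + th.sq * th.zq[k];
        if (th.v[k] <= 0.0 || th.v[k] > 1.0 || th.q[k] < 0.0 || th.q[k] >= 1.0)
          return -std::numeric_limits<double>::infinity();
      }
    }
    if (md.re_scale == 1) {
      if (th.alpha_v <= 0.0 || th.alpha_v > 1.0 ||
          th.alpha_q < 0.0 || th.alpha_q >= 1.0)
        return -std::numeric_limits<double>::infinity();
    }
  }

  // accumulated likelihood gradients wrt derived per-chemical theta2
  vector<double> gv(md.K, 0.0), gq(md.K, 0.0), gh(md.K, 0.0);
  double gr = 0.0;

  // ---- likelihood over dose groups
  for (int j = 0; j < md.J; ++j) {
    int k = md.chem[j];
    int i1 = md.s1mode == 0 ? 0 : (md.s1mode == 1 ? k : j);
    double sig1 = s1[i1];

    double w = 0.0, wd = 0.0, dlogd = 0.0;
    if (md.dose[j] > 0.0) {
      dlogd = std::log(md.dose[j]) - lc[k];
      w = invlogit(g * dlogd);
      wd = w * (1.0 - w);
    }
    double f1 = a[k] + b[k] * w;
    double M = f1 + s2 * t[j];
    double dM = 0.0;  // d lp / d M
    double pw = 0.0;

    if (md.has_up[j]) {
      double res = md.m[j] - M;
      double quad = md.n1[j] * res * res + (md.n1[j] - 1.0) * md.s[j] * md.s[j];
      double ll = -0.5 * md.n1[j] * LOG2PI - md.n1[j] * par[L.ls1 + i1] -
                  quad / (2.0 * sig1 * sig1);
      lp += ll; pw += ll;
      if (wg) {
        dM += md.n1[j] * res / (sig1 * sig1);
        grad[L.ls1 + i1] += -md.n1[j] + quad / (sig1 * sig1);
      }
    }
    if (md.has_down[j]) {
      double x, sg, p, dp_dsg, dp_dv, dp_dq, dx_dM, dx_dh, dx_dr;
      if (md.orientation == 0) {
        x = th.r * (M - th.h[k]);
        sg = invlogit(x);
        p = th.v[k] * (th.q[k] + (1.0 - th.q[k]) * sg);
        dp_dsg = th.v[k] * (1.0 - th.q[k]);
        dp_dv = th.q[k] + (1.0 - th.q[k]) * sg;
        dp_dq = th.v[k] * (1.0 - sg);
        dx_dM = th.r; dx_dh = -th.r; dx_dr = M - th.h[k];
      } else {
        x = th.r * M - th.h[k];
        sg = invlogit(x);
        p = th.v[k] * (1.0 - (1.0 - th.q[k]) * sg);
        dp_dsg = -th.v[k] * (1.0 - th.q[k]);
        dp_dv = 1.0 - (1.0 - th.q[k]) * sg;
        dp_dq = th.v[k] * sg;
        dx_dM = th.r; dx_dh = -1.0; dx_dr = M;
      }
      const double eps = 1e-12;
      if (p < eps) p = eps;
      if (p > 1.0 - eps) p = 1.0 - eps;
      double ll = md.X[j] * std::log(p) + (md.n2[j] - md.X[j]) * std::log1p(-p);
      lp += ll; pw += ll;
      if (wg) {
        double dp = md.X[j] / p - (md.n2[j] - md.X[j]) / (1.0 - p);
        double dx = dp * dp_dsg * sg * (1.0 - sg);
        dM += dx * dx_dM;
        gh[k] += dx * dx_dh;
        gr += dx * dx_dr;
        gv[k] += dp * dp_dv;
        gq[k] += dp * dp_dq;
      }
    }
    if (pointwise) (*pointwise)[j] = pw;

    // latent residual prior t_j ~ N(0,1)
    lp += -0.5 * t[j] * t[j] - 0.5 * LOG2PI;
    if (wg) {
      grad[L.t + j] += -t[j] + dM * s2;
      grad[L.a + k] += dM;
      grad[L.b + k] += dM * w;
      grad[L.lc + k] += dM * b[k] * wd * (-g);
      grad[L.lg] += dM * b[k] * wd * dlogd * g;
      grad[L.ls2] += dM * s2 * t[j];
    }
  }

  // ---- chain per-chemical theta2 gradients into hyperparameters
  if (wg) {
    if (!md.hier) {
      double v = th.v[0], q = th.q[0];
      double sgv = 0.0, sgq = 0.0, sgh = 0.0;
      for (int k = 0; k < md.K; ++k) { sgv += gv[k]; sgq += gq[k]; sgh += gh[k]; }
      grad[L.th2] += sgv * v * (1.0 - v);
      grad[L.th2 + 1] += sgq * q * (1.0 - q);
      grad[L.th2 + 2] += sgh;
      grad[L.th2 + 3] += gr;
    } else {
      double rr = std::sqrt(1.0 - th.rho * th.rho);
      for (int k = 0; k < md.K; ++k) {
        double dv_deta, dq_deta;
        if (md.re_scale == 0) {
          dv_deta = th.v[k] * (1.0 - th.v[k]);
          dq_deta = th.q[k] * (1.0 - th.q[k]);
        } else { dv_deta = 1.0; dq_deta = 1.0; }
        double gev = gv[k] * dv_deta;  // wrt eta_v_k
        double geq = gq[k] * dq_deta;
        grad[L.th2] += gev;                       // alpha_v
        grad[L.th2 + 1] += geq;                   // alpha_q
        grad[L.th2 + 2] += gev * th.zv[k] * th.sv; // log s_v
        grad[L.th2 + 3] += geq * th.zq[k] * th.sq; // log s_q
        double gzv = gev * th.sv;
        double gzq = geq * th.sq;
        double uv = par[L.uv + k], uq = par[L.uq + k];
        grad[L.uv + k] += gzv + gzq * th.rho;
        grad[L.uq + k] += gzq * rr;
        // rho enters through z_q; chain through tanh at the end
        double dzq_drho = uv - th.rho / rr * uq;
        grad[L.th2 + 4] += gzq * dzq_drho * (1.0 - th.rho * th.rho);
        grad[L.th2 + 5] += gh[k];                 // mu_h
        grad[L.th2 + 6] += gh[k] * par[L.zh + k] * th.sh; // log s_h
        grad[L.zh + k] += gh[k] * th.sh;
      }
      grad[L.th2 + 7] += gr;
    }
  }

  // ---- priors
  auto normal_prior = [&](int idx, double val, double mean, double sd,
                          double jac_grad, double jac_lp, double dval_dpar) {
    double z = (val - mean) / sd;
    lp += -0.5 * z * z - std::log(sd) - 0.5 * LOG2PI + jac_lp;
    if (wg) grad[idx] += -z / sd * dval_dpar + jac_grad;
  };
  auto half_cauchy_log = [&](int idx, double sigma, double tau) {
    // sigma = exp(par); prior half-Cauchy(0, tau); + log Jacobian
    lp += std::log(2.0 / M_PI) + std::log(tau) -
          std::log(tau * tau + sigma * sigma) + std::log(sigma);
    if (wg) grad[idx] += -2.0 * sigma * sigma / (tau * tau + sigma * sigma) + 1.0;
  };

  for (int k = 0; k < md.K; ++k) {
    normal_prior(L.a + k, a[k], md.a0[k], md.a_sd, 0.0, 0.0, 1.0);
    normal_prior(L.b + k, b[k], md.b0[k], md.b_sd, 0.0, 0.0, 1.0);
    double ck = std::exp(lc[k]);
    normal_prior(L.lc + k, ck, md.c0[k], md.c_sd[k], 1.0, lc[k], ck);
  }
  normal_prior(L.lg, g, md.g0, md.g_sd, 1.0, par[L.lg], g);
  for (int i = 0; i < L.S1; ++i) half_cauchy_log(L.ls1 + i, s1[i], md.tau_s1);
  half_cauchy_log(L.ls2, s2, md.tau_s2);

  if (!md.hier) {
    double v = th.v[0], q = th.q[0];
    auto lbeta = [](double a, double b) {
      return std::lgamma(a) + std::lgamma(b) - std::lgamma(a + b);
    };
    // beta prior + logit Jacobian
    lp += (md.v_a - 1.0) * std::log(v) + (md.v_b - 1.0) * std::log1p(-v) -
          lbeta(md.v_a, md.v_b) + std::log(v) + std::log1p(-v);
    lp += (md.q_a - 1.0) * std::log(q) + (md.q_b - 1.0) * std::log1p(-q) -
          lbeta(md.q_a, md.q_b) + std::log(q) + std::log1p(-q);
    if (wg) {
      grad[L.th2] += (md.v_a - 1.0) * (1.0 - v) - (md.v_b - 1.0) * v +
                     1.0 - 2.0 * v;
      grad[L.th2 + 1] += (md.q_a - 1.0) * (1.0 - q) - (md.q_b - 1.0) * q +
                         1.0 - 2.0 * q;
    }
    normal_prior(L.th2 + 2, th.h[0], md.h_mean, md.h_sd, 0.0, 0.0, 1.0);
    normal_prior(L.th2 + 3, th.r, md.r_mean, md.r_sd, 0.0, 0.0, 1.0);
  } else {
    if (md.re_scale == 0) {
      double mu_v = invlogit(th.alpha_v), mu_q = invlogit(th.alpha_q);
      normal_prior(L.th2, mu_v, md.muv_mean, md.muv_sd,
                   1.0 - 2.0 * mu_v,
                   std::log(mu_v) + std::log1p(-mu_v), mu_v * (1.0 - mu_v));
      normal_prior(L.th2 + 1, mu_q, md.muq_mean, md.muq_sd,
                   1.0 - 2.0 * mu_q,
                   std::log(mu_q) + std::log1p(-mu_q), mu_q * (1.0 - mu_q));
    } else {
      normal_prior(L.th2, th.alpha_v, md.muv_mean, md.muv_sd, 0.0, 0.0, 1.0);
      normal_prior(L.th2 + 1, th.alpha_q, md.muq_mean, md.muq_sd, 0.0, 0.0, 1.0);
    }
    half_cauchy_log(L.th2 + 2, th.sv, md.tau_sv);
    half_cauchy_log(L.th2 + 3, th.sq, md.tau_sq);
    // LKJ(eta) on the 2x2 correlation + tanh Jacobian
    lp += md.lkj_eta * std::log1p(-th.rho * th.rho);
    if (wg) grad[L.th2 + 4] += -2.0 * md.lkj_eta * th.rho;
    normal_prior(L.th2 + 5, th.mu_h, md.muh_mean, md.muh_sd, 0.0, 0.0, 1.0);
    half_cauchy_log(L.th2 + 6, th.sh, md.tau_sh);
    normal_prior(L.th2 + 7, th.r, md.r_mean, md.r_sd, 0.0, 0.0, 1.0);
    for (int k = 0; k < md.K; ++k) {
      for (int off : {L.uv + k, L.uq + k, L.zh + k}) {
        lp += -0.5 * par[off] * par[off] - 0.5 * LOG2PI;
        if (wg) grad[off] += -par[off];
      }
    }
  }

  if (wg) *grad_out = grad;
  return lp;
}

// [[Rcpp::export]]
List qaop_log_density(NumericVector par, List model, bool gradient = true) {
  ModelData md = unpack_model(model);
  Layout L(md);
  if ((int)par.size() != L.P)
    Rcpp::stop("parameter vector has length %d, expected %d",
               (int)par.size(), L.P);
  vector<double> p(par.begin(), par.end());
  vector<double> grad;
  double lp = log_density(md, p, gradient ? &grad : nullptr);
  List out = List::create(Rcpp::Named("lp") = lp);
  if (gradient) out["grad"] = NumericVector(grad.begin(), grad.end());
  return out;
}

// [[Rcpp::export]]
int qaop_n_par(List model) {
  ModelData md = unpack_model(model);
  return Layout(md).P;
}

// [[Rcpp::export]]
NumericMatrix qaop_pointwise(NumericMatrix draws, List model) {
  ModelData md = unpack_model(model);
  Layout L(md);
  if (draws.ncol() != L.P) Rcpp::stop("draws have wrong number of columns");
  NumericMatrix out(draws.nrow(), md.J);
  vector<double> p(L.P);
  vector<double> pw(md.J);
  for (int sdx = 0; sdx < draws.nrow(); ++sdx) {
    for (int i = 0; i < L.P; ++i) p[i] = draws(sdx, i);
    log_density(md, p, nullptr, &pw);
    for (int j = 0; j < md.J; ++j) out(sdx, j) = pw[j];
  }
  return out;
}

// ---------------------------------------------------------------------
// NUTS sampler (Hoffman & Gelman 2014, Algorithm 6) with dual-averaging
// step-size adaptation and windowed diagonal mass-matrix estimation.

struct PSPoint {
  vector<double> q, p, grad;
  double lp;
};

struct Sampler {
  const ModelData& md;
  int P;
  std::mt19937_64 rng;
  std::normal_distribution<double> rnorm{0.0, 1.0};
  std::uniform_real_distribution<double> runif{0.0, 1.0};
  vector<double> minv;  // diagonal inverse mass (posterior variances)
  double eps;
  int n_grad_evals = 0;

  Sampler(const ModelData& md_, unsigned long seed)
      : md(md_), P(Layout(md_).P), rng(seed), minv(P, 1.0), eps(0.1) {}

  double logp_grad(const vector<double>& q, vector<double>& grad) {
    ++n_grad_evals;
    return log_density(md, q, &grad);
  }

  double kinetic(const vector<double>& p) {
    double k = 0.0;
    for (int i = 0; i < P; ++i) k += 0.5 * minv[i] * p[i] * p[i];
    return k;
  }

  void sample_momentum(vector<double>& p) {
    for (int i = 0; i < P; ++i) p[i] = rnorm(rng) / std::sqrt(minv[i]);
  }

  // one leapfrog step; returns false if the density is non-finite
  bool leapfrog(PSPoint& z, double dir) {
    double e = dir * eps;
    for (int i = 0; i < P; ++i) z.p[i] += 0.5 * e * z.grad[i];
    for (int i = 0; i < P; ++i) z.q[i] += e * minv[i] * z.p[i];
    z.lp = logp_grad(z.q, z.grad);
    if (!std::isfinite(z.lp)) return false;
    for (int i = 0; i < P; ++i) z.p[i] += 0.5 * e * z.grad[i];
    return true;
  }

  struct Tree {
    PSPoint minus, plus, sample;
    double n;       // slice-acceptable states in the subtree
    bool ok;        // no U-turn, no divergence
    double alpha;   // accumulated Metropolis acceptance statistic
    int n_alpha;
    bool divergent;
  };

  bool no_uturn(const PSPoint& minus, const PSPoint& plus) {
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < P; ++i) {
      double dq = plus.q[i] - minus.q[i];
      s1 += dq * minv[i] * minus.p[i];
      s2 += dq * minv[i] * plus.p[i];
    }
    return s1 >= 0.0 && s2 >= 0.0;
  }

  void build_tree(Tree& tr, const PSPoint& z, double log_u, double dir,
                  int depth, double H0) {
    if (depth == 0) {
      PSPoint z1 = z;
      bool finite = leapfrog(z1, dir);
      double H = finite ? z1.lp - kinetic(z1.p)
                        : -std::numeric_limits<double>::infinity();
      tr.minus = z1; tr.plus = z1; tr.sample = z1;
      tr.n = (log_u <= H) ? 1.0 : 0.0;
      tr.divergent = !finite || (log_u - 1000.0 > H);
      tr.ok = !tr.divergent;
      double a = std::exp(std::min(0.0, H - H0));
      tr.alpha = std::isfinite(a) ? a : 0.0;
      tr.n_alpha = 1;
      return;
    }
    build_tree(tr, z, log_u, dir, depth - 1, H0);
    if (!tr.ok) return;
    Tree tr2;
    if (dir < 0) {
      build_tree(tr2, tr.minus, log_u, dir, depth - 1, H0);
      tr.minus = tr2.minus;
    } else {
      build_tree(tr2, tr.plus, log_u, dir, depth - 1, H0);
      tr.plus = tr2.plus;
    }
    if (tr2.ok && tr2.n > 0 &&
        runif(rng) < tr2.n / std::max(1.0, tr.n + tr2.n)) {
      tr.sample = tr2.sample;
    }
    tr.n += tr2.n;
    tr.alpha += tr2.alpha;
    tr.n_alpha += tr2.n_alpha;
    tr.divergent = tr.divergent || tr2.divergent;
    tr.ok = tr2.ok && !tr2.divergent && no_uturn(tr.minus, tr.plus);
  }

  // one NUTS transition; returns average acceptance statistic
  double transition(PSPoint& z, int max_depth, bool& divergent) {
    sample_momentum(z.p);
    double H0 = z.lp - kinetic(z.p);
    double log_u = H0 + std::log(runif(rng));
    PSPoint zminus = z, zplus = z, zsample = z;
    double n = 1.0;
    double alpha_sum = 0.0;
    int n_alpha = 0;
    divergent = false;
    for (int depth = 0; depth < max_depth; ++depth) {
      double dir = runif(rng) < 0.5 ? -1.0 : 1.0;
      Tree tr;
      build_tree(tr, dir < 0 ? zminus : zplus, log_u, dir, depth, H0);
      alpha_sum += tr.alpha;
      n_alpha += tr.n_alpha;
      if (tr.divergent) divergent = true;
      if (!tr.ok) break;
      if (dir < 0) zminus = tr.minus; else zplus = tr.plus;
      if (tr.n > 0 && runif(rng) < std::min(1.0, tr.n / n)) {
        zsample = tr.sample;
      }
      n += tr.n;
      if (!no_uturn(zminus, zplus)) break;
    }
    z = zsample;
    return n_alpha > 0 ? alpha_sum / n_alpha : 0.0;
  }
};

// [[Rcpp::export]]
List qaop_nuts(List model, NumericVector init, int n_warmup, int n_sample,
               int seed, double adapt_delta = 0.8, int max_treedepth = 10,
               int thin = 1) {
  ModelData md = unpack_model(model);
  Layout L(md);
  if ((int)init.size() != L.P) Rcpp::stop("init has wrong length");
  Sampler smp(md, (unsigned long)seed);

  PSPoint z;
  z.q.assign(init.begin(), init.end());
  z.p.assign(L.P, 0.0);
  z.grad.assign(L.P, 0.0);
  z.lp = smp.logp_grad(z.q, z.grad);
  if (!std::isfinite(z.lp))
    Rcpp::stop("non-finite log density at initialization");

  // crude initial step size: scale until acceptance crosses 0.5
  {
    PSPoint z0 = z;
    smp.sample_momentum(z0.p);
    double H0 = z0.lp - smp.kinetic(z0.p);
    PSPoint z1 = z0;
    bool fin = smp.leapfrog(z1, 1.0);
    double H1 = fin ? z1.lp - smp.kinetic(z1.p)
                    : -std::numeric_limits<double>::infinity();
    double dir = (H1 - H0 > std::log(0.5)) ? 1.0 : -1.0;
    for (int it = 0; it < 50; ++it) {
      smp.eps *= std::pow(2.0, dir);
      z1 = z0;
      fin = smp.leapfrog(z1, 1.0);
      H1 = fin ? z1.lp - smp.kinetic(z1.p)
               : -std::numeric_limits<double>::infinity();
      double crit = H1 - H0;
      if ((dir > 0 && crit < std::log(0.5)) ||
          (dir < 0 && crit > std::log(0.5))) break;
      if (smp.eps > 1e6 || smp.eps < 1e-10) break;
    }
  }

  // dual averaging state
  double mu = std::log(10.0 * smp.eps), log_eps_bar = 0.0, H_bar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;
  auto da_restart = [&]() {
    mu = std::log(10.0 * smp.eps);
    log_eps_bar = 0.0; H_bar = 0.0; da_count = 0;
  };
  auto da_update = [&](double alpha) {
    ++da_count;
    double w = 1.0 / (da_count + t0);
    H_bar = (1.0 - w) * H_bar + w * (adapt_delta - alpha);
    double log_eps = mu - std::sqrt((double)da_count) / gamma * H_bar;
    double w2 = std::pow((double)da_count, -kappa);
    log_eps_bar = w2 * log_eps + (1.0 - w2) * log_eps_bar;
    smp.eps = std::exp(log_eps);
  };

  // mass-adaptation windows (Stan-like: 75 init, doubling windows, 50 term)
  int init_buf = 75, term_buf = 50, base_win = 25;
  if (n_warmup < 200) {
    init_buf = std::max(5, (int)(0.15 * n_warmup));
    term_buf = std::max(5, (int)(0.1 * n_warmup));
    base_win = std::max(10, n_warmup - init_buf - term_buf);
  }
  vector<int> win_ends;
  {
    int start = init_buf, w = base_win;
    while (start + w < n_warmup - term_buf) {
      win_ends.push_back(start + w);
      start += w;
      w *= 2;
    }
    win_ends.push_back(n_warmup - term_buf);
  }

  vector<vector<double>> win_buf;
  size_t widx = 0;
  int n_div_warm = 0;

  for (int it = 0; it < n_warmup; ++it) {
    bool div;
    double alpha = smp.transition(z, max_treedepth, div);
    if (div) ++n_div_warm;
    da_update(alpha);
    if (widx < win_ends.size() && it >= init_buf) win_buf.push_back(z.q);
    if (widx < win_ends.size() && it + 1 == win_ends[widx]) {
      int n = (int)win_buf.size();
      if (n >= 10) {
        for (int i = 0; i < L.P; ++i) {
          double mean = 0.0;
          for (auto& row : win_buf) mean += row[i];
          mean /= n;
          double var = 0.0;
          for (auto& row : win_buf) var += (row[i] - mean) * (row[i] - mean);
          var /= (n - 1);
          smp.minv[i] = var * n / (n + 5.0) + 1e-3 * (5.0 / (n + 5.0));
        }
      }
      win_buf.clear();
      ++widx;
      da_restart();
    }
  }
  if (da_count > 0) smp.eps = std::exp(log_eps_bar);

  int n_keep = n_sample / thin;
  NumericMatrix draws(n_keep, L.P);
  NumericVector lp_out(n_keep);
  int n_div = 0, kept = 0;
  for (int it = 0; it < n_sample; ++it) {
    bool div;
    smp.transition(z, max_treedepth, div);
    if (div) ++n_div;
    if ((it + 1) % thin == 0 && kept < n_keep) {
      for (int i = 0; i < L.P; ++i) draws(kept, i) = z.q[i];
      lp_out[kept] = z.lp;
      ++kept;
    }
  }

  return List::create(
      Rcpp::Named("draws") = draws,
      Rcpp::Named("lp") = lp_out,
      Rcpp::Named("step_size") = smp.eps,
      Rcpp::Named("divergences") = n_div,
      Rcpp::Named("divergences_warmup") = n_div_warm,
      Rcpp::Named("inv_mass") = NumericVector(smp.minv.begin(), smp.minv.end()),
      Rcpp::Named("n_grad_evals") = smp.n_grad_evals);
}
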
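#include <Rcpp.h>
using namespace Rcpp;

// Trial-by-trial variational update scheme for the three-level binary
// Hierarchical Gaussian Filter. Level 1 is the (noise-free) binary outcome,
// level 2 the log-odds of winning, level 3 the log-volatility of level 2.
// kappa couples level 3 into the level-2 step-size variance exp(kappa*mu3+omega);
// theta is the level-3 random-walk variance. A non-positive updated level-3
// precision marks the parameter set as invalid (bad_trial >= 1).

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static const double X1_EPS = 1e-8;   // clip for x1hat before sigma1/delta1
static const double P_EPS  = 1e-12;  // clip for response probabilities

// [[Rcpp::export]]
List hgf_filter_c(IntegerVector u, double kappa, double omega, double theta,
                  double mu2_0, double sigma2_0, double mu3_0, double sigma3_0) {
  int n = u.size();
  NumericMatrix out(n, 16);
  colnames(out) = CharacterVector::create(
    "x1hat", "sigma1", "mu2", "sigma2", "mu3", "sigma3",
    "delta1", "delta2", "pihat2", "pi2", "pihat3", "pi3",
    "psi2", "psi3", "sigma2_pre", "mu3_pre");

  double mu2 = mu2_0, sigma2 = sigma2_0, mu3 = mu3_0, sigma3 = sigma3_0;
  int bad_trial = -1;

  for (int k = 0; k < n; ++k) {
    double mu2_prev = mu2, sigma2_prev = sigma2;
    double mu3_prev = mu3, sigma3_prev = sigma3;

    // prediction step
    double x1hat = sigmoid(mu2_prev);
    if (x1hat < X1_EPS) x1hat = X1_EPS;
    if (x1hat > 1.0 - X1_EPS) x1hat = 1.0 - X1_EPS;
    double sigma1 = x1hat * (1.0 - x1hat);
    double delta1 = (double)u[k] - x1hat;

    // level 2
    double v2 = std::exp(kappa * mu3_prev + omega);
    double pihat2 = 1.0 / (sigma2_prev + v2);
    double pi2 = pihat2 + sigma1;            // Bernoulli observation precision
    sigma2 = 1.0 / pi2;
    mu2 = mu2_prev + delta1 / pi2;

    // level 3 (volatility)
    double pihat3 = 1.0 / (sigma3_prev + theta);
    double w2 = v2 * pihat2;
    double delta2 = (sigma2 + (mu2 - mu2_prev) * (mu2 - mu2_prev)) * pihat2 - 1.0;
    double pi3 = pihat3 + 0.5 * kappa * kappa * w2 * (w2 + (2.0 * w2 - 1.0) * delta2);
    if (!(pi3 > 0.0) || !R_finite(pi3)) { bad_trial = k + 1; break; }
    mu3 = mu3_prev + kappa / (2.0 * pi3) * w2 * delta2;
    sigma3 = 1.0 / pi3;

    out(k, 0) = x1hat;   out(k, 1) = sigma1;
    out(k, 2) = mu2;     out(k, 3) = sigma2;
    out(k, 4) = mu3;     out(k, 5) = sigma3;
    out(k, 6) = delta1;  out(k, 7) = delta2;
    out(k, 8) = pihat2;  out(k, 9) = pi2;
    out(k, 10) = pihat3; out(k, 11) = pi3;
    out(k, 12) = (1.0 / sigma1) / pi2;   // pihat1 / pi2
    out(k, 13) = pihat2 / pi3;
    out(k, 14) = sigma2_prev;            // uncertainty available pre-response
    out(k, 15) = mu3_prev;
  }

  return List::create(_["traj"] = out, _["bad_trial"] = bad_trial);
}

// [[Rcpp::export]]
List rw_filter_c(IntegerVector u, double alpha, double v0) {
  int n = u.size();
  NumericMatrix out(n, 3);
  colnames(out) = CharacterVector::create("V", "pe", "V_pre");
  double V = v0;
  for (int k = 0; k < n; ++k) {
    double pe = (double)u[k] - V;
    out(k, 2) = V;
    V += alpha * pe;
    out(k, 0) = V;
    out(k, 1) = pe;
  }
  return List::create(_["traj"] = out, _["bad_trial"] = -1);
}

static inline double softmax_unit(double x, double beta, bool centered) {
  double arg = centered ? (x - 0.5) : x;
  return sigmoid(2.0 * beta * arg);
}

// MAP objective in transformed space. Model codes: 1..4 = HGF response
// variants, 5 = Rescorla-Wagner + softmax. Parameter layout (transformed):
//   M1, M4: (omega, log theta, log beta)
//   M2, M3: (omega, log theta)
//   RW:     (logit alpha, log beta)
// Gaussian priors act on the transformed coordinates. Returns -Inf on an
// invalid filter (non-positive precision).
// [[Rcpp::export]]
double log_joint_c(NumericVector par, IntegerVector u, IntegerVector y,
                   int model, NumericVector prior_mean, NumericVector prior_sd,
                   double kappa, NumericVector init, bool centered,
                   bool include_prior) {
  int n = u.size();
  double ll = 0.0;

  if (model >= 1 && model <= 4) {
    double omega = par[0];
    double theta = std::exp(par[1]);
    double beta = (model == 1 || model == 4) ? std::exp(par[2]) : 1.0;
    List fl = hgf_filter_c(u, kappa, omega, theta, init[0], init[1], init[2], init[3]);
    if (as<int>(fl["bad_trial"]) > 0) return R_NegInf;
    NumericMatrix tr = fl["traj"];
    for (int k = 0; k < n; ++k) {
      double p;
      if (model == 1) {
        p = softmax_unit(tr(k, 0), beta, centered);
      } else if (model == 2) {
        double b = 1.0 / tr(k, 14);                 // 1 / sigma2 pre-trial
        p = softmax_unit(tr(k, 0), b, centered);
      } else if (model == 3) {
        double b = std::exp(-tr(k, 15));            // 1 / exp(mu3 pre-trial)
        p = softmax_unit(tr(k, 0), b, centered);
      } else {
        p = softmax_unit(4.0 * tr(k, 1), beta, centered);
      }
      if (p < P_EPS) p = P_EPS;
      if (p > 1.0 - P_EPS) p = 1.0 - P_EPS;
      ll += y[k] ? std::log(p) : std::log1p(-p);
    }
  } else if (model == 5) {
    double alpha = sigmoid(par[0]);
    double beta = std::exp(par[1]);
    double V = 0.5;                                  // V0 default
    for (int k = 0; k < n; ++k) {
      double p = softmax_unit(V, beta, centered);
      if (p < P_EPS) p = P_EPS;
      if (p > 1.0 - P_EPS) p = 1.0 - P_EPS;
      ll += y[k] ? std::log(p) : std::log1p(-p);
      V += alpha * ((double)u[k] - V);
    }
  } else {
    stop("unknown model code");
  }

  if (include_prior) {
    for (int j = 0; j < par.size(); ++j) {
      double z = (par[j] - prior_mean[j]) / prior_sd[j];
      ll += -0.5 * z * z - std::log(prior_sd[j]) - 0.5 * std::log(2.0 * M_PI);
    }
  }
  return ll;
}
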
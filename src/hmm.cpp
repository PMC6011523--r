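#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion for a 2-state HMM with time-varying transitions.
// dens: T x 2 state-dependent densities f_j(x_t) (linear scale);
// g12, g21: length-T off-diagonal transition probabilities, where row t of
// Gamma_t governs the step from t-1 to t (g12[0], g21[0] unused);
// delta: initial distribution (length 2).
// Returns log-likelihood.
// [[Rcpp::export]]
double hmm_forward_cpp(NumericMatrix dens, NumericVector g12,
                       NumericVector g21, NumericVector delta) {
  const int T = dens.nrow();
  double a1 = delta[0] * dens(0, 0);
  double a2 = delta[1] * dens(0, 1);
  double s = a1 + a2;
  if (!(s > 0) || !R_finite(s)) return R_NegInf;
  double ll = std::log(s);
  a1 /= s; a2 /= s;
  for (int t = 1; t < T; ++t) {
    const double p12 = g12[t], p21 = g21[t];
    const double b1 = (a1 * (1.0 - p12) + a2 * p21) * dens(t, 0);
    const double b2 = (a1 * p12 + a2 * (1.0 - p21)) * dens(t, 1);
    s = b1 + b2;
    if (!(s > 0) || !R_finite(s)) return R_NegInf;
    ll += std::log(s);
    a1 = b1 / s; a2 = b2 / s;
  }
  return ll;
}

// Viterbi decoding (log space). Returns integer path of states in {1, 2}.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logdens, NumericVector g12,
                              NumericVector g21, NumericVector delta) {
  const int T = logdens.nrow();
  IntegerVector path(T);
  std::vector<double> v1(T), v2(T);
  std::vector<int> bp1(T), bp2(T);
  v1[0] = std::log(delta[0]) + logdens(0, 0);
  v2[0] = std::log(delta[1]) + logdens(0, 1);
  for (int t = 1; t < T; ++t) {
    const double l11 = std::log(1.0 - g12[t]), l12 = std::log(g12[t]);
    const double l21 = std::log(g21[t]), l22 = std::log(1.0 - g21[t]);
    double c11 = v1[t - 1] + l11, c21 = v2[t - 1] + l21;
    if (c11 >= c21) { v1[t] = c11 + logdens(t, 0); bp1[t] = 1; }
    else            { v1[t] = c21 + logdens(t, 0); bp1[t] = 2; }
    double c12 = v1[t - 1] + l12, c22 = v2[t - 1] + l22;
    if (c12 >= c22) { v2[t] = c12 + logdens(t, 1); bp2[t] = 1; }
    else            { v2[t] = c22 + logdens(t, 1); bp2[t] = 2; }
  }
  path[T - 1] = (v1[T - 1] >= v2[T - 1]) ? 1 : 2;
  for (int t = T - 1; t >= 1; --t)
    path[t - 1] = (path[t] == 1) ? bp1[t] : bp2[t];
  return path;
}

// Forward-backward smoothing: returns T x 2 matrix of P(S_t = j | data).
// [[Rcpp::export]]
NumericMatrix hmm_fb_cpp(NumericMatrix dens, NumericVector g12,
                         NumericVector g21, NumericVector delta) {
  const int T = dens.nrow();
  NumericMatrix alpha(T, 2), post(T, 2);
  std::vector<double> scale(T);
  double a1 = delta[0] * dens(0, 0), a2 = delta[1] * dens(0, 1);
  scale[0] = a1 + a2;
  alpha(0, 0) = a1 / scale[0]; alpha(0, 1) = a2 / scale[0];
  for (int t = 1; t < T; ++t) {
    const double p12 = g12[t], p21 = g21[t];
    double b1 = (alpha(t - 1, 0) * (1.0 - p12) + alpha(t - 1, 1) * p21) * dens(t, 0);
    double b2 = (alpha(t - 1, 0) * p12 + alpha(t - 1, 1) * (1.0 - p21)) * dens(t, 1);
    scale[t] = b1 + b2;
    alpha(t, 0) = b1 / scale[t]; alpha(t, 1) = b2 / scale[t];
  }
  double bb1 = 1.0, bb2 = 1.0;
  post(T - 1, 0) = alpha(T - 1, 0); post(T - 1, 1) = alpha(T - 1, 1);
  for (int t = T - 1; t >= 1; --t) {
    const double p12 = g12[t], p21 = g21[t];
    double n1 = ((1.0 - p12) * dens(t, 0) * bb1 + p12 * dens(t, 1) * bb2) / scale[t];
    double n2 = (p21 * dens(t, 0) * bb1 + (1.0 - p21) * dens(t, 1) * bb2) / scale[t];
    bb1 = n1; bb2 = n2;
    double u1 = alpha(t - 1, 0) * bb1, u2 = alpha(t - 1, 1) * bb2;
    post(t - 1, 0) = u1 / (u1 + u2); post(t - 1, 1) = u2 / (u1 + u2);
  }
  return post;
}

// Simulate a 2-state Markov chain with time-varying transitions, given
// uniforms u (length T). Returns states in {1, 2}. u[0] draws the initial
// state from delta.
// [[Rcpp::export]]
IntegerVector hmm_simpath_cpp(NumericVector g12, NumericVector g21,
                              NumericVector delta, NumericVector u) {
  const int T = u.size();
  IntegerVector s(T);
  s[0] = (u[0] < delta[0]) ? 1 : 2;
  for (int t = 1; t < T; ++t) {
    if (s[t - 1] == 1) s[t] = (u[t] < g12[t]) ? 2 : 1;
    else               s[t] = (u[t] < g21[t]) ? 1 : 2;
  }
  return s;
}
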
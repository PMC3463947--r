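#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sig(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Synchronous Euler update of one CTRNN: outputs from the current state feed
// every neuron, then outputs are recomputed from the new state. g = 1.
// input1 is the (already gain-multiplied) external input to neuron 1.
static void ctrnn_update(int n, std::vector<double> &s, std::vector<double> &o,
                         const NumericVector &tau, const NumericMatrix &w,
                         const NumericVector &theta, double input1, double h,
                         int agent_id, int step) {
  for (int j = 0; j < n; ++j) o[j] = sig(s[j] + theta[j]);
  for (int i = 0; i < n; ++i) {
    double net = 0.0;
    for (int j = 0; j < n; ++j) net += w(j, i) * o[j];
    double I = (i == 0) ? input1 : 0.0;
    s[i] += (h / tau[i]) * (-s[i] + net + I);
    if (!std::isfinite(s[i]))
      stop("non-finite neuron state (agent %d, neuron %d) at step %d",
           agent_id, i + 1, step);
  }
  for (int j = 0; j < n; ++j) o[j] = sig(s[j] + theta[j]);
}

// One coupled two-agent episode. Neuron roles: 1 receptor, 2 movement,
// 3 left button, 4 right button. Both controllers are clones; agent 2's
// motor effects are mirrored (multiplied by -1). Per step: sense on the
// previous step's positions, update both networks, then apply both motions
// and clicks. One N(0, noise_sd) draw per agent per step is added to the
// mapped movement output before the effector gain (agent 1 drawn first),
// taken from R's RNG so a run is reproducible from set.seed().
// [[Rcpp::export]]
List run_trial_core(int steps, double h, NumericVector tau, NumericMatrix w,
                    NumericVector theta, double r_gain, double e_move,
                    double e_left, double e_right, double rf1_0, double rf2_0,
                    double d1_0, double d2_0, double noise_sd,
                    double threshold, double contact_radius) {
  const int n = tau.size();
  if (n < 4) stop("embodied controller needs at least 4 neurons");
  std::vector<double> s1(n, 0.0), s2(n, 0.0), o1(n), o2(n);
  double rf1 = rf1_0, rf2 = rf2_0, d1 = d1_0, d2 = d2_0;
  bool on1L = false, on1R = false, on2L = false, on2R = false;

  NumericMatrix out1(steps, n), out2(steps, n);
  NumericVector rf1s(steps), rf2s(steps), d1s(steps), d2s(steps);
  IntegerVector c1s(steps), c2s(steps), cl1L(steps), cl1R(steps),
      cl2L(steps), cl2R(steps);

  RNGScope scope;
  for (int t = 0; t < steps; ++t) {
    // sense: RF of one agent against BO of the other, inclusive radius
    int c1 = (std::fabs(rf1 - (rf2 + d2)) <= contact_radius) ? 1 : 0;
    int c2 = (std::fabs(rf2 - (rf1 + d1)) <= contact_radius) ? 1 : 0;

    ctrnn_update(n, s1, o1, tau, w, theta, r_gain * c1, h, 1, t + 1);
    ctrnn_update(n, s2, o2, tau, w, theta, r_gain * c2, h, 2, t + 1);

    double z1 = norm_rand(), z2 = norm_rand();
    double v1 = e_move * (2.0 * o1[1] - 1.0 + noise_sd * z1);
    double v2 = e_move * (2.0 * o2[1] - 1.0 + noise_sd * z2);
    rf1 += h * v1;        // mirror +1
    rf2 += -h * v2;       // mirror -1

    // buttons: on at output >= threshold, off below; click = off->on only.
    // Left applied before right within a step.
    bool n1L = o1[2] >= threshold, n1R = o1[3] >= threshold;
    bool n2L = o2[2] >= threshold, n2R = o2[3] >= threshold;
    int e1L = (n1L && !on1L), e1R = (n1R && !on1R);
    int e2L = (n2L && !on2L), e2R = (n2R && !on2R);
    if (e1L) d1 -= e_left;   // mirror +1: left shifts BO leftward
    if (e1R) d1 += e_right;
    if (e2L) d2 += e_left;   // mirror -1: egocentric left is allocentric right
    if (e2R) d2 -= e_right;
    on1L = n1L; on1R = n1R; on2L = n2L; on2R = n2R;

    rf1s[t] = rf1; rf2s[t] = rf2; d1s[t] = d1; d2s[t] = d2;
    c1s[t] = c1; c2s[t] = c2;
    cl1L[t] = e1L; cl1R[t] = e1R; cl2L[t] = e2L; cl2R[t] = e2R;
    for (int j = 0; j < n; ++j) { out1(t, j) = o1[j]; out2(t, j) = o2[j]; }
  }

  return List::create(
      _["rf1"] = rf1s, _["rf2"] = rf2s, _["d1"] = d1s, _["d2"] = d2s,
      _["contact1"] = c1s, _["contact2"] = c2s, _["o_agent1"] = out1,
      _["o_agent2"] = out2, _["clickL1"] = cl1L, _["clickR1"] = cl1R,
      _["clickL2"] = cl2L, _["clickR2"] = cl2R);
}

// Euler-integrate a CTRNN under a constant clamped input vector until the
// sup-norm of s-dot falls below tol or the step budget is exhausted.
// [[Rcpp::export]]
List ctrnn_settle(NumericVector s0, NumericVector tau, NumericMatrix w,
                  NumericVector theta, NumericVector input, double h,
                  double tol, double max_steps) {
  const int n = s0.size();
  std::vector<double> s(s0.begin(), s0.end()), o(n), ds(n);
  bool converged = false;
  double used = 0;
  for (double t = 0; t < max_steps; ++t) {
    for (int j = 0; j < n; ++j) o[j] = sig(s[j] + theta[j]);
    double mx = 0.0;
    for (int i = 0; i < n; ++i) {
      double net = 0.0;
      for (int j = 0; j < n; ++j) net += w(j, i) * o[j];
      ds[i] = (-s[i] + net + input[i]) / tau[i];
      double a = std::fabs(ds[i]);
      if (a > mx) mx = a;
    }
    if (!std::isfinite(mx)) stop("non-finite state during settling");
    if (mx < tol) { converged = true; used = t; break; }
    for (int i = 0; i < n; ++i) s[i] += h * ds[i];
    used = t + 1;
  }
  return List::create(_["s"] = NumericVector(s.begin(), s.end()),
                      _["converged"] = converged, _["steps"] = used);
}
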
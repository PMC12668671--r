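// Receding-horizon tree search with nested-CVaR backups.
//
// The recursion mirrors the R module surface exactly: edge rewards
// (imagined exploration reward on object turns, travel cost on
// approach/retreat, dying cost on the dead transition), branch-local
// belief/pool updates on imagined safe continuations, and one CVaR
// distortion per chance stage. Kept in compiled code because the simulator
// and ABC-SMC call the planner hundreds of thousands of times.

#include <Rcpp.h>
#include <algorithm>
#include <array>

namespace {

enum State { NEST = 0, CAU_OBJ = 1, CON_OBJ = 2,
             CAU_DET = 4, CON_DET = 5, DEAD = 6 };

struct Params {
  double omega_cau, omega_con, base, f, G0;
  double travel, dying, p1, p2, gamma, alpha;
};

typedef std::array<double, 3> Counts;  // pseudocounts for tau = 2, 3, 4

// Greedy solution of min_{xi in U(alpha)} sum xi_i p_i v_i over the CVaR
// risk envelope {0 <= xi <= 1/alpha, sum xi p = 1}, for two outcomes.
double distort2(double v0, double p0, double v1, double p1, double alpha) {
  double cap = 1.0 / alpha;
  double lo_v = v0, lo_p = p0, hi_v = v1, hi_p = p1;
  if (v1 < v0) { lo_v = v1; lo_p = p1; hi_v = v0; hi_p = p0; }
  double mass = 0.0, total = 0.0;
  if (lo_p > 0) {
    double xi = std::min(cap, 1.0 / lo_p);
    mass = xi * lo_p;
    total = mass * lo_v;
  }
  if (mass < 1.0 && hi_p > 0) {
    double xi = std::min(cap, (1.0 - mass) / hi_p);
    total += xi * hi_p * hi_v;
  }
  return total;
}

double value(int s, int tau, const Counts &a, const Counts &b, double G,
             int depth, const Params &P);

// Cumulative noisy-or hazard at stay length tau under the current belief:
// h(tau) = 1 - prod_{j=2..tau} (1 - mu_j), with mu_1 = 0 structurally.
double hazard_at(int tau, const Counts &a, const Counts &b) {
  double surv = 1.0;
  for (int j = 0; j < tau - 1; ++j) surv *= 1.0 - a[j] / (a[j] + b[j]);
  return 1.0 - surv;
}

// Resolution of an (imagined) detect chance node: escape fails with
// probability p_die, leading to the absorbing dead state.
double detect_value(bool confident, const Counts &a, const Counts &b,
                    double G, int depth, const Params &P) {
  double p_die = confident ? P.p1 : P.p2;
  double Gn = std::min(G + P.f, P.G0);
  double v_dead = P.dying;  // dead is absorbing with value 0
  double v_esc = P.gamma * value(NEST, 0, a, b, Gn, depth - 1, P);
  return distort2(v_dead, p_die, v_esc, 1.0 - p_die, P.alpha);
}

double value(int s, int tau, const Counts &a, const Counts &b, double G,
             int depth, const Params &P) {
  if (depth <= 0 || s == DEAD) return 0.0;
  if (s == CAU_DET || s == CON_DET)
    return detect_value(s == CON_DET, a, b, G, depth, P);

  double Gn_idle = std::min(G + P.f, P.G0);

  if (s == NEST) {
    double best = P.gamma * value(NEST, 0, a, b, Gn_idle, depth - 1, P);
    for (int conf = 0; conf <= 1; ++conf) {
      double om = conf ? P.omega_con : P.omega_cau;
      double r = P.travel + om * G + P.base;
      double Gn = std::min((1.0 - om) * G + P.f, P.G0);
      double q = r + P.gamma * value(conf ? CON_OBJ : CAU_OBJ, 1, a, b, Gn,
                                     depth - 1, P);
      if (q > best) best = q;
    }
    return best;
  }

  // object states
  bool conf = (s == CON_OBJ);
  double om = conf ? P.omega_con : P.omega_cau;
  double best = -std::numeric_limits<double>::infinity();
  if (tau < 4) {  // stay_object
    double q = hazard_at(tau + 1, a, b);
    double v_det = P.gamma *
        value(conf ? CON_DET : CAU_DET, tau + 1, a, b, Gn_idle, depth - 1, P);
    Counts b2 = b;
    b2[tau - 1] += 1.0;
    double Gn = std::min((1.0 - om) * G + P.f, P.G0);
    double r = om * G + P.base;
    double v_safe = r + P.gamma * value(s, tau + 1, a, b2, Gn, depth - 1, P);
    best = distort2(v_det, q, v_safe, 1.0 - q, P.alpha);
  }
  if (tau >= 2) {  // retreat: one-turn transition back to the nest
    double q = P.travel + P.gamma * value(NEST, 0, a, b, Gn_idle,
                                          depth - 1, P);
    if (q > best) best = q;
  }
  return best;
}

Counts as_counts(const Rcpp::NumericVector &x) {
  Counts c;
  for (int i = 0; i < 3; ++i) c[i] = x[i];
  return c;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector plan_values_cpp(
    int state, int tau, Rcpp::NumericVector a, Rcpp::NumericVector b,
    double G, double omega_cau, double omega_con, double base, double f,
    double G0, double travel, double dying, double p1, double p2,
    double gamma, double alpha, int depth) {
  Params P{omega_cau, omega_con, base, f, G0,
           travel, dying, p1, p2, gamma, alpha};
  Counts ca = as_counts(a), cb = as_counts(b);
  std::vector<double> q;

  double Gn_idle = std::min(G + f, G0);
  if (state == NEST) {
    q.push_back(gamma * value(NEST, 0, ca, cb, Gn_idle, depth - 1, P));
    for (int conf = 0; conf <= 1; ++conf) {
      double om = conf ? omega_con : omega_cau;
      double r = travel + om * G + base;
      double Gn = std::min((1.0 - om) * G + f, G0);
      q.push_back(r + gamma * value(conf ? CON_OBJ : CAU_OBJ, 1, ca, cb, Gn,
                                    depth - 1, P));
    }
  } else if (state == CAU_OBJ || state == CON_OBJ) {
    bool conf = (state == CON_OBJ);
    double om = conf ? omega_con : omega_cau;
    if (tau < 4) {
      double qdet = hazard_at(tau + 1, ca, cb);
      double v_det = gamma * value(conf ? CON_DET : CAU_DET, tau + 1, ca, cb,
                                   Gn_idle, depth - 1, P);
      Counts b2 = cb;
      b2[tau - 1] += 1.0;
      double Gn = std::min((1.0 - om) * G + f, G0);
      double r = om * G + base;
      double v_safe = r + gamma * value(state, tau + 1, ca, b2, Gn,
                                        depth - 1, P);
      q.push_back(distort2(v_det, qdet, v_safe, 1.0 - qdet, alpha));
    }
    if (tau >= 2) {
      q.push_back(travel + gamma * value(NEST, 0, ca, cb, Gn_idle,
                                         depth - 1, P));
    }
  } else {
    Rcpp::stop("planning must start from a real state");
  }
  return Rcpp::wrap(q);
}
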
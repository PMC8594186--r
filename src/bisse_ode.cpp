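// BiSSE pruning likelihood with per-branch adaptive Runge-Kutta integration.
//
// State vector y = (E0, E1, D0, D1): extinction probabilities and partial
// likelihoods for the low (0) and high (1) activity states. Time runs from
// the tips (0) toward the root; epoch multipliers rescale both speciation
// rates in epochs older than each change-point boundary.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Rates {
  double l0, l1, m0, m1, q01, q10;
};

static inline void deriv(const Rates &r, double mult, const double *y,
                         double *dy) {
  const double l0 = r.l0 * mult, l1 = r.l1 * mult;
  const double E0 = y[0], E1 = y[1], D0 = y[2], D1 = y[3];
  dy[0] = r.m0 - (l0 + r.m0 + r.q01) * E0 + r.q01 * E1 + l0 * E0 * E0;
  dy[1] = r.m1 - (l1 + r.m1 + r.q10) * E1 + r.q10 * E0 + l1 * E1 * E1;
  dy[2] = -(l0 + r.m0 + r.q01) * D0 + r.q01 * D1 + 2.0 * l0 * E0 * D0;
  dy[3] = -(l1 + r.m1 + r.q10) * D1 + r.q10 * D0 + 2.0 * l1 * E1 * D1;
}

// Cash-Karp embedded RK45 step: y -> y + h * f, err = 4th/5th order gap.
static inline void ck_step(const Rates &r, double mult, const double *y,
                           double h, double *yout, double *yerr) {
  static const double b21 = 0.2, b31 = 3.0 / 40.0, b32 = 9.0 / 40.0,
                      b41 = 0.3, b42 = -0.9, b43 = 1.2,
                      b51 = -11.0 / 54.0, b52 = 2.5, b53 = -70.0 / 27.0,
                      b54 = 35.0 / 27.0, b61 = 1631.0 / 55296.0,
                      b62 = 175.0 / 512.0, b63 = 575.0 / 13824.0,
                      b64 = 44275.0 / 110592.0, b65 = 253.0 / 4096.0,
                      c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                      c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0,
                      dc1 = c1 - 2825.0 / 27648.0,
                      dc3 = c3 - 18575.0 / 48384.0,
                      dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
                      dc6 = c6 - 0.25;
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], tmp[4];
  deriv(r, mult, y, k1);
  for (int i = 0; i < 4; ++i) tmp[i] = y[i] + h * b21 * k1[i];
  deriv(r, mult, tmp, k2);
  for (int i = 0; i < 4; ++i)
    tmp[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
  deriv(r, mult, tmp, k3);
  for (int i = 0; i < 4; ++i)
    tmp[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
  deriv(r, mult, tmp, k4);
  for (int i = 0; i < 4; ++i)
    tmp[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] +
                         b54 * k4[i]);
  deriv(r, mult, tmp, k5);
  for (int i = 0; i < 4; ++i)
    tmp[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                         b64 * k4[i] + b65 * k5[i]);
  deriv(r, mult, tmp, k6);
  for (int i = 0; i < 4; ++i) {
    yout[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
    yerr[i] = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] + dc5 * k5[i] +
                   dc6 * k6[i]);
  }
}

// Integrate y over an interval of length len with constant multiplier.
// Returns false on integration failure.
static bool integrate_segment(const Rates &r, double mult, double *y,
                              double len, double rtol, double atol) {
  if (len <= 0.0) return true;
  // rate scale bounds the initial step
  double scale = (r.l0 + r.l1) * mult + r.m0 + r.m1 + r.q01 + r.q10;
  double h = (scale > 0.0) ? std::min(len, 0.1 / scale) : len;
  double t = 0.0;
  const int max_steps = 1000000;
  double ynew[4], yerr[4];
  for (int step = 0; step < max_steps; ++step) {
    if (t >= len) return true;
    if (h > len - t) h = len - t;
    ck_step(r, mult, y, h, ynew, yerr);
    double errmax = 0.0;
    for (int i = 0; i < 4; ++i) {
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double e = std::fabs(yerr[i]) / sc;
      if (e > errmax) errmax = e;
    }
    if (!std::isfinite(errmax)) return false;
    if (errmax <= 1.0) {
      t += h;
      for (int i = 0; i < 4; ++i) y[i] = ynew[i];
      double fac = (errmax > 0.0)
                       ? 0.9 * std::pow(errmax, -0.2)
                       : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
      // keep E inside [0,1] against round-off
      for (int i = 0; i < 2; ++i) {
        if (y[i] < 0.0) y[i] = 0.0;
        if (y[i] > 1.0) y[i] = 1.0;
      }
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < 1e-14 * len) return false;
    }
  }
  return false;
}

// multiplier in effect at time-before-present t. cp_times ascending;
// cp_mult[k] applies on [cp_times[k], cp_times[k+1]).
static inline double mult_at(double t, const NumericVector &cp_times,
                             const NumericVector &cp_mult) {
  double m = 1.0;
  for (int k = 0; k < cp_times.size(); ++k) {
    if (t >= cp_times[k]) m = cp_mult[k]; else break;
  }
  return m;
}

// Integrate a branch from time t0 (tipward) to t1 (rootward), splitting at
// change-point boundaries so the multiplier is constant per segment.
static bool integrate_branch(const Rates &r, double *y, double t0, double t1,
                             const NumericVector &cp_times,
                             const NumericVector &cp_mult, double rtol,
                             double atol) {
  if (cp_times.size() == 0) {
    return integrate_segment(r, 1.0, y, t1 - t0, rtol, atol);
  }
  double cur = t0;
  while (cur < t1) {
    double nxt = t1;
    for (int k = 0; k < cp_times.size(); ++k) {
      if (cp_times[k] > cur && cp_times[k] < nxt) nxt = cp_times[k];
    }
    double m = mult_at(cur, cp_times, cp_mult);
    if (!integrate_segment(r, m, y, nxt - cur, rtol, atol)) return false;
    cur = nxt;
  }
  return true;
}

// [[Rcpp::export]]
List bisse_pruning_cpp(IntegerMatrix edge, NumericVector edge_length,
                       int n_tip, IntegerVector tip_state, NumericVector pars,
                       NumericVector node_time, NumericVector cp_times,
                       NumericVector cp_mult, double rtol, double atol) {
  const Rates r = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5]};
  const int n_node = node_time.size();
  const int n_edge = edge.nrow();
  std::vector<double> E0(n_node, 0.0), E1(n_node, 0.0);
  std::vector<double> D0(n_node, 0.0), D1(n_node, 0.0);
  std::vector<int> seen(n_node, 0);
  double logcomp = 0.0;

  // tip initialisation: D = 1 for the observed state, both 1 when unknown
  for (int i = 0; i < n_tip; ++i) {
    int s = tip_state[i];
    if (s == NA_INTEGER) {
      D0[i] = 1.0;
      D1[i] = 1.0;
    } else if (s == 0) {
      D0[i] = 1.0;
    } else {
      D1[i] = 1.0;
    }
  }

  // edges are supplied in postorder: children before parents
  for (int e = 0; e < n_edge; ++e) {
    int par = edge(e, 0) - 1;
    int child = edge(e, 1) - 1;
    double y[4] = {E0[child], E1[child], D0[child], D1[child]};
    double t0 = node_time[child];
    double t1 = node_time[par];
    if (t1 < t0) t1 = t0;  // guard tiny negative slack on near-ultrametric trees
    if (!integrate_branch(r, y, t0, t1, cp_times, cp_mult, rtol, atol)) {
      return List::create(_["ok"] = false, _["node"] = child + 1);
    }
    // clamp small negative D from round-off; larger negatives are an error
    for (int i = 2; i < 4; ++i) {
      if (y[i] < 0.0) {
        if (y[i] > -1e-12) y[i] = 0.0;
        else return List::create(_["ok"] = false, _["node"] = child + 1);
      }
    }
    if (!seen[par]) {
      E0[par] = y[0];
      E1[par] = y[1];
      D0[par] = y[2];
      D1[par] = y[3];
      seen[par] = 1;
    } else {
      // join: D_i = lambda_i(t) * D_left_i * D_right_i; E averaged over
      // children (equal in exact arithmetic; averaging preserves symmetry)
      double m = mult_at(t1, cp_times, cp_mult);
      E0[par] = 0.5 * (E0[par] + y[0]);
      E1[par] = 0.5 * (E1[par] + y[1]);
      D0[par] = r.l0 * m * D0[par] * y[2];
      D1[par] = r.l1 * m * D1[par] * y[3];
      double tot = D0[par] + D1[par];
      if (tot > 0.0 && std::isfinite(tot)) {
        D0[par] /= tot;
        D1[par] /= tot;
        logcomp += std::log(tot);
      } else if (!std::isfinite(tot)) {
        return List::create(_["ok"] = false, _["node"] = par + 1);
      }
    }
  }

  int root = edge(n_edge - 1, 0) - 1;
  return List::create(
      _["ok"] = true, _["logcomp"] = logcomp,
      _["D"] = NumericVector::create(D0[root], D1[root]),
      _["E"] = NumericVector::create(E0[root], E1[root]),
      _["root_mult"] = mult_at(node_time[root], cp_times, cp_mult));
}
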
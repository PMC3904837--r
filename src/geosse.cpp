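// GeoSSE pruning core: six coupled ODEs (E_T, E_R, E_W, D_T, D_R, D_W)
// integrated along branches with an adaptive Dormand-Prince 5(4) scheme,
// plus the full postorder tree traversal.
//
// State/index convention (fixed across the package):
//   0 = TEMPERATE endemic, 1 = TROPICAL endemic, 2 = WIDESPREAD.
// Parameter vector (length 9):
//   [0] sA  within-temperate speciation rate at present (lambda_temp)
//   [1] sB  within-tropical speciation rate at present (lambda_trop)
//   [2] sAB biome-divergence speciation rate (lambda_TT), time-constant
//   [3] xA  temperate extinction / range-contraction rate (mu_temp)
//   [4] xB  tropical extinction / range-contraction rate (mu_trop)
//   [5] dA  range expansion temperate -> widespread (d_temp)
//   [6] dB  range expansion tropical -> widespread (d_trop)
//   [7] rA  linear slope of lambda_temp in t (age, Myr before present)
//   [8] rB  linear slope of lambda_trop
// lambda_temp(t) = sA + rA * t with t = 0 at the present increasing into
// the past; the caller guarantees nonnegativity over the tree height.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline void geosse_deriv(double t, const double* y, double* dy,
                                const double* p) {
  const double lamA = p[0] + p[7] * t;
  const double lamB = p[1] + p[8] * t;
  const double sAB = p[2], xA = p[3], xB = p[4], dA = p[5], dB = p[6];

  const double EA = y[0], EB = y[1], EW = y[2];
  const double DA = y[3], DB = y[4], DW = y[5];

  dy[0] = xA - (lamA + dA + xA) * EA + dA * EW + lamA * EA * EA;
  dy[1] = xB - (lamB + dB + xB) * EB + dB * EW + lamB * EB * EB;
  dy[2] = -(lamA + lamB + sAB + xA + xB) * EW + xA * EB + xB * EA
          + lamA * EA * EW + lamB * EB * EW + sAB * EA * EB;
  dy[3] = -(lamA + dA + xA) * DA + dA * DW + 2.0 * lamA * DA * EA;
  dy[4] = -(lamB + dB + xB) * DB + dB * DW + 2.0 * lamB * DB * EB;
  dy[5] = -(lamA + lamB + sAB + xA + xB) * DW + xA * DB + xB * DA
          + lamA * (EA * DW + EW * DA) + lamB * (EB * DW + EW * DB)
          + sAB * (EA * DB + EB * DA);
}

// Dormand-Prince 5(4) with PI-free elementary step-size control.
// Integrates y over [t0, t1] (t1 > t0). Returns false on failure.
static bool dopri5(double t0, double t1, double* y, const double* p,
                   double rtol, double atol) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double a71 = 35.0 / 384, a73 = 500.0 / 1113,
                      a74 = 125.0 / 192, a75 = -2187.0 / 6784,
                      a76 = 11.0 / 84;
  // embedded 4th-order error weights (b5 - b4)
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695,
                      e4 = 71.0 / 1920, e5 = -17253.0 / 339200,
                      e6 = 22.0 / 525, e7 = -1.0 / 40;
  const int n = 6;
  double k1[6], k2[6], k3[6], k4[6], k5[6], k6[6], k7[6], yt[6], ynew[6];

  double t = t0;
  double span = t1 - t0;
  if (span <= 0.0) return span == 0.0;
  double h = span / 10.0;
  if (h > 1.0) h = 1.0;
  long steps = 0;
  const long max_steps = 1000000L;
  bool have_k1 = false;

  while (t < t1) {
    if (++steps > max_steps) return false;
    if (t + h > t1) h = t1 - t;
    if (!have_k1) geosse_deriv(t, y, k1, p);

    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * a21 * k1[i];
    geosse_deriv(t + c2 * h, yt, k2, p);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    geosse_deriv(t + c3 * h, yt, k3, p);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    geosse_deriv(t + c4 * h, yt, k4, p);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i]
                          + a54 * k4[i]);
    geosse_deriv(t + c5 * h, yt, k5, p);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i]
                          + a64 * k4[i] + a65 * k5[i]);
    geosse_deriv(t + h, yt, k6, p);
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + h * (a71 * k1[i] + a73 * k3[i] + a74 * k4[i]
                            + a75 * k5[i] + a76 * k6[i]);
    geosse_deriv(t + h, ynew, k7, p);

    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i]
                       + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]),
                                         std::fabs(ynew[i]));
      double r = ei / sc;
      err += r * r;
    }
    err = std::sqrt(err / n);
    if (!std::isfinite(err)) return false;

    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < n; ++i) {
        y[i] = ynew[i];
        k1[i] = k7[i];  // FSAL
      }
      have_k1 = true;
      // keep extinction probabilities in [0,1] against roundoff drift
      for (int i = 0; i < 3; ++i) {
        if (y[i] < 0.0 && y[i] > -1e-10) y[i] = 0.0;
        if (y[i] > 1.0 && y[i] < 1.0 + 1e-10) y[i] = 1.0;
      }
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < 1e-14 * span) return false;
  }
  return true;
}

// [[Rcpp::export]]
NumericVector geosse_branch_cpp(NumericVector y0, double t0, double t1,
                                NumericVector pars, double rtol,
                                double atol) {
  if (y0.size() != 6) stop("state vector must have length 6");
  if (pars.size() != 9) stop("parameter vector must have length 9");
  if (t1 < t0) stop("t_old must be >= t_young");
  double y[6];
  for (int i = 0; i < 6; ++i) y[i] = y0[i];
  if (!dopri5(t0, t1, y, REAL(pars), rtol, atol))
    stop("ODE integration failed on branch [%g, %g]", t0, t1);
  NumericVector out(6);
  for (int i = 0; i < 6; ++i) out[i] = y[i];
  return out;
}

static inline void combine(const double* Dl, const double* Dr,
                           double lamA, double lamB, double sAB,
                           double* Dout) {
  Dout[0] = lamA * Dl[0] * Dr[0];
  Dout[1] = lamB * Dl[1] * Dr[1];
  Dout[2] = 0.5 * (lamA * (Dl[0] * Dr[2] + Dl[2] * Dr[0])
                   + lamB * (Dl[1] * Dr[2] + Dl[2] * Dr[1])
                   + sAB * (Dl[0] * Dr[1] + Dl[1] * Dr[0]));
}

// Full postorder pruning likelihood.
//   edge: 2-column integer matrix in postorder (ape node ids, 1-based)
//   ages: node ages (Myr before present), length = n_tip + n_internal
//   tip_state: 0/1/2 per tip id 1..n_tip
//   f: sampling fractions (f_temp, f_trop, f_wide)
//   root_mode: 0 = likelihood-weighted (FitzJohn), 1 = equal weights,
//              2 = fixed state (root_state 0/1/2)
// Returns log-likelihood (possibly -Inf).
// [[Rcpp::export]]
double geosse_loglik_cpp(IntegerMatrix edge, int n_tip, NumericVector ages,
                         IntegerVector tip_state, NumericVector f,
                         NumericVector pars, int root_mode, int root_state,
                         bool condition_surv, double rtol, double atol) {
  const int n_node = ages.size();
  const double* p = REAL(pars);

  std::vector<double> E(3 * n_node), D(3 * n_node);
  std::vector<double> logcomp(n_node, 0.0);
  std::vector<int> seen(n_node, 0);

  for (int i = 0; i < edge.nrow(); ++i) {
    const int parent = edge(i, 0) - 1;
    const int child = edge(i, 1) - 1;

    double y[6];
    double child_log = 0.0;
    if (child < n_tip) {
      const int st = tip_state[child];
      y[0] = 1.0 - f[0];
      y[1] = 1.0 - f[1];
      y[2] = 1.0 - f[2];
      y[3] = y[4] = y[5] = 0.0;
      y[3 + st] = f[st];
    } else {
      if (seen[child] != 2)
        stop("internal error: node %d reached before its children",
             child + 1);
      for (int k = 0; k < 3; ++k) {
        y[k] = E[3 * child + k];
        y[3 + k] = D[3 * child + k];
      }
      child_log = logcomp[child];
    }

    const double t0 = ages[child], t1 = ages[parent];
    if (!dopri5(t0, t1, y, p, rtol, atol))
      stop("ODE integration failed on the branch above node %d", child + 1);

    double s = y[3] + y[4] + y[5];
    if (!std::isfinite(s) || s < 0.0)
      stop("non-finite subtree density above node %d", child + 1);
    if (s == 0.0) return R_NegInf;
    double blog = child_log + std::log(s);
    for (int k = 0; k < 3; ++k) y[3 + k] /= s;

    if (!seen[parent]) {
      for (int k = 0; k < 3; ++k) {
        E[3 * parent + k] = y[k];
        D[3 * parent + k] = y[3 + k];
      }
      logcomp[parent] = blog;
      seen[parent] = 1;
    } else if (seen[parent] == 1) {
      const double tn = ages[parent];
      const double lamA = p[0] + p[7] * tn;
      const double lamB = p[1] + p[8] * tn;
      double Dn[3];
      combine(&D[3 * parent], &y[3], lamA, lamB, p[2], Dn);
      for (int k = 0; k < 3; ++k) D[3 * parent + k] = Dn[k];
      // E carried from the first child (children agree at the node age)
      logcomp[parent] += blog;
      seen[parent] = 2;
    } else {
      stop("non-binary node %d encountered", parent + 1);
    }
  }

  // root = parent of the last postorder edge
  const int root = edge(edge.nrow() - 1, 0) - 1;
  if (seen[root] != 2) stop("root node was not fully combined");

  const double t_root = ages[root];
  const double lamA = p[0] + p[7] * t_root;
  const double lamB = p[1] + p[8] * t_root;
  double lam_root[3] = {lamA, lamB, lamA + lamB + p[2]};

  double d_root[3], e_root[3], w[3];
  for (int k = 0; k < 3; ++k) {
    d_root[k] = D[3 * root + k];
    e_root[k] = E[3 * root + k];
  }
  double dsum = d_root[0] + d_root[1] + d_root[2];
  if (dsum <= 0.0) return R_NegInf;

  if (root_mode == 0) {
    for (int k = 0; k < 3; ++k) w[k] = d_root[k] / dsum;
  } else if (root_mode == 1) {
    for (int k = 0; k < 3; ++k) w[k] = 1.0 / 3.0;
  } else {
    for (int k = 0; k < 3; ++k) w[k] = 0.0;
    w[root_state] = 1.0;
  }

  double lik = 0.0;
  for (int k = 0; k < 3; ++k) lik += w[k] * d_root[k];
  if (lik <= 0.0) return R_NegInf;
  double ll = std::log(lik) + logcomp[root];

  if (condition_surv) {
    double cond = 0.0;
    for (int k = 0; k < 3; ++k) {
      double g = 1.0 - e_root[k];
      cond += w[k] * lam_root[k] * g * g;
    }
    if (cond <= 0.0) return R_NegInf;
    ll -= std::log(cond);
  }
  return std::isfinite(ll) ? ll : R_NegInf;
}
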
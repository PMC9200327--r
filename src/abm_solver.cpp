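#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <sstream>
using namespace Rcpp;

// Fractional Adams-Bashforth-Moulton predictor-corrector stepping loop.
// Each species i carries its own order mu_i; the memory convolution over the
// stored right-hand-side history is evaluated per species with increment
// weights w_m = m^mu - (m-1)^mu (predictor) and
// d_m = (m+1)^{mu+1} - 2 m^{mu+1} + (m-1)^{mu+1} (corrector interior),
// where m is the age (in steps) of the history node.  Species with mu = 1
// and full history use running sums (classical trapezoidal PECE).
//
// history_window <= 0 means full history; otherwise only the most recent
// `history_window` nodes enter the convolution (short-memory approximation).

static void check_state(const NumericVector& x, double t, double negative_floor,
                        NumericVector& out) {
  int S = x.size();
  for (int i = 0; i < S; ++i) {
    double v = x[i];
    if (!R_finite(v)) {
      std::ostringstream msg;
      msg << "non-finite abundance for species " << (i + 1) << " at t = " << t;
      stop(msg.str());
    }
    if (v < -negative_floor) {
      std::ostringstream msg;
      msg << "abundance " << v << " below -negative_floor for species "
          << (i + 1) << " at t = " << t
          << " (likely step-size misconfiguration)";
      stop(msg.str());
    }
    out[i] = (v < 0.0) ? 0.0 : v;
  }
}

// [[Rcpp::export]]
NumericMatrix abm_solve_cpp(Function rhs, NumericVector x0, NumericVector mu,
                            double t0, double h, int n_steps,
                            int corrector_iterations, int history_window,
                            double negative_floor) {
  const int S = x0.size();
  if (mu.size() != S) stop("orders and state dimension mismatch");
  NumericMatrix X(S, n_steps + 1);
  NumericMatrix Fh(S, n_steps + 1);

  std::vector< std::vector<double> > w(S), d(S);
  std::vector<double> cpred(S), ccor(S);
  std::vector<bool> fast(S);
  for (int i = 0; i < S; ++i) {
    double m_ = mu[i];
    fast[i] = (m_ == 1.0) && (history_window <= 0);
    cpred[i] = std::pow(h, m_) / std::tgamma(m_ + 1.0);
    ccor[i] = std::pow(h, m_) / std::tgamma(m_ + 2.0);
    if (!fast[i]) {
      w[i].resize(n_steps);
      d[i].resize(n_steps);
      for (int m = 1; m <= n_steps; ++m) {
        w[i][m - 1] = std::pow((double)m, m_) - std::pow((double)(m - 1), m_);
        d[i][m - 1] = std::pow((double)(m + 1), m_ + 1.0) -
                      2.0 * std::pow((double)m, m_ + 1.0) +
                      std::pow((double)(m - 1), m_ + 1.0);
      }
    }
  }

  NumericVector x = clone(x0);
  NumericVector f0 = rhs(t0, x);
  if (f0.size() != S) stop("rhs output length mismatch");
  for (int i = 0; i < S; ++i) {
    X(i, 0) = x[i];
    Fh(i, 0) = f0[i];
  }
  std::vector<double> sumAll(S);  // sum of F over nodes 0..n (fast path)
  for (int i = 0; i < S; ++i) sumAll[i] = Fh(i, 0);

  NumericVector xP(S), hist(S);
  for (int n = 0; n < n_steps; ++n) {
    double t1 = t0 + (double)(n + 1) * h;
    int navail = n + 1;  // history nodes 0..n
    int mmax = (history_window > 0 && history_window < navail)
                   ? history_window : navail;
    for (int i = 0; i < S; ++i) {
      if (fast[i]) {
        xP[i] = x0[i] + h * sumAll[i];
        hist[i] = Fh(i, 0) + 2.0 * (sumAll[i] - Fh(i, 0));
      } else {
        double m_ = mu[i];
        double sp = 0.0, sc = 0.0;
        const double* wi = w[i].data();
        const double* di = d[i].data();
        for (int m = 1; m <= mmax; ++m) {
          double f = Fh(i, navail - m);
          sp += wi[m - 1] * f;
          // age m = navail corresponds to node j = 0, which carries the
          // special corrector weight a0 when the full history is in view
          double wt;
          if (m == navail) {
            double nn = (double)n;
            wt = std::pow(nn, m_ + 1.0) -
                 (nn - m_) * std::pow(nn + 1.0, m_);
          } else {
            wt = di[m - 1];
          }
          sc += wt * f;
        }
        xP[i] = x0[i] + cpred[i] * sp;
        hist[i] = sc;
      }
    }
    // corrector passes: P(EC)^m with a final evaluation at the accepted
    // state; intermediate states are evaluated on the non-negative orthant
    // (predictor overshoot below zero is truncated for the F evaluation
    // only -- the accepted state keeps the floor/abort policy)
    NumericVector xc = clone(xP);
    NumericVector xeval(S);
    for (int it = 0; it < corrector_iterations; ++it) {
      for (int i = 0; i < S; ++i) xeval[i] = (xc[i] < 0.0) ? 0.0 : xc[i];
      NumericVector fn = rhs(t1, xeval);
      if (fn.size() != S) stop("rhs output length mismatch");
      for (int i = 0; i < S; ++i) {
        if (fast[i]) {
          xc[i] = x0[i] + (h / 2.0) * (hist[i] + fn[i]);
        } else {
          xc[i] = x0[i] + ccor[i] * (hist[i] + fn[i]);
        }
      }
    }
    NumericVector xclamped(S);
    check_state(xc, t1, negative_floor, xclamped);
    NumericVector fn = rhs(t1, xclamped);
    if (fn.size() != S) stop("rhs output length mismatch");
    for (int i = 0; i < S; ++i) {
      if (!R_finite(fn[i])) {
        std::ostringstream msg;
        msg << "non-finite derivative for species " << (i + 1)
            << " at t = " << t1;
        stop(msg.str());
      }
      X(i, n + 1) = xclamped[i];
      Fh(i, n + 1) = fn[i];
      sumAll[i] += fn[i];
    }
  }
  return X;
}
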
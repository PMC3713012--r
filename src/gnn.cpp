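#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 4-1-1 feed-forward network with logistic activations:
//   hidden  h = sig(w0*x0 + w1*x1 + w2*x2 + w3*x3 + w4)
//   output  y = sig(w5*h + w6)
// 7 adjustable parameters (5 weights + 2 thresholds). Trained by
// minimizing E = 0.5 * sum (y - t)^2 with Moller's scaled conjugate
// gradient; fully deterministic for a given initial weight vector.

static const int NP = 7;

static inline double sig(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static double net_error(const double* w, const NumericMatrix& X,
                        const NumericVector& t) {
  const int n = X.nrow();
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    double a = w[4];
    for (int j = 0; j < 4; ++j) a += w[j] * X(i, j);
    const double h = sig(a);
    const double y = sig(w[5] * h + w[6]);
    const double d = y - t[i];
    e += d * d;
  }
  return 0.5 * e;
}

static void net_gradient(const double* w, const NumericMatrix& X,
                         const NumericVector& t, double* g) {
  const int n = X.nrow();
  for (int k = 0; k < NP; ++k) g[k] = 0.0;
  for (int i = 0; i < n; ++i) {
    double a = w[4];
    for (int j = 0; j < 4; ++j) a += w[j] * X(i, j);
    const double h = sig(a);
    const double y = sig(w[5] * h + w[6]);
    const double dz = (y - t[i]) * y * (1.0 - y);     // dE/dz
    const double da = dz * w[5] * h * (1.0 - h);      // dE/da
    for (int j = 0; j < 4; ++j) g[j] += da * X(i, j);
    g[4] += da;
    g[5] += dz * h;
    g[6] += dz;
  }
}

// Scaled conjugate gradient (Moller 1993). Stops when the gradient
// 2-norm drops below tol, when the error plateaus, or after max_iter
// weight updates. The gradient at the current point is cached so each
// iteration costs one trial-error evaluation plus (on conjugate-system
// refresh) one finite-difference gradient.
static int scg_minimize(double* w, const NumericMatrix& X,
                        const NumericVector& t, int max_iter, double tol,
                        double* final_err, double* final_gnorm) {
  double g[NP], g2[NP], r[NP], p[NP], s[NP], wtry[NP];
  const double sigma0 = 1e-4;
  double lambda = 1e-6, lambdabar = 0.0;
  double E = net_error(w, X, t);
  net_gradient(w, X, t, g);  // g stays the gradient at the current w
  double rnorm2 = 0.0;
  for (int k = 0; k < NP; ++k) { r[k] = -g[k]; p[k] = r[k]; rnorm2 += r[k] * r[k]; }
  bool success = true;
  double delta = 0.0;
  int iter = 0, stalled = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    if (std::sqrt(rnorm2) <= tol) break;
    double pnorm2 = 0.0;
    for (int k = 0; k < NP; ++k) pnorm2 += p[k] * p[k];
    if (pnorm2 < 1e-300) break;
    if (success) {
      const double sigma = sigma0 / std::sqrt(pnorm2);
      for (int k = 0; k < NP; ++k) wtry[k] = w[k] + sigma * p[k];
      net_gradient(wtry, X, t, g2);
      delta = 0.0;
      for (int k = 0; k < NP; ++k) {
        s[k] = (g2[k] - g[k]) / sigma;
        delta += p[k] * s[k];
      }
    }
    delta += (lambda - lambdabar) * pnorm2;
    if (delta <= 0.0) {  // make the Hessian estimate positive definite
      lambdabar = 2.0 * (lambda - delta / pnorm2);
      delta = -delta + lambda * pnorm2;
      lambda = lambdabar;
    }
    double mu = 0.0;
    for (int k = 0; k < NP; ++k) mu += p[k] * r[k];
    const double alpha = mu / delta;
    for (int k = 0; k < NP; ++k) wtry[k] = w[k] + alpha * p[k];
    const double Etry = net_error(wtry, X, t);
    const double Delta = 2.0 * delta * (E - Etry) / (mu * mu);
    if (Delta >= 0.0) {  // successful step
      const double gain = E - Etry;
      for (int k = 0; k < NP; ++k) w[k] = wtry[k];
      E = Etry;
      stalled = (gain < 1e-13 * (1.0 + E)) ? stalled + 1 : 0;
      net_gradient(w, X, t, g);
      double rnew_norm2 = 0.0, rnew_dot_r = 0.0;
      for (int k = 0; k < NP; ++k) {
        const double rn = -g[k];
        rnew_norm2 += rn * rn;
        rnew_dot_r += rn * r[k];
      }
      lambdabar = 0.0;
      success = true;
      if ((iter + 1) % NP == 0) {
        for (int k = 0; k < NP; ++k) { r[k] = -g[k]; p[k] = r[k]; }
      } else {
        const double beta = (rnew_norm2 - rnew_dot_r) / mu;
        for (int k = 0; k < NP; ++k) {
          r[k] = -g[k];
          p[k] = r[k] + beta * p[k];
        }
      }
      rnorm2 = rnew_norm2;
      if (Delta >= 0.75) lambda *= 0.25;
      if (stalled >= 3) { ++iter; break; }  // error plateau
    } else {
      lambdabar = lambda;
      success = false;
      ++stalled;
      if (stalled >= 25) { ++iter; break; } // no acceptable step found
    }
    if (Delta < 0.25) {
      lambda += delta * (1.0 - Delta) / pnorm2;
      if (lambda > 1e12) lambda = 1e12;
    }
  }
  *final_err = E;
  *final_gnorm = std::sqrt(rnorm2);
  return iter;
}

// [[Rcpp::export]]
List cpp_train_net(NumericMatrix X, NumericVector t, NumericVector w0,
                   int max_iter, double tol) {
  if (X.ncol() != 4) stop("inputs must have 4 columns");
  if (w0.size() != NP) stop("w0 must have length 7");
  double w[NP];
  for (int k = 0; k < NP; ++k) w[k] = w0[k];
  double err, gnorm;
  const int it = scg_minimize(w, X, t, max_iter, tol, &err, &gnorm);
  NumericVector par(NP);
  for (int k = 0; k < NP; ++k) par[k] = w[k];
  return List::create(_["par"] = par, _["sse"] = 2.0 * err,
                      _["iterations"] = it, _["grad_norm"] = gnorm);
}

// [[Rcpp::export]]
NumericVector cpp_forward_net(NumericVector w, NumericMatrix X) {
  if (w.size() != NP) stop("w must have length 7");
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double a = w[4];
    for (int j = 0; j < 4; ++j) a += w[j] * X(i, j);
    out[i] = sig(w[5] * sig(a) + w[6]);
  }
  return out;
}

// Leave-one-out q2 (Eq-9 style): for each row, retrain the net on the
// remaining rows from the same initial weights, predict the held-out
// activity, back-transform, and score
//   q2 = 1 - sum(y_pred - y_exp)^2 / sum(y_exp - mean(y_exp))^2.
// Targets are scaled from [min, max] of y onto [0.1, 0.9].
// [[Rcpp::export]]
double cpp_loo_q2(NumericMatrix X, NumericVector y, NumericVector w0,
                  int max_iter, double tol) {
  const int n = X.nrow();
  if (n < 3) stop("need at least 3 rows for LOO q2");
  double ymin = y[0], ymax = y[0], ybar = 0.0;
  for (int i = 0; i < n; ++i) {
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
    ybar += y[i];
  }
  ybar /= n;
  if (ymax - ymin <= 0) stop("activities are constant");
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (y[i] - ybar) * (y[i] - ybar);

  NumericMatrix Xf(n - 1, 4);
  NumericVector tf(n - 1);
  double press = 0.0, err, gnorm;
  for (int hold = 0; hold < n; ++hold) {
    int r = 0;
    for (int i = 0; i < n; ++i) {
      if (i == hold) continue;
      for (int j = 0; j < 4; ++j) Xf(r, j) = X(i, j);
      tf[r] = 0.1 + 0.8 * (y[i] - ymin) / (ymax - ymin);
      ++r;
    }
    double w[NP];
    for (int k = 0; k < NP; ++k) w[k] = w0[k];
    scg_minimize(w, Xf, tf, max_iter, tol, &err, &gnorm);
    double a = w[4];
    for (int j = 0; j < 4; ++j) a += w[j] * X(hold, j);
    const double o = sig(w[5] * sig(a) + w[6]);
    const double pred = ymin + (o - 0.1) / 0.8 * (ymax - ymin);
    press += (pred - y[hold]) * (pred - y[hold]);
  }
  return 1.0 - press / ss;
}
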
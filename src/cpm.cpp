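#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cumulative probability model (ordinal cumulative-link regression treating
// every distinct response value as a category), fitted by Newton-Raphson.
//
//   P(Y <= y_(m) | Z) = G(gamma_m - Z theta),  m = 1..M-1
//
// The log-likelihood is concave for the logit and probit links; the cutpoint
// block of the Hessian is tridiagonal (an observation in category m involves
// only gamma_{m-1} and gamma_m), so each Newton step is solved with a Thomas
// factorization plus a k x k Schur complement, O(M + n k^2) per iteration.
// That is what makes bootstrap refits over hundreds of categories affordable.

struct LinkFns {
  int link;  // 0 logit, 1 probit
  double F(double x) const {
    if (link == 0) return 1.0 / (1.0 + std::exp(-x));
    return R::pnorm(x, 0.0, 1.0, 1, 0);
  }
  double f(double x) const {
    if (link == 0) { double p = F(x); return p * (1.0 - p); }
    return R::dnorm(x, 0.0, 1.0, 0);
  }
  double fp(double x) const {  // derivative of density
    if (link == 0) { double p = F(x); return p * (1.0 - p) * (1.0 - 2.0 * p); }
    return -x * R::dnorm(x, 0.0, 1.0, 0);
  }
};

// Solve T x = b for symmetric tridiagonal T (diag dd, off-diag ee), nrhs
// right-hand sides stored column-major in B (n x nrhs). In-place on B.
static bool thomas_solve(std::vector<double> dd, std::vector<double> ee,
                         std::vector<double> &B, int n, int nrhs) {
  if (n == 0) return true;
  std::vector<double> cp(n, 0.0);
  // forward sweep on the matrix
  for (int i = 0; i < n; ++i) {
    double m = dd[i];
    if (i > 0) m -= ee[i - 1] * cp[i - 1] * ee[i - 1];
    if (std::abs(m) < 1e-300) return false;
    cp[i] = 1.0 / m;
    dd[i] = m;
  }
  for (int r = 0; r < nrhs; ++r) {
    double *b = &B[(size_t)r * n];
    for (int i = 1; i < n; ++i) b[i] -= ee[i - 1] * cp[i - 1] * b[i - 1];
    b[n - 1] *= cp[n - 1];
    for (int i = n - 2; i >= 0; --i) b[i] = cp[i] * (b[i] - ee[i] * b[i + 1]);
  }
  return true;
}

// log-likelihood at (gamma, theta); returns -Inf on invalid ordering
static double cpm_loglik(const IntegerVector &cat, const NumericMatrix &Z,
                         const std::vector<double> &gamma,
                         const std::vector<double> &theta,
                         const LinkFns &lk, int M) {
  const int n = cat.size(), k = Z.ncol();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int r = 0; r < k; ++r) eta += Z(i, r) * theta[r];
    int m = cat[i];
    double Fu = (m < M) ? lk.F(gamma[m - 1] - eta) : 1.0;
    double Fl = (m > 1) ? lk.F(gamma[m - 2] - eta) : 0.0;
    double p = Fu - Fl;
    if (!(p > 0.0)) return R_NegInf;
    ll += std::log(p);
  }
  return ll;
}

// [[Rcpp::export]]
List cpm_fit_cpp(IntegerVector cat, int M, NumericMatrix Z, int link,
                 int maxit, double tol) {
  const int n = cat.size(), k = Z.ncol(), Mg = M - 1;
  LinkFns lk{link};

  // init: cutpoints at empirical-CDF quantiles of the link, theta = 0
  std::vector<double> cnt(M, 0.0);
  for (int i = 0; i < n; ++i) cnt[cat[i] - 1] += 1.0;
  std::vector<double> gamma(Mg), theta(k, 0.0);
  double cum = 0.0;
  for (int m = 0; m < Mg; ++m) {
    cum += cnt[m];
    double p = cum / n;
    gamma[m] = (link == 0) ? std::log(p / (1.0 - p)) : R::qnorm(p, 0, 1, 1, 0);
  }

  double ll = cpm_loglik(cat, Z, gamma, theta, lk, M);
  bool converged = false;
  int it = 0;

  std::vector<double> gg(Mg), gt(k), dd(Mg), ee(Mg > 0 ? Mg - 1 : 0);
  std::vector<double> C((size_t)Mg * k), D((size_t)k * k);

  for (it = 0; it < maxit; ++it) {
    std::fill(gg.begin(), gg.end(), 0.0);
    std::fill(gt.begin(), gt.end(), 0.0);
    std::fill(dd.begin(), dd.end(), 0.0);
    std::fill(ee.begin(), ee.end(), 0.0);
    std::fill(C.begin(), C.end(), 0.0);
    std::fill(D.begin(), D.end(), 0.0);

    for (int i = 0; i < n; ++i) {
      double eta = 0.0;
      for (int r = 0; r < k; ++r) eta += Z(i, r) * theta[r];
      int m = cat[i];
      double u = (m < M) ? gamma[m - 1] - eta : 0.0;
      double l = (m > 1) ? gamma[m - 2] - eta : 0.0;
      double Fu = (m < M) ? lk.F(u) : 1.0, fu = (m < M) ? lk.f(u) : 0.0,
             fpu = (m < M) ? lk.fp(u) : 0.0;
      double Fl = (m > 1) ? lk.F(l) : 0.0, fl = (m > 1) ? lk.f(l) : 0.0,
             fpl = (m > 1) ? lk.fp(l) : 0.0;
      double p = Fu - Fl;
      double A = fu / p, B = fl / p;
      double Huu = fpu / p - A * A;        // d2 logp / du2
      double Hll = -fpl / p - B * B;       // d2 logp / dl2
      double Hul = A * B;                  // d2 logp / du dl

      if (m < M) gg[m - 1] += A;
      if (m > 1) gg[m - 2] -= B;
      double dleta = -(fu - fl) / p;       // d logp / d eta ... times dZ below
      for (int r = 0; r < k; ++r) gt[r] += dleta * Z(i, r);

      if (m < M) dd[m - 1] += Huu;
      if (m > 1) dd[m - 2] += Hll;
      if (m < M && m > 1) ee[m - 2] += Hul;

      for (int r = 0; r < k; ++r) {
        double zr = Z(i, r);
        if (m < M) C[(size_t)r * Mg + (m - 1)] += -(Huu + Hul) * zr;
        if (m > 1) C[(size_t)r * Mg + (m - 2)] += -(Hll + Hul) * zr;
        for (int q = r; q < k; ++q) {
          double h = (Huu + 2.0 * Hul + Hll) * zr * Z(i, q);
          D[(size_t)r * k + q] += h;
          if (q != r) D[(size_t)q * k + r] += h;
        }
      }
    }

    double gmax = 0.0;
    for (int m = 0; m < Mg; ++m) gmax = std::max(gmax, std::abs(gg[m]));
    for (int r = 0; r < k; ++r) gmax = std::max(gmax, std::abs(gt[r]));
    if (gmax < tol) { converged = true; break; }

    // negate to get a positive-definite system
    std::vector<double> ndd(Mg), nee(ee);
    for (int m = 0; m < Mg; ++m) ndd[m] = -dd[m] + 1e-10;
    for (size_t q = 0; q < nee.size(); ++q) nee[q] = -nee[q];

    // W = T^-1 [gg | C]
    std::vector<double> W((size_t)Mg * (k + 1));
    for (int m = 0; m < Mg; ++m) W[m] = gg[m];
    for (int r = 0; r < k; ++r)
      for (int m = 0; m < Mg; ++m) W[(size_t)(r + 1) * Mg + m] = C[(size_t)r * Mg + m];
    if (!thomas_solve(ndd, nee, W, Mg, k + 1)) break;

    // Schur complement S = (-D) - C' T^-1 C ; rhs = gt - C' T^-1 gg
    std::vector<double> S((size_t)k * k), rhs(k);
    for (int r = 0; r < k; ++r) {
      double acc = 0.0;
      for (int m = 0; m < Mg; ++m) acc += C[(size_t)r * Mg + m] * W[m];
      rhs[r] = gt[r] + acc;
      for (int q = 0; q < k; ++q) {
        double a2 = 0.0;
        for (int m = 0; m < Mg; ++m)
          a2 += C[(size_t)r * Mg + m] * W[(size_t)(q + 1) * Mg + m];
        S[(size_t)r * k + q] = -D[(size_t)r * k + q] - a2;
      }
    }
    // small dense Cholesky solve of S st = rhs
    std::vector<double> st(rhs);
    {
      std::vector<double> L((size_t)k * k, 0.0);
      bool ok = true;
      for (int r = 0; r < k && ok; ++r) {
        for (int q = 0; q <= r; ++q) {
          double sum = S[(size_t)r * k + q];
          for (int x = 0; x < q; ++x) sum -= L[(size_t)r * k + x] * L[(size_t)q * k + x];
          if (q == r) {
            if (sum <= 0) { ok = false; break; }
            L[(size_t)r * k + r] = std::sqrt(sum);
          } else L[(size_t)r * k + q] = sum / L[(size_t)q * k + q];
        }
      }
      if (!ok) break;
      for (int r = 0; r < k; ++r) {
        double sum = st[r];
        for (int x = 0; x < r; ++x) sum -= L[(size_t)r * k + x] * st[x];
        st[r] = sum / L[(size_t)r * k + r];
      }
      for (int r = k - 1; r >= 0; --r) {
        double sum = st[r];
        for (int x = r + 1; x < k; ++x) sum -= L[(size_t)x * k + r] * st[x];
        st[r] = sum / L[(size_t)r * k + r];
      }
    }
    // sg = T^-1 gg - (T^-1 C) st
    std::vector<double> sg(Mg);
    for (int m = 0; m < Mg; ++m) {
      double v = W[m];
      for (int r = 0; r < k; ++r) v += W[(size_t)(r + 1) * Mg + m] * st[r];
      sg[m] = v;
    }

    // step with halving
    double step = 1.0;
    bool improved = false;
    for (int h = 0; h < 40; ++h) {
      std::vector<double> g_new(gamma), t_new(theta);
      for (int m = 0; m < Mg; ++m) g_new[m] += step * sg[m];
      for (int r = 0; r < k; ++r) t_new[r] += step * st[r];
      double ll_new = cpm_loglik(cat, Z, g_new, t_new, lk, M);
      if (R_finite(ll_new) && ll_new >= ll - 1e-12) {
        bool tiny = std::abs(ll_new - ll) < 1e-12 * (std::abs(ll) + 1.0);
        gamma = g_new; theta = t_new; ll = ll_new;
        improved = true;
        if (tiny && gmax < 1e-4) converged = true;
        break;
      }
      step *= 0.5;
    }
    if (!improved) break;
    if (converged) break;
  }

  return List::create(_["gamma"] = NumericVector(gamma.begin(), gamma.end()),
                      _["theta"] = NumericVector(theta.begin(), theta.end()),
                      _["loglik"] = ll, _["converged"] = converged,
                      _["iterations"] = it + 1);
}

// Probability-scale residual: P(Y < y_i | Z_i) - P(Y > y_i | Z_i)
// [[Rcpp::export]]
NumericVector cpm_psr_cpp(IntegerVector cat, int M, NumericMatrix Z,
                          NumericVector gamma, NumericVector theta, int link) {
  const int n = cat.size(), k = Z.ncol();
  LinkFns lk{link};
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double eta = 0.0;
    for (int r = 0; r < k; ++r) eta += Z(i, r) * theta[r];
    int m = cat[i];
    double Fu = (m < M) ? lk.F(gamma[m - 1] - eta) : 1.0;  // P(Y <= y_i)
    double Fl = (m > 1) ? lk.F(gamma[m - 2] - eta) : 0.0;  // P(Y <  y_i)
    out[i] = Fl - (1.0 - Fu);
  }
  return out;
}
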
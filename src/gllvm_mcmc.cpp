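#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Negative-binomial GLLVM, adaptive Metropolis-within-Gibbs.
//
//   y_ij ~ NB(mu_ij, phi_j),  Var = mu + mu^2/phi
//   log mu_ij = alpha_i + beta0_j + x_i' beta_j + z_i' lambda_j
//
// alpha is hierarchical: alpha_i ~ N(0, sigma_alpha^2) with sigma_alpha
// estimated (half-normal hyperprior).  A free fixed-effect alpha would be
// unidentified against taxon-shared structure (the design columns and
// common loading shifts); the learned shrinkage closes those ridges while
// still absorbing sequencing depth.  The R wrapper additionally projects
// each saved alpha draw onto span(1, X) and folds the projection into
// beta0/beta, so reported draws satisfy the sum-to-zero convention.
// Loadings: lambda_{jl} = 0 for l > j (upper triangle of the leading d x d
// block), lambda_{jj} > 0 for j <= d.  Scalar random-walk updates with
// Robbins-Monro step-size adaptation targeting 0.44 acceptance, frozen
// after warmup, plus likelihood-invariant location and scale moves per
// latent factor that decorrelate (z, beta0) and (z, lambda).  R's RNG is
// used throughout so set.seed() on the R side makes chains reproducible.

// log(phi + exp(eta)) computed stably for large eta
static inline double lse_phi(double eta, double phi) {
  if (eta > 30.0) return eta + std::log1p(phi * std::exp(-eta));
  return std::log(phi + std::exp(eta));
}

// per-cell NB log-lik, dropping terms constant in eta
static inline double ll_eta(double y, double eta, double phi) {
  return y * eta - (y + phi) * lse_phi(eta, phi);
}

static inline double rm_gain(int iter) {
  return 1.0 / std::pow(1.0 + iter, 0.6);
}

static inline void adapt_step(double &ls, double acc, double gain) {
  ls += gain * (acc - 0.44);
  if (ls < -8.0) ls = -8.0;
  if (ls > 3.0) ls = 3.0;
}

// [[Rcpp::export]]
List gllvm_mcmc_chain(IntegerMatrix Y, NumericMatrix X, int d,
                      int n_warm, int n_save, int thin,
                      double prior_sd, double lambda_prior_sd,
                      double invphi_rate,
                      NumericVector alpha0, NumericVector beta00,
                      NumericMatrix beta0m, NumericMatrix lambda0,
                      NumericVector phi0, NumericMatrix z0) {
  const int s = Y.nrow(), t = Y.ncol(), k = X.ncol();
  const double pv = prior_sd * prior_sd;   // prior variance for beta0/beta
  const double lv = lambda_prior_sd * lambda_prior_sd;  // loadings
  double sigma_a = 0.5;                    // row-effect SD (estimated)

  // state (copies of inits)
  std::vector<double> alpha(alpha0.begin(), alpha0.end());
  std::vector<double> beta0(beta00.begin(), beta00.end());
  NumericMatrix beta(clone(beta0m));       // t x k
  NumericMatrix lambda(clone(lambda0));    // t x d
  std::vector<double> phi(phi0.begin(), phi0.end());
  NumericMatrix z(clone(z0));              // s x d

  // linear predictor
  NumericMatrix eta(s, t);
  auto recompute_eta = [&]() {
    for (int j = 0; j < t; ++j)
      for (int i = 0; i < s; ++i) {
        double e = alpha[i] + beta0[j];
        for (int kk = 0; kk < k; ++kk) e += X(i, kk) * beta(j, kk);
        for (int l = 0; l < d; ++l)    e += z(i, l) * lambda(j, l);
        eta(i, j) = e;
      }
  };
  recompute_eta();

  // adaptive log step sizes
  std::vector<double> ls_alpha(s, -0.7);
  std::vector<double> ls_beta0(t, -1.0);
  std::vector<double> ls_beta((size_t)t * k, -1.0);
  std::vector<double> ls_lambda((size_t)t * d, -1.0);
  std::vector<double> ls_z((size_t)s * d, -0.7);
  std::vector<double> ls_phi(t, -0.7);
  std::vector<double> ls_floc(d > 0 ? d : 0, -1.0);
  std::vector<double> ls_fscale(d > 0 ? d : 0, -1.5);
  std::vector<double> ls_fx((size_t)d * k, -1.5);
  std::vector<double> ls_fshift(d > 0 ? d : 0, -2.0);
  double ls_sigma_a = -1.0;

  // storage
  NumericMatrix dr_alpha(n_save, s), dr_beta0(n_save, t),
      dr_beta(n_save, t * k), dr_lambda(n_save, t * d),
      dr_phi(n_save, t), dr_z(n_save, s * d);
  NumericVector dr_sigma(n_save);

  RNGScope scope;
  const int n_iter = n_warm + n_save * thin;
  int stored = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    const bool adapting = iter < n_warm;
    const double gain = adapting ? rm_gain(iter) : 0.0;

    // ---- alpha (hierarchical row effects) ----
    const double sv = sigma_a * sigma_a;
    for (int i = 0; i < s; ++i) {
      double e = R::norm_rand() * std::exp(ls_alpha[i]);
      double dll = 0.0;
      for (int j = 0; j < t; ++j)
        dll += ll_eta(Y(i, j), eta(i, j) + e, phi[j]) -
               ll_eta(Y(i, j), eta(i, j), phi[j]);
      double a_new = alpha[i] + e;
      double lr = dll - (a_new * a_new - alpha[i] * alpha[i]) / (2 * sv);
      double acc = lr >= 0 ? 1.0 : std::exp(lr);
      if (R::unif_rand() < acc) {
        alpha[i] = a_new;
        for (int j = 0; j < t; ++j) eta(i, j) += e;
      }
      if (adapting) adapt_step(ls_alpha[i], acc, gain);
    }
    // sigma_alpha: log random walk, half-normal(0, prior_sd^2) hyperprior
    {
      double e = R::norm_rand() * std::exp(ls_sigma_a);
      double s_new = sigma_a * std::exp(e);
      double ssq = 0.0;
      for (int i = 0; i < s; ++i) ssq += alpha[i] * alpha[i];
      double lr = -s * (std::log(s_new) - std::log(sigma_a)) -
                  ssq / 2.0 * (1.0 / (s_new * s_new) - 1.0 / sv) -
                  (s_new * s_new - sv) / (2 * pv) + e;
      double acc = lr >= 0 ? 1.0 : std::exp(lr);
      if (R::unif_rand() < acc) sigma_a = s_new;
      if (adapting) adapt_step(ls_sigma_a, acc, gain);
    }

    // ---- beta0 ----
    for (int j = 0; j < t; ++j) {
      double e = R::norm_rand() * std::exp(ls_beta0[j]);
      double dll = 0.0;
      for (int i = 0; i < s; ++i)
        dll += ll_eta(Y(i, j), eta(i, j) + e, phi[j]) -
               ll_eta(Y(i, j), eta(i, j), phi[j]);
      double b_new = beta0[j] + e;
      double lr = dll - (b_new * b_new - beta0[j] * beta0[j]) / (2 * pv);
      double acc = lr >= 0 ? 1.0 : std::exp(lr);
      if (R::unif_rand() < acc) {
        beta0[j] = b_new;
        for (int i = 0; i < s; ++i) eta(i, j) += e;
      }
      if (adapting) adapt_step(ls_beta0[j], acc, gain);
    }

    // ---- beta ----
    for (int j = 0; j < t; ++j)
      for (int kk = 0; kk < k; ++kk) {
        size_t idx = (size_t)j * k + kk;
        double e = R::norm_rand() * std::exp(ls_beta[idx]);
        double dll = 0.0;
        for (int i = 0; i < s; ++i) {
          double de = e * X(i, kk);
          dll += ll_eta(Y(i, j), eta(i, j) + de, phi[j]) -
                 ll_eta(Y(i, j), eta(i, j), phi[j]);
        }
        double b_new = beta(j, kk) + e;
        double lr = dll - (b_new * b_new - beta(j, kk) * beta(j, kk)) / (2 * pv);
        double acc = lr >= 0 ? 1.0 : std::exp(lr);
        if (R::unif_rand() < acc) {
          beta(j, kk) = b_new;
          for (int i = 0; i < s; ++i) eta(i, j) += e * X(i, kk);
        }
        if (adapting) adapt_step(ls_beta[idx], acc, gain);
      }

    // ---- lambda (constrained) ----
    for (int j = 0; j < t; ++j) {
      int lmax = std::min(j + 1, d);      // l > j fixed at zero
      for (int l = 0; l < lmax; ++l) {
        size_t idx = (size_t)j * d + l;
        double e = R::norm_rand() * std::exp(ls_lambda[idx]);
        double lam_new = lambda(j, l) + e;
        bool diag = (j == l);
        double acc;
        if (diag && lam_new <= 0.0) {
          acc = 0.0;                       // half-normal support
        } else {
          double dll = 0.0;
          for (int i = 0; i < s; ++i) {
            double de = e * z(i, l);
            dll += ll_eta(Y(i, j), eta(i, j) + de, phi[j]) -
                   ll_eta(Y(i, j), eta(i, j), phi[j]);
          }
          double lr = dll - (lam_new * lam_new - lambda(j, l) * lambda(j, l)) / (2 * lv);
          acc = lr >= 0 ? 1.0 : std::exp(lr);
          if (R::unif_rand() < acc) {
            lambda(j, l) = lam_new;
            for (int i = 0; i < s; ++i) eta(i, j) += e * z(i, l);
          }
        }
        if (adapting) adapt_step(ls_lambda[idx], acc, gain);
      }
    }

    // ---- z (standard-normal prior) ----
    for (int i = 0; i < s; ++i)
      for (int l = 0; l < d; ++l) {
        size_t idx = (size_t)i * d + l;
        double e = R::norm_rand() * std::exp(ls_z[idx]);
        double dll = 0.0;
        for (int j = 0; j < t; ++j) {
          double de = e * lambda(j, l);
          dll += ll_eta(Y(i, j), eta(i, j) + de, phi[j]) -
                 ll_eta(Y(i, j), eta(i, j), phi[j]);
        }
        double z_new = z(i, l) + e;
        double lr = dll - (z_new * z_new - z(i, l) * z(i, l)) / 2.0;
        double acc = lr >= 0 ? 1.0 : std::exp(lr);
        if (R::unif_rand() < acc) {
          z(i, l) = z_new;
          for (int j = 0; j < t; ++j) eta(i, j) += e * lambda(j, l);
        }
        if (adapting) adapt_step(ls_z[idx], acc, gain);
      }

    // ---- likelihood-invariant factor moves ----
    // location: z_.l += delta, beta0_j -= delta * lambda_jl (eta unchanged)
    // scale:    z_.l *= c,     lambda_.l /= c               (eta unchanged)
    for (int l = 0; l < d; ++l) {
      {
        double delta = R::norm_rand() * std::exp(ls_floc[l]);
        double dlp = 0.0;
        for (int i = 0; i < s; ++i) {
          double zn = z(i, l) + delta;
          dlp -= (zn * zn - z(i, l) * z(i, l)) / 2.0;
        }
        for (int j = 0; j < t; ++j) {
          double bn = beta0[j] - delta * lambda(j, l);
          dlp -= (bn * bn - beta0[j] * beta0[j]) / (2 * pv);
        }
        double acc = dlp >= 0 ? 1.0 : std::exp(dlp);
        if (R::unif_rand() < acc) {
          for (int i = 0; i < s; ++i) z(i, l) += delta;
          for (int j = 0; j < t; ++j) beta0[j] -= delta * lambda(j, l);
        }
        if (adapting) adapt_step(ls_floc[l], acc, gain);
      }
      {
        double eps = R::norm_rand() * std::exp(ls_fscale[l]);
        double c = std::exp(eps);
        int n_free = 0;                       // free loading entries in col l
        for (int j = l; j < t; ++j) ++n_free; // j >= l are free (diag incl.)
        double dlp = (s - n_free) * eps;      // log-Jacobian
        for (int i = 0; i < s; ++i) {
          double zn = z(i, l) * c;
          dlp -= (zn * zn - z(i, l) * z(i, l)) / 2.0;
        }
        for (int j = l; j < t; ++j) {
          double ln = lambda(j, l) / c;
          dlp -= (ln * ln - lambda(j, l) * lambda(j, l)) / (2 * lv);
        }
        double acc = dlp >= 0 ? 1.0 : std::exp(dlp);
        if (R::unif_rand() < acc) {
          for (int i = 0; i < s; ++i) z(i, l) *= c;
          for (int j = l; j < t; ++j) lambda(j, l) /= c;
        }
        if (adapting) adapt_step(ls_fscale[l], acc, gain);
      }
      // loading shift: lambda_.l += c, alpha_i -= c z_il (eta unchanged);
      // mixes the common-loading / row-effect ridge
      {
        double c = R::norm_rand() * std::exp(ls_fshift[l]);
        double dlp = 0.0;
        for (int j = l; j < t; ++j) {   // only free entries may shift
          double ln = lambda(j, l) + c;
          dlp -= (ln * ln - lambda(j, l) * lambda(j, l)) / (2 * lv);
        }
        bool ok = l >= t || (lambda(l, l) + c) > 0.0;  // keep diag positive
        if (ok) {
          for (int i = 0; i < s; ++i) {
            double an = alpha[i] - c * z(i, l);
            dlp -= (an * an - alpha[i] * alpha[i]) / (2 * sigma_a * sigma_a);
          }
          // taxa j < l have structural zeros and cannot shift: the move is
          // only likelihood-invariant when no such taxa exist for column l,
          // i.e. l == 0; for l > 0 fall back to a partial move that skips
          // the constrained taxa and corrects the likelihood explicitly
          double dll = 0.0;
          if (l > 0) {
            // eta changes for constrained taxa j < l by -c * z_il? no:
            // those lambda stay 0 while alpha moves, so eta_ij changes by
            // -c z_il for j < l only
            for (int j = 0; j < l; ++j)
              for (int i = 0; i < s; ++i)
                dll += ll_eta(Y(i, j), eta(i, j) - c * z(i, l), phi[j]) -
                       ll_eta(Y(i, j), eta(i, j), phi[j]);
          }
          double lr = dlp + dll;
          double acc = lr >= 0 ? 1.0 : std::exp(lr);
          if (R::unif_rand() < acc) {
            for (int j = l; j < t; ++j) lambda(j, l) += c;
            for (int i = 0; i < s; ++i) alpha[i] -= c * z(i, l);
            if (l > 0)
              for (int j = 0; j < l; ++j)
                for (int i = 0; i < s; ++i) eta(i, j) -= c * z(i, l);
          }
          if (adapting) adapt_step(ls_fshift[l], acc, gain);
        } else if (adapting) adapt_step(ls_fshift[l], 0.0, gain);
      }
      // alignment: z_.l += delta x_.k, beta_jk -= delta lambda_jl (eta
      // unchanged) -- mixes the softly identified factor-covariate direction
      for (int kk = 0; kk < k; ++kk) {
        size_t idx = (size_t)l * k + kk;
        double delta = R::norm_rand() * std::exp(ls_fx[idx]);
        double dlp = 0.0;
        for (int i = 0; i < s; ++i) {
          double zn = z(i, l) + delta * X(i, kk);
          dlp -= (zn * zn - z(i, l) * z(i, l)) / 2.0;
        }
        for (int j = 0; j < t; ++j) {
          double bn = beta(j, kk) - delta * lambda(j, l);
          dlp -= (bn * bn - beta(j, kk) * beta(j, kk)) / (2 * pv);
        }
        double acc = dlp >= 0 ? 1.0 : std::exp(dlp);
        if (R::unif_rand() < acc) {
          for (int i = 0; i < s; ++i) z(i, l) += delta * X(i, kk);
          for (int j = 0; j < t; ++j) beta(j, kk) -= delta * lambda(j, l);
        }
        if (adapting) adapt_step(ls_fx[idx], acc, gain);
      }
    }

    // ---- phi (log random walk; prior 1/phi ~ Exp(rate)) ----
    for (int j = 0; j < t; ++j) {
      double e = R::norm_rand() * std::exp(ls_phi[j]);
      double ph_new = phi[j] * std::exp(e);
      double dll = 0.0;
      for (int i = 0; i < s; ++i) {
        double y = Y(i, j), et = eta(i, j);
        dll += R::lgammafn(y + ph_new) - R::lgammafn(ph_new) +
               ph_new * std::log(ph_new) - (y + ph_new) * lse_phi(et, ph_new);
        dll -= R::lgammafn(y + phi[j]) - R::lgammafn(phi[j]) +
               phi[j] * std::log(phi[j]) - (y + phi[j]) * lse_phi(et, phi[j]);
      }
      // log prior of phi when 1/phi ~ Exp(rate): -rate/phi - 2 log phi (+const)
      double dlp = (-invphi_rate / ph_new - 2.0 * std::log(ph_new)) -
                   (-invphi_rate / phi[j] - 2.0 * std::log(phi[j]));
      double lr = dll + dlp + e;           // + log-Jacobian of log walk
      double acc = lr >= 0 ? 1.0 : std::exp(lr);
      if (R::unif_rand() < acc) phi[j] = ph_new;
      if (adapting) adapt_step(ls_phi[j], acc, gain);
    }

    if ((iter + 1) % 200 == 0) recompute_eta();  // guard against drift

    if (!adapting && ((iter - n_warm + 1) % thin == 0) && stored < n_save) {
      for (int i = 0; i < s; ++i) dr_alpha(stored, i) = alpha[i];
      for (int j = 0; j < t; ++j) dr_beta0(stored, j) = beta0[j];
      for (int j = 0; j < t; ++j)
        for (int kk = 0; kk < k; ++kk) dr_beta(stored, j * k + kk) = beta(j, kk);
      for (int j = 0; j < t; ++j)
        for (int l = 0; l < d; ++l) dr_lambda(stored, j * d + l) = lambda(j, l);
      for (int j = 0; j < t; ++j) dr_phi(stored, j) = phi[j];
      for (int i = 0; i < s; ++i)
        for (int l = 0; l < d; ++l) dr_z(stored, i * d + l) = z(i, l);
      dr_sigma[stored] = sigma_a;
      ++stored;
    }
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["alpha"] = dr_alpha, _["beta0"] = dr_beta0,
                      _["beta"] = dr_beta, _["lambda"] = dr_lambda,
                      _["phi"] = dr_phi, _["z"] = dr_z,
                      _["sigma_alpha"] = dr_sigma);
}
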
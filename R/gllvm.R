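# Bayesian NB-GLLVM front end over the C++ Metropolis-within-Gibbs kernel.

#' Fit a Bayesian negative-binomial latent variable model
#'
#' Joint model for a filtered site x taxon count table:
#' `y_ij ~ NB(mu_ij, phi_j)` with
#' `log mu_ij = alpha_i + beta0_j + x_i' beta_j + z_i' lambda_j`.
#' The per-site effects `alpha` (sum-to-zero) absorb sequencing depth; the
#' `d` latent factors with taxon loadings capture covariate-independent
#' co-variation.  Weakly informative priors: normal(0, prior_sd^2) on alpha,
#' beta0, beta and free loadings, half-normal on loading diagonals,
#' exponential(0.1) on 1/phi.  The loading matrix is identified by zeroing
#' the upper triangle of its leading d x d block and keeping its diagonal
#' positive.
#'
#' @param counts a `community_table`, prevalence-filtered.
#' @param env an `env_matrix` (standardized covariates).
#' @param d number of latent variables (default 2; 0 gives plain NB
#'   regression and residual correlations become unavailable).
#' @param n_chains,n_draws,n_warmup,thin sampler schedule; defaults
#'   4 chains x 1000 saved draws after 1000 warmup.
#' @param prior_sd prior SD for intercepts and covariate coefficients,
#'   default 10.
#' @param lambda_prior_sd prior SD for latent loadings, default 1.5.  Loadings
#'   act on unit-variance latent scores, so a unit-scale prior is what keeps
#'   the factor scale identified; a very diffuse loading prior lets the
#'   latent scale ridge inflate every coefficient's posterior.
#' @param invphi_rate rate of the exponential prior on 1/phi, default 0.1.
#' @param seed RNG seed; chain c uses seed + c - 1.
#' @param rhat_threshold convergence flag threshold, default 1.1.
#' @return object of class `gllvm_fit` with posterior draw arrays, sampler
#'   diagnostics (split R-hat, effective sample size) and the model spec.
#' @export
fit_gllvm <- function(counts, env, d = 2, n_chains = 4, n_draws = 1000,
                      n_warmup = 1000, thin = 1, prior_sd = 10,
                      lambda_prior_sd = 1.5, invphi_rate = 0.1, seed = 1,
                      rhat_threshold = 1.1) {
  stopifnot(inherits(counts, "community_table"), inherits(env, "env_matrix"))
  Y <- counts$counts
  X <- env$values
  if (nrow(Y) != nrow(X)) stop("counts and env site dimensions differ", call. = FALSE)
  s <- nrow(Y); t <- ncol(Y); k <- ncol(X)
  if (d < 0) stop("d must be >= 0", call. = FALSE)
  if (s < d + 2) stop("need at least d + 2 sites", call. = FALSE)
  if (any(colSums(Y) == 0))
    stop("all-zero taxon present; run filter_prevalence() first", call. = FALSE)

  # moment-based starting values, jittered per chain
  beta0_init <- log(colMeans(Y) + 0.5)
  depth <- rowSums(Y) + 1
  alpha_init <- log(depth) - mean(log(depth))

  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1L)
    lam0 <- matrix(rnorm(t * max(d, 1), 0, 0.3), t)[, seq_len(max(d, 0)), drop = FALSE]
    if (d > 0) for (l in seq_len(min(d, t))) {
      if (l < d) lam0[l, (l + 1):d] <- 0
      lam0[l, l] <- abs(lam0[l, l]) + 0.1
    }
    z0 <- matrix(rnorm(s * max(d, 1), 0, 0.3), s)[, seq_len(max(d, 0)), drop = FALSE]
    chains[[ch]] <- gllvm_mcmc_chain(
      Y, X, d, n_warmup, n_draws, thin, prior_sd, lambda_prior_sd, invphi_rate,
      alpha_init + rnorm(s, 0, 0.1), beta0_init + rnorm(t, 0, 0.1),
      matrix(rnorm(t * k, 0, 0.05), t, k), lam0,
      rep(2, t) * exp(rnorm(t, 0, 0.1)), z0)
  }

  bind <- function(name) do.call(rbind, lapply(chains, `[[`, name))
  n_total <- n_chains * n_draws
  # estimability convention: free per-site effects alias the intercepts (a
  # constant) and every covariate's coefficient column (a common shift c_k
  # paired with alpha - X c_k leaves the likelihood unchanged because x_ik
  # is shared across taxa).  Report the representative with alpha orthogonal
  # to span(1, X): project each draw's alpha onto the design and fold the
  # projection into beta0 and beta.  Reported alpha then also sums to zero.
  alpha_draws <- bind("alpha")
  beta0_draws <- bind("beta0")
  W <- cbind(1, X)
  H <- solve(crossprod(W), t(W))           # (k+1) x s projector
  proj_coef <- alpha_draws %*% t(H)        # n_total x (k+1)
  alpha_draws <- alpha_draws - proj_coef %*% t(W)
  beta0_draws <- beta0_draws + proj_coef[, 1]
  draws <- list(
    alpha = alpha_draws,
    beta0 = beta0_draws,
    beta = NULL, lambda = NULL, phi = bind("phi"), z = NULL)
  # C++ stores beta row-major as j*k + kk; reshape to [draw, taxon, covariate]
  bmat <- bind("beta")
  draws$beta <- array(0, dim = c(n_total, t, k),
                      dimnames = list(NULL, counts$taxa$display_name,
                                      env$covariate_names))
  for (kk in seq_len(k))
    draws$beta[, , kk] <- bmat[, (seq_len(t) - 1) * k + kk, drop = FALSE] +
      proj_coef[, kk + 1]
  if (d > 0) {
    lmat <- bind("lambda")
    draws$lambda <- array(0, dim = c(n_total, t, d),
                          dimnames = list(NULL, counts$taxa$display_name, NULL))
    zmat <- bind("z")
    draws$z <- array(0, dim = c(n_total, s, d),
                     dimnames = list(NULL, counts$site_ids, NULL))
    for (l in seq_len(d)) {
      draws$lambda[, , l] <- lmat[, (seq_len(t) - 1) * d + l, drop = FALSE]
      draws$z[, , l] <- zmat[, (seq_len(s) - 1) * d + l, drop = FALSE]
    }
  }
  draws$sigma_alpha <- as.vector(unlist(lapply(chains, `[[`, "sigma_alpha")))
  colnames(draws$alpha) <- counts$site_ids
  colnames(draws$beta0) <- colnames(draws$phi) <- counts$taxa$display_name
  chain_id <- rep(seq_len(n_chains), each = n_draws)

  diagnostics <- gllvm_diagnostics(draws, chain_id)
  # latent loadings/scores are identified only up to column sign flips when
  # an anchor loading sits near zero, so cross-chain R-hat is meaningful for
  # the sign-identifiable blocks only; rho and variance partitions are
  # invariant to the flips
  core <- diagnostics$block %in% c("alpha", "beta0", "beta", "phi")
  frac_bad <- mean(diagnostics$rhat[core] > rhat_threshold, na.rm = TRUE)
  converged <- is.finite(frac_bad) && frac_bad <= 0.05
  if (!converged)
    warning(sprintf("possible non-convergence: %.1f%% of parameters have R-hat > %.2f",
                    100 * frac_bad, rhat_threshold), call. = FALSE)

  structure(list(
    draws = draws, chain_id = chain_id, n_chains = n_chains,
    n_draws = n_draws, diagnostics = diagnostics, converged = converged,
    taxa = counts$taxa, site_ids = counts$site_ids,
    covariate_names = env$covariate_names, groups = env$groups,
    env_values = X,
    model_spec = list(family = "negative_binomial", d = d,
                      prior_sd = prior_sd, lambda_prior_sd = lambda_prior_sd,
                      invphi_rate = invphi_rate,
                      n_chains = n_chains, n_draws = n_draws,
                      n_warmup = n_warmup, thin = thin, seed = seed)),
    class = "gllvm_fit")
}

#' @export
print.gllvm_fit <- function(x, ...) {
  cat(sprintf("gllvm_fit: %d sites x %d taxa, %d covariates, d = %d\n",
              length(x$site_ids), nrow(x$taxa), length(x$covariate_names),
              x$model_spec$d))
  cat(sprintf("  %d chains x %d draws; max R-hat %.3f; converged: %s\n",
              x$n_chains, x$n_draws, max(x$diagnostics$rhat, na.rm = TRUE),
              x$converged))
  invisible(x)
}

# split-Rhat and a crude autocorrelation-based ESS, per scalar parameter
split_rhat <- function(mat, chain_id) {
  # mat: n_total x P
  halves <- unlist(lapply(split(seq_along(chain_id), chain_id), function(ix) {
    h <- length(ix) %/% 2
    rep(c(1, 2), c(h, length(ix) - h)) + 2 * (chain_id[ix[1]] - 1)
  }), use.names = FALSE)
  grp <- split(seq_along(halves), halves)
  m <- length(grp); n <- min(lengths(grp))
  means <- vapply(grp, function(ix) colMeans(mat[ix, , drop = FALSE]),
                  numeric(ncol(mat)))
  vars <- vapply(grp, function(ix) apply(mat[ix, , drop = FALSE], 2, var),
                 numeric(ncol(mat)))
  if (is.null(dim(means))) { means <- matrix(means, nrow = 1); vars <- matrix(vars, nrow = 1) }
  B <- n * apply(means, 1, var)
  W <- rowMeans(vars)
  sqrt(pmax((n - 1) / n + B / (n * W), 0))
}

ess_basic <- function(mat, chain_id, max_lag = 50) {
  n_total <- nrow(mat)
  apply(mat, 2, function(v) {
    vc <- unlist(lapply(split(v, chain_id), function(x) x - mean(x)),
                 use.names = FALSE)
    va <- var(vc)
    if (va == 0) return(NA_real_)
    lag_max <- min(max_lag, length(vc) %/% 4)
    rho <- vapply(seq_len(lag_max), function(l) {
      mean(vc[seq_len(length(vc) - l)] * vc[(l + 1):length(vc)]) / va
    }, 0)
    # truncate at first negative autocorrelation
    neg <- which(rho < 0)
    if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
    max(n_total / (1 + 2 * sum(rho)), 1)
  })
}

gllvm_diagnostics <- function(draws, chain_id) {
  blocks <- list(alpha = draws$alpha, beta0 = draws$beta0,
                 beta = if (!is.null(draws$beta))
                   matrix(draws$beta, nrow = dim(draws$beta)[1]),
                 lambda = if (!is.null(draws$lambda))
                   matrix(draws$lambda, nrow = dim(draws$lambda)[1]),
                 phi = draws$phi)
  blocks <- Filter(Negate(is.null), blocks)
  out <- do.call(rbind, lapply(names(blocks), function(nm) {
    m <- blocks[[nm]]
    keep <- apply(m, 2, function(v) var(v) > 0)   # structural zeros excluded
    data.frame(block = nm,
               param = paste0(nm, "[", which(keep), "]"),
               rhat = split_rhat(m[, keep, drop = FALSE], chain_id),
               ess = ess_basic(m[, keep, drop = FALSE], chain_id),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Highest posterior density interval
#'
#' The minimal-width contiguous interval over the sorted draws containing
#' `ceiling(prob * n)` points.
#'
#' @param draws numeric vector of posterior draws (>= 10 unless degenerate).
#' @param prob probability mass, in (0, 1].
#' @return list of class `hpd_interval`: `lower`, `upper`, `width`, `prob`.
#' @export
hpd <- function(draws, prob = 0.95) {
  if (prob <= 0 || prob > 1) stop("prob must be in (0, 1]", call. = FALSE)
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 1) stop("no finite draws", call. = FALSE)
  x <- sort(draws)
  m <- ceiling(prob * n)
  if (m >= n) {
    lo <- x[1]; hi <- x[n]
  } else {
    widths <- x[seq(m, n)] - x[seq(1, n - m + 1)]
    i <- which.min(widths)
    lo <- x[i]; hi <- x[i + m - 1]
  }
  structure(list(lower = lo, upper = hi, width = hi - lo, prob = prob),
            class = "hpd_interval")
}

#' Classify covariate coefficients by HPD interval
#'
#' A coefficient is positive when the HPD lower bound exceeds zero, negative
#' when the upper bound is below zero, and non-significant when the interval
#' contains zero.  The interval width doubles as a niche-breadth proxy.
#'
#' @param fit a `gllvm_fit`.
#' @param prob HPD mass, default 0.95.
#' @return data.frame: taxon, covariate, estimate (posterior median), lower,
#'   upper, width, direction in \{positive, negative, ns\}.
#' @export
classify_coefficients <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "gllvm_fit"))
  t <- nrow(fit$taxa); k <- length(fit$covariate_names)
  out <- expand.grid(taxon = fit$taxa$display_name,
                     covariate = fit$covariate_names,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  est <- lower <- upper <- numeric(nrow(out))
  for (kk in seq_len(k)) for (j in seq_len(t)) {
    v <- fit$draws$beta[, j, kk]
    h <- hpd(v, prob)
    i <- (kk - 1) * t + j
    est[i] <- median(v); lower[i] <- h$lower; upper[i] <- h$upper
  }
  out$estimate <- est; out$lower <- lower; out$upper <- upper
  out$width <- upper - lower
  out$direction <- ifelse(lower > 0, "positive",
                          ifelse(upper < 0, "negative", "ns"))
  out$kingdom <- fit$taxa$kingdom[match(out$taxon, fit$taxa$display_name)]
  out$phylum <- fit$taxa$phylum[match(out$taxon, fit$taxa$display_name)]
  out
}

#' Serialize a fit to a directory (TSV draws + JSON spec)
#' @param fit a `gllvm_fit`.
#' @param dir output directory (created).
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "gllvm_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(m, name) write.table(
    as.data.frame(m), file.path(dir, paste0(name, ".tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  wt(fit$draws$alpha, "alpha"); wt(fit$draws$beta0, "beta0")
  wt(matrix(fit$draws$beta, nrow = dim(fit$draws$beta)[1]), "beta")
  if (!is.null(fit$draws$lambda)) {
    wt(matrix(fit$draws$lambda, nrow = dim(fit$draws$lambda)[1]), "lambda")
    wt(matrix(fit$draws$z, nrow = dim(fit$draws$z)[1]), "z")
  }
  wt(fit$draws$phi, "phi")
  wt(fit$diagnostics, "diagnostics")
  jsonlite::write_json(fit$model_spec, file.path(dir, "model_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
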
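# Synthetic communities drawn from the same model class the fitting code
# assumes: NB counts, per-sample effects, sparse covariate coefficients,
# low-rank latent loadings, and (optionally) modifier-dependent Gaussian-copula
# dependence injected between chosen taxon pairs.  Ground truth is carried
# along so every downstream stage has a recovery test.

# default cross-correlation of the simulated soil covariates, built from a
# two-factor structure (soil fertility, elevation) so it is always PSD; the
# fertility factor reproduces the strong TC-TN/TC-DOC/TC-pH correlation
# pattern typical of organic wetland soils.
default_env_correlation <- function(covariates) {
  k <- length(covariates)
  L <- matrix(0, k, 2, dimnames = list(covariates, NULL))
  set_if <- function(name, l, v) if (name %in% covariates) L[name, l] <<- v
  set_if("TC", 1, 0.95); set_if("TN", 1, 0.89); set_if("DOC", 1, 0.70)
  set_if("TP", 1, 0.60); set_if("CN", 1, 0.63); set_if("pH", 1, -0.58)
  set_if("elevation", 2, 0.80); set_if("pH", 2, -0.30)
  set_if("latitude", 2, 0.40); set_if("longitude", 2, -0.30)
  R <- L %*% t(L)
  diag(R) <- 1
  R
}

# typical measurement-scale location/spread used to emit a raw metadata table
default_env_scales <- function() {
  list(elevation = c(3722, 550), pH = c(7.8, 0.7), TC = c(100, 80),
       TN = c(6, 4), TP = c(1.15, 0.45), DOC = c(110, 55),
       CN = c(14, 6), E2E3 = c(6.2, 1.4), SUVA254 = c(2.2, 1.1),
       latitude = c(35.5, 1.8), longitude = c(96, 3.2))
}

#' Simulate an environmental gradient
#'
#' Draws per-site covariates from a multivariate normal with a configurable
#' cross-correlation (default: a positive-semidefinite two-factor structure
#' with strong positive TC-TN correlation), then standardizes them.
#'
#' @param n_sites number of sites (>= 4; 2-3 allowed with a message).
#' @param seed RNG seed.
#' @param covariates covariate names to simulate.
#' @param correlation target correlation matrix (must be positive definite
#'   after the factor default; checked by Cholesky).
#' @return list with `env` (an `env_matrix`), `raw` (measurement-scale
#'   data.frame including latitude/longitude geography), and `correlation`.
#' @export
simulate_environment <- function(n_sites, seed = 1,
                                 covariates = c("elevation", "pH", "TC", "TN",
                                                "CN", "TP", "DOC", "E2E3",
                                                "SUVA254", "latitude",
                                                "longitude"),
                                 correlation = NULL) {
  if (n_sites < 2) stop("need at least 2 sites", call. = FALSE)
  if (n_sites < 4) message("n_sites < 4: standardization will be very noisy")
  set.seed(seed)
  k <- length(covariates)
  if (is.null(correlation)) correlation <- default_env_correlation(covariates)
  ch <- tryCatch(chol(correlation),
                 error = function(e) stop("target correlation matrix is not positive definite",
                                          call. = FALSE))
  zmat <- matrix(rnorm(n_sites * k), n_sites, k) %*% ch
  colnames(zmat) <- covariates
  scales <- default_env_scales()
  raw <- as.data.frame(zmat)
  for (v in covariates) {
    sc <- scales[[v]]
    if (is.null(sc)) sc <- c(0, 1)
    raw[[v]] <- sc[1] + sc[2] * zmat[, v]
  }
  raw <- cbind(site = sprintf("S%02d", seq_len(n_sites)), raw)
  env <- standardize_env(raw, covariates = covariates)
  list(env = env, raw = raw, correlation = correlation)
}

#' Construct a ground-truth parameter set
#'
#' Defaults mirror a desk-scale version of a 43-site plateau gradient study:
#' sparse coefficients with magnitudes in \{0.5, 1, 2\}, two latent
#' dimensions, NB dispersions in \[1, 5\].
#'
#' @param env an `env_matrix` (defines sites and covariates).
#' @param n_taxa number of taxa, default 80.
#' @param d latent dimensions, default 2.
#' @param seed RNG seed.
#' @param beta_sparsity probability a coefficient is nonzero, default 0.2.
#' @param beta_values magnitudes sampled for nonzero coefficients.
#' @param lambda_sd SD of free loading entries; 0 disables the latent part.
#' @param phi_range range of NB dispersions.
#' @param mean_log_abundance mean of the per-taxon intercepts (log scale).
#' @param alpha_sd SD of the (sum-to-zero) per-site effects.
#' @param prop_bacteria fraction of taxa labelled bacterial; the rest fungal.
#' @return object of class `ground_truth`.
#' @export
make_ground_truth <- function(env, n_taxa = 80, d = 2, seed = 1,
                              beta_sparsity = 0.2,
                              beta_values = c(0.5, 1, 2),
                              lambda_sd = 0.7, phi_range = c(1, 5),
                              mean_log_abundance = log(30), alpha_sd = 0.5,
                              prop_bacteria = 0.6) {
  stopifnot(inherits(env, "env_matrix"), d >= 0)
  set.seed(seed)
  s <- nrow(env$values); k <- ncol(env$values)
  alpha <- rnorm(s, 0, alpha_sd); alpha <- alpha - mean(alpha)
  beta0 <- rnorm(n_taxa, mean_log_abundance, 0.6)
  beta <- matrix(0, n_taxa, k,
                 dimnames = list(NULL, env$covariate_names))
  nz <- matrix(runif(n_taxa * k) < beta_sparsity, n_taxa, k)
  beta[nz] <- sample(c(-1, 1), sum(nz), replace = TRUE) *
    sample(beta_values, sum(nz), replace = TRUE)
  lambda <- matrix(0, n_taxa, max(d, 1))[, seq_len(d), drop = FALSE]
  if (d > 0 && lambda_sd > 0) {
    lambda <- matrix(rnorm(n_taxa * d, 0, lambda_sd), n_taxa, d)
    for (l in seq_len(d)) {
      if (l <= n_taxa) lambda[l, ] [seq_len(d) > l] <- 0
      if (l <= n_taxa) lambda[l, l] <- abs(lambda[l, l])
    }
  } else if (d > 0) {
    lambda <- matrix(0, n_taxa, d)
  }
  phi <- runif(n_taxa, phi_range[1], phi_range[2])
  n_bact <- round(prop_bacteria * n_taxa)
  kingdom <- c(rep("Bacteria", n_bact), rep("Fungi", n_taxa - n_bact))
  phylum <- ifelse(kingdom == "Bacteria",
                   sprintf("BactPhylum%02d", 1 + (seq_len(n_taxa) - 1) %% 6),
                   sprintf("FungPhylum%02d", 1 + (seq_len(n_taxa) - 1) %% 3))
  taxa <- data.frame(
    display_name = sprintf("Order%03d", seq_len(n_taxa)),
    kingdom = kingdom, phylum = phylum,
    class = sprintf("Class%03d", seq_len(n_taxa)),
    order = sprintf("Order%03d", seq_len(n_taxa)),
    resolution_flag = "order",
    lineage = sprintf("%s;%s;Class%03d;Order%03d", kingdom, phylum,
                      seq_len(n_taxa), seq_len(n_taxa)),
    stringsAsFactors = FALSE)
  structure(list(alpha = alpha, beta0 = beta0, beta = beta, lambda = lambda,
                 d = d, phi = phi, taxa = taxa, shift_pairs = list()),
            class = "ground_truth")
}

truth_linpred <- function(env, truth, z) {
  eta <- outer(truth$alpha, truth$beta0, "+")
  eta <- eta + env$values %*% t(truth$beta)
  if (truth$d > 0) eta <- eta + z %*% t(truth$lambda)
  eta
}

#' Simulate a community from ground truth
#'
#' Latent scores are iid standard normal;
#' `log mu_ij = alpha_i + beta0_j + x_i' beta_j + z_i' lambda_j`, and counts
#' are negative binomial with `Var = mu + mu^2/phi_j`.
#'
#' @param env an `env_matrix` whose sites define the community.
#' @param truth a `ground_truth`.
#' @param seed RNG seed.
#' @return a `community_table`; attributes `truth`, `mu` and `z` carry the
#'   generating state for recovery tests.
#' @export
simulate_community <- function(env, truth, seed = 1) {
  stopifnot(inherits(env, "env_matrix"), inherits(truth, "ground_truth"))
  if (ncol(env$values) != ncol(truth$beta))
    stop("env and truth covariate dimensions differ", call. = FALSE)
  set.seed(seed)
  s <- nrow(env$values); t <- length(truth$beta0)
  z <- matrix(rnorm(s * max(truth$d, 1)), s)[, seq_len(max(truth$d, 0)), drop = FALSE]
  eta <- truth_linpred(env, truth, z)
  if (any(eta > 30))
    stop("linear predictor overflow (eta > 30); use smaller coefficients",
         call. = FALSE)
  mu <- exp(eta)
  y <- matrix(rnbinom(s * t, mu = mu, size = rep(truth$phi, each = s)), s, t)
  out <- community_table(y, truth$taxa, site_ids = rownames(env$values))
  attr(out, "truth") <- truth
  attr(out, "mu") <- mu
  attr(out, "z") <- z
  out
}

#' Inject modifier-dependent dependence into a taxon pair
#'
#' Re-samples the two taxa's counts with Gaussian-copula dependence while
#' preserving their NB margins: correlation `rho_low` in the lower tercile of
#' the modifier, `rho_high` in the upper tercile, and their mean in the middle
#' tercile (so the ground-truth conditional rank correlation is piecewise
#' constant and monotone).
#'
#' @param counts a `community_table` produced by [simulate_community()]
#'   (its `mu`/`truth` attributes supply the margins), or any table if `mu`
#'   and `phi` are given explicitly.
#' @param env the `env_matrix` used for simulation (modifier source).
#' @param pair_spec list with `taxon_a`, `taxon_b` (display names), `modifier`
#'   (covariate name), `rho_low`, `rho_high`.
#' @param seed RNG seed.
#' @param mu optional site x taxon NB mean matrix; default from `counts`.
#' @param phi optional per-taxon dispersions; default from `counts`.
#' @return the `community_table` with the pair's counts replaced; the spec is
#'   appended to `attr(, "truth")$shift_pairs` when truth is present.
#' @export
inject_conditional_dependence <- function(counts, env, pair_spec, seed = 1,
                                          mu = NULL, phi = NULL) {
  stopifnot(inherits(counts, "community_table"), inherits(env, "env_matrix"))
  if (abs(pair_spec$rho_low) >= 1 || abs(pair_spec$rho_high) >= 1)
    stop("|rho| must be < 1", call. = FALSE)
  ja <- match(pair_spec$taxon_a, counts$taxa$display_name)
  jb <- match(pair_spec$taxon_b, counts$taxa$display_name)
  if (is.na(ja) || is.na(jb))
    stop("pair references a non-existent taxon", call. = FALSE)
  if (!pair_spec$modifier %in% colnames(env$values))
    stop("modifier is not a covariate of env", call. = FALSE)
  truth <- attr(counts, "truth")
  if (is.null(mu)) mu <- attr(counts, "mu")
  if (is.null(phi) && !is.null(truth)) phi <- truth$phi
  if (is.null(mu) || is.null(phi))
    stop("NB margins unavailable: supply mu and phi or use a simulated table",
         call. = FALSE)
  set.seed(seed)
  s <- nrow(counts$counts)
  m <- env$values[, pair_spec$modifier]
  terc <- cut(rank(m, ties.method = "first"), breaks = 3, labels = FALSE)
  rho <- c(pair_spec$rho_low,
           (pair_spec$rho_low + pair_spec$rho_high) / 2,
           pair_spec$rho_high)[terc]
  u1 <- rnorm(s)
  u2 <- rho * u1 + sqrt(1 - rho^2) * rnorm(s)
  y <- counts$counts
  y[, ja] <- qnbinom(pnorm(u1), mu = mu[, ja], size = phi[ja])
  y[, jb] <- qnbinom(pnorm(u2), mu = mu[, jb], size = phi[jb])
  out <- community_table(y, counts$taxa, site_ids = counts$site_ids)
  if (!is.null(truth)) {
    truth$shift_pairs <- c(truth$shift_pairs, list(pair_spec))
    attr(out, "truth") <- truth
  }
  attr(out, "mu") <- mu
  attr(out, "z") <- attr(counts, "z")
  out
}

#' Simulate a specialist/generalist niche structure
#'
#' Builds a community in which "specialist" taxa are abundant, weakly
#' overdispersed and share strong latent loadings (tight niches, many
#' residual co-occurrences), while "generalist" taxa are sparse, noisy and
#' latent-free (broad niches, no detected interactions).  Used to test the
#' negative closeness ~ HPD-width relationship end to end.
#'
#' @param n_sites sites, default 43.
#' @param n_taxa taxa (half specialists), default 30.
#' @param seed RNG seed.
#' @return list `counts` (a `community_table`), `env`, `is_specialist`.
#' @export
simulate_niche_structure <- function(n_sites = 43, n_taxa = 30, seed = 1) {
  sim <- simulate_environment(n_sites, seed = seed,
                              covariates = c("elevation", "pH"))
  truth <- make_ground_truth(sim$env, n_taxa = n_taxa, d = 2, seed = seed,
                             beta_sparsity = 0, lambda_sd = 0)
  n_spec <- floor(n_taxa / 2)
  is_spec <- seq_len(n_taxa) <= n_spec
  set.seed(seed + 7L)
  lam <- matrix(0, n_taxa, 2)
  lam[is_spec, 1] <- 1.4 * sample(c(-1, 1), n_spec, TRUE)
  lam[is_spec, 2] <- 0.6 * rnorm(n_spec)
  lam[1, 2] <- 0; lam[1, 1] <- abs(lam[1, 1])
  lam[2, 2] <- abs(if (lam[2, 2] == 0) 0.6 else lam[2, 2])
  truth$lambda <- lam
  # specialists: abundant, weakly overdispersed, strongly loaded -> narrow
  # coefficient HPDs and high closeness; generalists: sparse, extremely
  # overdispersed, latent-free -> the data barely constrain their
  # coefficients (broad niches) and they sit outside the network
  truth$beta0 <- ifelse(is_spec, log(120), log(2)) + rnorm(n_taxa, 0, 0.2)
  truth$phi <- ifelse(is_spec, 5, 0.2)
  counts <- simulate_community(sim$env, truth, seed = seed + 13L)
  list(counts = counts, env = sim$env, is_specialist = is_spec, truth = truth)
}
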
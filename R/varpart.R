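# Variance partitioning of the linear predictor (minus intercept and sample
# effect) across covariate groups and the latent component, plus summary
# statistics of the resulting distribution.

#' Partition each taxon's modelled variance across covariate groups
#'
#' Per posterior draw and taxon, the component variance of a covariate group
#' is the empirical variance over sites of the summed within-group linear
#' predictor (which keeps within-group covariances); the latent component is
#' the variance of `z_i' lambda_j`.  Cross-group covariances are excluded
#' from the numerators, so proportions are normalized to sum to one and the
#' raw covariance remainder is recorded.  Row effects are excluded (they
#' absorb sequencing depth, not ecology).  Proportions are averaged over
#' draws.
#'
#' @param fit a `gllvm_fit` with at least one covariate.
#' @param groups named covariate->group map; defaults to the grouping stored
#'   in the fit.
#' @return object of class `varpart_result`: `proportions` (taxon x group
#'   matrix incl. "latent"), `total_explained` (non-latent sum),
#'   `covariance_remainder`, `taxa`.
#' @export
variance_partition <- function(fit, groups = NULL) {
  stopifnot(inherits(fit, "gllvm_fit"))
  if (is.null(groups)) groups <- fit$groups
  covs <- fit$covariate_names
  miss <- setdiff(covs, names(groups))
  if (length(miss))
    stop("group map missing covariates: ", paste(miss, collapse = ", "),
         call. = FALSE)
  has_latent <- fit$model_spec$d > 0 && !is.null(fit$draws$lambda)
  gl <- unique(unname(groups[covs]))
  gidx <- lapply(gl, function(g) which(groups[covs] == g))
  n <- dim(fit$draws$beta)[1]
  t <- nrow(fit$taxa)
  # site-standardized covariate values come from the env the fit was given;
  # reconstruct X from per-draw predictors is impossible, so the fit stores it
  X <- fit$env_values
  if (is.null(X))
    stop("fit does not carry env values; refit with this package version",
         call. = FALSE)
  ng <- length(gl) + as.integer(has_latent)
  acc <- matrix(0, t, ng)
  rem <- numeric(t)
  colvar <- function(m) {
    mu <- colMeans(m)
    colSums(m * m) / (nrow(m) - 1) - nrow(m) / (nrow(m) - 1) * mu^2
  }
  for (r in seq_len(n)) {
    B <- matrix(fit$draws$beta[r, , ], nrow = t)   # t x k
    comp <- matrix(0, t, ng)
    for (gi in seq_along(gl)) {
      Xg <- X[, gidx[[gi]], drop = FALSE]
      comp[, gi] <- colvar(Xg %*% t(B[, gidx[[gi]], drop = FALSE]))
    }
    if (has_latent) {
      L <- matrix(fit$draws$lambda[r, , ], nrow = t)
      Zr <- matrix(fit$draws$z[r, , ], ncol = ncol(L))
      comp[, ng] <- colvar(Zr %*% t(L))
      full <- colvar(X %*% t(B) + Zr %*% t(L))
    } else {
      full <- colvar(X %*% t(B))
    }
    tot <- rowSums(comp)
    tot[tot == 0] <- 1  # taxon with nothing modelled: all proportions zero
    acc <- acc + comp / tot
    rem <- rem + (full - rowSums(comp))
  }
  props <- acc / n
  colnames(props) <- c(gl, if (has_latent) "latent")
  rownames(props) <- fit$taxa$display_name
  structure(list(proportions = props,
                 total_explained = rowSums(props[, gl, drop = FALSE]),
                 covariance_remainder = rem / n,
                 taxa = fit$taxa),
            class = "varpart_result")
}

#' Summarize a variance partition per kingdom
#'
#' @param result a `varpart_result`.
#' @param threshold "more than" threshold on total explained variance
#'   (strict inequality), default 0.5.
#' @return list per kingdom: `mean_explained`, `sd_explained`, `n_above`,
#'   `pct_above`, `skewness`, and per-group median/IQR; kingdoms with no taxa
#'   are omitted.
#' @export
varpart_summaries <- function(result, threshold = 0.5) {
  stopifnot(inherits(result, "varpart_result"))
  kingdoms <- unique(result$taxa$kingdom)
  out <- lapply(kingdoms, function(kg) {
    ix <- which(result$taxa$kingdom == kg)
    if (!length(ix)) return(NULL)
    te <- result$total_explained[ix]
    groups <- setdiff(colnames(result$proportions), "latent")
    per_group <- do.call(rbind, lapply(groups, function(g) {
      v <- result$proportions[ix, g]
      q <- quantile(v, c(0.25, 0.75), type = QUANTILE_TYPE, names = FALSE)
      data.frame(group = g, median = median(v), q25 = q[1], q75 = q[2])
    }))
    list(kingdom = kg, n_taxa = length(ix),
         mean_explained = mean(te), sd_explained = sd(te),
         n_above = sum(te > threshold),
         pct_above = 100 * mean(te > threshold),
         skewness = if (length(ix) >= 3 && var(te) > 0) skewness(te) else NA_real_,
         per_group = per_group)
  })
  out <- Filter(Negate(is.null), out)
  names(out) <- vapply(out, `[[`, "", "kingdom")
  out
}

#' Adjusted Fisher-Pearson skewness
#'
#' The standardized third moment with the small-sample adjustment
#' `g1 * sqrt(n (n - 1)) / (n - 2)`.
#'
#' @param values numeric vector, n >= 3, nonzero variance.
#' @return scalar skewness.
#' @export
skewness <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 values", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("zero variance", call. = FALSE)
  g1 <- mean((values - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}
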
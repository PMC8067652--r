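# Covariate-adjusted and conditional Spearman correlations via cumulative
# probability models (CPMs) and probability-scale residuals (PSRs), and the
# detection/counting of interaction shifts along an environmental modifier.

link_code <- function(link) {
  link <- match.arg(link, c("logit", "probit"))
  c(logit = 0L, probit = 1L)[[link]]
}

#' Fit a cumulative probability model
#'
#' Ordinal cumulative-link regression treating every distinct response value
#' as a category (ties share a category); semiparametric in the response
#' distribution, which is what lets rank-based quantities survive
#' overdispersed counts.  With no covariates the fitted `P(Y <= y)` is the
#' empirical CDF.
#'
#' @param y numeric response, at least 2 distinct values, n >= 10.
#' @param Z covariate matrix (or NULL for intercept-only).
#' @param link "logit" (default) or "probit".
#' @return object of class `cpm_fit`: `yvals` (sorted distinct values),
#'   `gamma` (nondecreasing cutpoints), `theta`, `link`, `loglik`.
#' @export
fit_cpm <- function(y, Z = NULL, link = "logit") {
  if (any(!is.finite(y))) stop("non-finite response values", call. = FALSE)
  n <- length(y)
  if (n < 10) stop("need at least 10 observations", call. = FALSE)
  yvals <- sort(unique(y))
  if (length(yvals) < 2) stop("response is constant", call. = FALSE)
  cat <- match(y, yvals)
  Z <- prep_Z(Z, n)
  res <- cpm_fit_cpp(cat, length(yvals), Z, link_code(link), 100L, 1e-8)
  if (!res$converged)
    stop("CPM did not converge (possible complete separation); ",
         "consider fewer covariates or the probit link", call. = FALSE)
  structure(list(yvals = yvals, gamma = res$gamma, theta = res$theta,
                 link = link, loglik = res$loglik, n = n),
            class = "cpm_fit")
}

prep_Z <- function(Z, n) {
  if (is.null(Z)) return(matrix(numeric(0), n, 0))
  Z <- as.matrix(Z)
  if (nrow(Z) != n) stop("Z and y lengths differ", call. = FALSE)
  storage.mode(Z) <- "double"
  Z
}

#' Probability-scale residuals
#'
#' `PSR_i = P(Y < y_i | Z_i) - P(Y > y_i | Z_i)`, in \[-1, 1\]; for an
#' intercept-only fit this is twice the mid-rank empirical CDF minus one.
#'
#' @param fit a `cpm_fit`.
#' @param y,Z the data the model was fitted on.
#' @return numeric vector of residuals.
#' @export
psr <- function(fit, y, Z = NULL) {
  stopifnot(inherits(fit, "cpm_fit"))
  cat <- match(y, fit$yvals)
  if (any(is.na(cat))) stop("y contains values unseen at fit time", call. = FALSE)
  Z <- prep_Z(Z, length(y))
  cpm_psr_cpp(cat, length(fit$yvals), Z, fit$gamma, fit$theta,
              link_code(fit$link))
}

# PSRs for x and y adjusted for Z; closed form when Z is empty
psr_pair <- function(x, y, Z, link = "logit") {
  if (is.null(Z) || NCOL(Z) == 0) {
    list(px = psr_empirical(x), py = psr_empirical(y))
  } else {
    fx <- fit_cpm(x, Z, link); fy <- fit_cpm(y, Z, link)
    list(px = psr(fx, x, Z), py = psr(fy, y, Z))
  }
}

# intercept-only PSR: P(Y < y) - P(Y > y) from the empirical distribution
psr_empirical <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  (2 * r - n - 1) / n
}

#' Covariate-adjusted (partial) Spearman correlation
#'
#' Pearson correlation of the two probability-scale residual vectors after
#' adjusting each variable for Z with a CPM; reduces to (a consistent
#' estimate of) Spearman's rho when Z is empty.  Confidence interval by
#' nonparametric bootstrap over observations, refitting the CPMs in every
#' resample.
#'
#' @param x,y numeric vectors of common length.
#' @param Z covariate matrix or NULL.
#' @param n_boot bootstrap resamples (default 1000; 0 for point estimate
#'   only).
#' @param conf confidence level, default 0.95.
#' @param link CPM link.
#' @param seed RNG seed for the bootstrap.
#' @return list: `rho`, `ci` (or NULL), `n`, `n_boot`.
#' @export
partial_spearman <- function(x, y, Z = NULL, n_boot = 1000, conf = 0.95,
                             link = "logit", seed = 1) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant x or y", call. = FALSE)
  p <- psr_pair(x, y, Z, link)
  rho <- cor(p$px, p$py)
  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    bs <- vapply(seq_len(n_boot), function(b) {
      ix <- sample.int(n, n, replace = TRUE)
      pb <- tryCatch(psr_pair(x[ix], y[ix],
                              if (is.null(Z)) NULL else Z[ix, , drop = FALSE],
                              link),
                     error = function(e) NULL)
      if (is.null(pb) || sd(pb$px) == 0 || sd(pb$py) == 0) return(NA_real_)
      cor(pb$px, pb$py)
    }, 0)
    a <- (1 - conf) / 2
    ci <- unname(quantile(bs, c(a, 1 - a), na.rm = TRUE))
  }
  list(rho = rho, ci = ci, n = n, n_boot = n_boot)
}

# Gaussian-kernel Nadaraya-Watson smooth of v over modifier m, evaluated at g
nw_smooth <- function(v, m, g, bw) {
  W <- exp(-0.5 * (outer(g, m, "-") / bw)^2)
  drop(W %*% v) / rowSums(W)
}

cond_rho_at <- function(px, py, m, grid, bw) {
  sxy <- nw_smooth(px * py, m, grid, bw)
  sxx <- nw_smooth(px * px, m, grid, bw)
  syy <- nw_smooth(py * py, m, grid, bw)
  pmin(pmax(sxy / sqrt(sxx * syy), -1), 1)
}

#' Conditional Spearman correlation along a modifier
#'
#' Kernel-smoothed rank correlation between x and y as a function of a
#' numeric modifier:
#' `rho(m) = S[psr_x psr_y](m) / sqrt(S[psr_x^2](m) S[psr_y^2](m))`
#' with Gaussian-kernel Nadaraya-Watson smoothing `S` (rule-of-thumb
#' bandwidth by default).  PSRs are adjusted for `Z_adjust` with CPMs.
#' Bootstrap resamples sites (refitting CPMs) for pointwise intervals.
#'
#' @param x,y numeric vectors.
#' @param modifier numeric modifier vector.
#' @param Z_adjust adjustment covariates or NULL.
#' @param grid evaluation points; default the 10th-90th percentiles of the
#'   modifier in steps of 5.
#' @param bandwidth kernel bandwidth; default `bw.nrd0(modifier)`.
#' @param n_boot bootstrap resamples, default 1000 (0 = point estimates only).
#' @param conf pointwise interval level.
#' @param link CPM link.
#' @param seed RNG seed.
#' @return object of class `conditional_curve`: `grid`, `rho`, `lower`,
#'   `upper`, `boot` (n_boot x grid matrix), `bandwidth`, `modifier`.
#' @export
conditional_spearman <- function(x, y, modifier, Z_adjust = NULL, grid = NULL,
                                 bandwidth = NULL, n_boot = 1000, conf = 0.95,
                                 link = "logit", seed = 1) {
  n <- length(x)
  stopifnot(length(y) == n, length(modifier) == n)
  if (!is.numeric(modifier)) stop("modifier must be numeric", call. = FALSE)
  if (is.null(grid))
    grid <- unname(quantile(modifier, probs = seq(0.1, 0.9, by = 0.05)))
  if (any(grid < min(modifier) | grid > max(modifier)))
    stop("grid point outside the observed modifier range", call. = FALSE)
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(modifier)
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  p <- psr_pair(x, y, Z_adjust, link)
  rho <- cond_rho_at(p$px, p$py, modifier, grid, bandwidth)
  boot <- NULL; lower <- upper <- rep(NA_real_, length(grid))
  if (n_boot > 0) {
    set.seed(seed)
    boot <- matrix(NA_real_, n_boot, length(grid))
    for (b in seq_len(n_boot)) {
      ix <- sample.int(n, n, replace = TRUE)
      pb <- tryCatch(psr_pair(x[ix], y[ix],
                              if (is.null(Z_adjust)) NULL
                              else Z_adjust[ix, , drop = FALSE], link),
                     error = function(e) NULL)
      if (is.null(pb)) next
      boot[b, ] <- cond_rho_at(pb$px, pb$py, modifier[ix], grid, bandwidth)
    }
    a <- (1 - conf) / 2
    lower <- apply(boot, 2, quantile, probs = a, na.rm = TRUE)
    upper <- apply(boot, 2, quantile, probs = 1 - a, na.rm = TRUE)
  }
  structure(list(grid = grid, rho = rho, lower = lower, upper = upper,
                 boot = boot, bandwidth = bandwidth, modifier = modifier,
                 conf = conf, n_boot = n_boot),
            class = "conditional_curve")
}

#' Detect an interaction shift between two modifier quantiles
#'
#' Compares the conditional correlation at the `low_q` and `high_q` modifier
#' quantiles; the shift direction is the sign of `rho_high - rho_low` and it
#' is significant when the bootstrap interval of that difference excludes
#' zero.  Whether the correlation also changes sign is flagged separately.
#'
#' @param curve a `conditional_curve` whose grid covers both quantiles.
#' @param low_q,high_q modifier quantiles, defaults 0.1 and 0.9.
#' @param conf level for the difference interval, default 0.95.
#' @return list of class `shift_record`: `rho_low`, `rho_high`, `direction`,
#'   `significant`, `sign_change`, `diff_ci`.
#' @export
detect_shift <- function(curve, low_q = 0.1, high_q = 0.9, conf = 0.95) {
  stopifnot(inherits(curve, "conditional_curve"))
  qs <- quantile(curve$modifier, c(low_q, high_q))
  tolg <- 1e-8 + diff(range(curve$modifier)) * 1e-6
  ilo <- which.min(abs(curve$grid - qs[1]))
  ihi <- which.min(abs(curve$grid - qs[2]))
  if (abs(curve$grid[ilo] - qs[1]) > tolg || abs(curve$grid[ihi] - qs[2]) > tolg)
    stop("curve was not evaluated at the requested modifier quantiles",
         call. = FALSE)
  rho_low <- curve$rho[ilo]; rho_high <- curve$rho[ihi]
  significant <- FALSE; diff_ci <- c(NA_real_, NA_real_)
  if (!is.null(curve$boot)) {
    d <- curve$boot[, ihi] - curve$boot[, ilo]
    a <- (1 - conf) / 2
    diff_ci <- unname(quantile(d, c(a, 1 - a), na.rm = TRUE))
    significant <- is.finite(diff_ci[1]) &&
      (diff_ci[1] > 0 || diff_ci[2] < 0)
  }
  structure(list(rho_low = unname(rho_low), rho_high = unname(rho_high),
                 direction = if (rho_high >= rho_low) "positive" else "negative",
                 significant = significant,
                 sign_change = sign(rho_low) * sign(rho_high) < 0,
                 diff_ci = diff_ci, low_q = low_q, high_q = high_q),
            class = "shift_record")
}

#' Aggregate a community table to phylum level
#'
#' Within-phylum sum of counts per site (keeps the overdispersed count nature
#' the CPM expects).
#'
#' @param counts a `community_table`.
#' @return list: `counts` (site x phylum matrix), `kingdom` (named vector
#'   phylum -> kingdom).
#' @export
aggregate_phyla <- function(counts) {
  stopifnot(inherits(counts, "community_table"))
  ph <- counts$taxa$phylum
  ph[is.na(ph)] <- "Unclassified"
  phy <- unique(ph)
  m <- vapply(phy, function(p)
    rowSums(counts$counts[, ph == p, drop = FALSE]), numeric(nrow(counts$counts)))
  kingdom <- vapply(phy, function(p) counts$taxa$kingdom[ph == p][1], "")
  list(counts = m, kingdom = kingdom)
}

pairing_label <- function(k1, k2) {
  b <- sum(c(k1, k2) == "Bacteria")
  if (b == 2) "Bact-Bact" else if (b == 0) "Fung-Fung" else "Bact-Fung"
}

#' Scan phylum pairs for interaction shifts along modifiers
#'
#' For every pair of phyla and every modifier, estimates the conditional
#' Spearman correlation (adjusted for the other modifiers in `adjust_set`)
#' and tests for a shift between the 10th and 90th modifier percentiles.
#'
#' @param counts a `community_table` (aggregated to phylum internally).
#' @param env_raw data.frame of per-site metadata on the measurement scale
#'   (used for the modifiers and adjusters; standardization is irrelevant for
#'   rank-based quantities).
#' @param modifiers covariate names to scan, default elevation, CN, pH.
#' @param n_boot bootstrap resamples per pair.
#' @param seed RNG seed.
#' @param fdr if TRUE, Benjamini-Hochberg across pairs per modifier using
#'   bootstrap two-sided p-values (off by default; no correction mirrors the
#'   HPD-style usage).
#' @return data.frame of shift records, one row per (pair, modifier).
#' @export
shift_analysis <- function(counts, env_raw, modifiers = c("elevation", "CN", "pH"),
                           n_boot = 1000, seed = 1, fdr = FALSE) {
  agg <- aggregate_phyla(counts)
  env_raw <- normalize_meta_names(as.data.frame(env_raw))
  miss <- setdiff(modifiers, names(env_raw))
  if (length(miss)) stop("modifier not in metadata: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  phy <- colnames(agg$counts)
  pairs <- utils::combn(phy, 2, simplify = FALSE)
  rows <- list()
  ctr <- 0L
  for (mod in modifiers) {
    adjusters <- setdiff(modifiers, mod)
    Z <- if (length(adjusters))
      as.matrix(env_raw[, adjusters, drop = FALSE]) else NULL
    mvec <- env_raw[[mod]]
    for (pp in pairs) {
      xa <- agg$counts[, pp[1]]; xb <- agg$counts[, pp[2]]
      if (sd(xa) == 0 || sd(xb) == 0) next
      ctr <- ctr + 1L
      cur <- tryCatch(
        conditional_spearman(xa, xb, mvec, Z_adjust = Z,
                             grid = unname(quantile(mvec, c(0.1, 0.5, 0.9))),
                             n_boot = n_boot, seed = seed + ctr),
        error = function(e) NULL)
      if (is.null(cur)) next
      sh <- detect_shift(cur)
      rows[[length(rows) + 1L]] <- data.frame(
        phylum_a = pp[1], phylum_b = pp[2],
        pairing = pairing_label(agg$kingdom[pp[1]], agg$kingdom[pp[2]]),
        modifier = mod, rho_low = sh$rho_low, rho_high = sh$rho_high,
        direction = sh$direction, significant = sh$significant,
        sign_change = sh$sign_change,
        diff_lo = sh$diff_ci[1], diff_hi = sh$diff_ci[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phylum_a = character(), phylum_b = character(),
               pairing = character(), modifier = character(),
               rho_low = numeric(), rho_high = numeric(),
               direction = character(), significant = logical(),
               sign_change = logical(), diff_lo = numeric(),
               diff_hi = numeric())
  if (fdr && nrow(out)) {
    # approximate two-sided bootstrap p from the difference interval width is
    # not available post hoc; recompute from normal-theory on the CI instead
    zw <- (out$diff_hi - out$diff_lo) / (2 * stats::qnorm(0.975))
    zstat <- (out$rho_high - out$rho_low) / pmax(zw, 1e-12)
    p <- 2 * stats::pnorm(-abs(zstat))
    out$significant <- stats::p.adjust(p, "BH") < 0.05
  }
  out
}

#' Tabulate significant shifts
#'
#' Counts of significant shift records by domain pairing, modifier and
#' direction, formatted with pairings as rows.
#'
#' @param records data.frame from [shift_analysis()] (or rows of the same
#'   shape).
#' @return integer table: rows Bact-Bact / Fung-Fung / Bact-Fung, columns
#'   `<modifier>.<direction>`.
#' @export
count_shifts <- function(records) {
  pairings <- c("Bact-Bact", "Fung-Fung", "Bact-Fung")
  mods <- unique(records$modifier)
  if (!length(mods)) mods <- character()
  cols <- as.vector(outer(mods, c("positive", "negative"), paste, sep = "."))
  out <- matrix(0L, nrow = length(pairings), ncol = length(cols),
                dimnames = list(pairings, cols))
  sig <- records[records$significant %in% TRUE, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    cl <- paste(sig$modifier[i], sig$direction[i], sep = ".")
    out[sig$pairing[i], cl] <- out[sig$pairing[i], cl] + 1L
  }
  out
}
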
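# Residual (covariate-independent) correlations from the latent loadings,
# the co-occurrence graph over significant pairs, a component-scaled
# closeness centrality, and the niche-breadth (HPD width) regression.

#' Residual correlations from latent loadings
#'
#' Per posterior draw, `Omega = Lambda Lambda'` and
#' `rho_jk = Omega_jk / sqrt(Omega_jj Omega_kk)`; the point estimate is the
#' posterior median and a pair is significant when the equal-tailed credible
#' interval of its rho draws excludes zero.  A draw in which a taxon has an
#' exactly zero loading vector contributes no rho for that taxon's pairs
#' (excluded with a count).
#'
#' @param fit a `gllvm_fit` with d >= 1.
#' @param level credible level for significance, default 0.95.
#' @return list: `rho` (taxon x taxon, unit diagonal), `significant` (logical
#'   mask, diagonal FALSE), `level`, `n_excluded_draws`.
#' @export
residual_correlation <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "gllvm_fit"))
  if (fit$model_spec$d < 1 || is.null(fit$draws$lambda))
    stop("residual correlations require d >= 1 latent variables", call. = FALSE)
  n <- dim(fit$draws$lambda)[1]
  t <- nrow(fit$taxa)
  rho_draws <- array(NA_real_, dim = c(n, t, t))
  n_excluded <- 0L
  for (r in seq_len(n)) {
    L <- matrix(fit$draws$lambda[r, , ], nrow = t)
    om <- L %*% t(L)
    dg <- diag(om)
    zero <- dg == 0
    if (any(zero)) n_excluded <- n_excluded + sum(zero)
    sc <- sqrt(dg); sc[zero] <- NA
    rho_draws[r, , ] <- om / outer(sc, sc)
  }
  rho <- apply(rho_draws, c(2, 3), median, na.rm = TRUE)
  a <- (1 - level) / 2
  lo <- apply(rho_draws, c(2, 3), quantile, probs = a, na.rm = TRUE)
  hi <- apply(rho_draws, c(2, 3), quantile, probs = 1 - a, na.rm = TRUE)
  sig <- (lo > 0 | hi < 0)
  diag(sig) <- FALSE
  diag(rho) <- 1
  dimnames(rho) <- dimnames(sig) <-
    list(fit$taxa$display_name, fit$taxa$display_name)
  list(rho = rho, significant = sig, level = level,
       n_excluded_draws = n_excluded)
}

#' Build a residual co-occurrence network
#'
#' Unweighted undirected graph whose edges are the significant residual
#' correlations (sign kept as an edge attribute).  Computes the
#' component-scaled closeness of every taxon and its median significant
#' residual correlation.
#'
#' @param resid output of [residual_correlation()], or a `gllvm_fit` (in
#'   which case the correlations are computed first).
#' @param level credible level when `resid` is a fit.
#' @return object of class `residual_network`: `rho`, `significant`, `graph`
#'   (igraph), `closeness`, `median_cooccurrence`.
#' @export
build_network <- function(resid, level = 0.95) {
  if (inherits(resid, "gllvm_fit")) resid <- residual_correlation(resid, level)
  adj <- resid$significant
  adj <- adj | t(adj)          # symmetry guard
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  el <- igraph::as_edgelist(g)
  if (nrow(el))
    igraph::E(g)$sign <- sign(resid$rho[cbind(el[, 1], el[, 2])])
  med <- vapply(seq_len(ncol(adj)), function(j) {
    nb <- which(adj[, j])
    if (!length(nb)) NA_real_ else median(resid$rho[nb, j])
  }, 0)
  names(med) <- colnames(adj)
  structure(list(rho = resid$rho, significant = adj, graph = g,
                 closeness = closeness_centrality(adj),
                 median_cooccurrence = med, level = resid$level),
            class = "residual_network")
}

#' @export
print.residual_network <- function(x, ...) {
  cat(sprintf("residual_network: %d taxa, %d significant edges (level %.2f)\n",
              ncol(x$rho), sum(x$significant) / 2, x$level))
  invisible(x)
}

#' Component-scaled closeness centrality
#'
#' For node v in a connected component of size `n_c` inside a graph of `n`
#' nodes, closeness is `[(n_c - 1) / sum of hop distances within the
#' component] * [(n_c - 1) / (n - 1)]`; the second factor keeps values
#' comparable across components of a disconnected graph.  Isolated nodes get
#' zero.
#'
#' @param adj symmetric logical/0-1 adjacency matrix (no self loops).
#' @return numeric vector of closeness values, one per node.
#' @export
closeness_centrality <- function(adj) {
  adj <- adj != 0
  diag(adj) <- FALSE
  n <- ncol(adj)
  out <- numeric(n)
  if (n <= 1) return(out)
  D <- bfs_distances(adj)
  for (v in seq_len(n)) {
    comp <- which(is.finite(D[v, ]))
    nc <- length(comp)
    if (nc <= 1) { out[v] <- 0; next }
    out[v] <- ((nc - 1) / sum(D[v, comp])) * ((nc - 1) / (n - 1))
  }
  names(out) <- colnames(adj)
  out
}

# all-pairs hop distances by layered expansion of the reachability set
bfs_distances <- function(adj) {
  n <- ncol(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(TRUE, n)
  frontier <- diag(TRUE, n)
  step <- 0
  while (any(frontier)) {
    step <- step + 1
    nxt <- (frontier %*% adj) > 0
    nxt <- nxt & !reach
    if (!any(nxt)) break
    D[nxt] <- step
    reach <- reach | nxt
    frontier <- nxt
  }
  D
}

#' Regress closeness on HPD width (niche breadth vs centrality)
#'
#' Ordinary least squares of closeness on the per-taxon HPD width of the
#' chosen covariate's coefficient; also fits the same regression with the
#' median residual co-occurrence as the response (both responses circulate
#' in the literature for this relationship).
#'
#' @param fit a `gllvm_fit`.
#' @param network a `residual_network` built from the same fit.
#' @param covariate covariate name whose coefficient widths define niche
#'   breadth.
#' @param prob HPD mass for the widths, default 0.95.
#' @return data.frame with one row per response (`closeness`,
#'   `median_cooccurrence`): slope, intercept, r_squared, n_taxa.
#' @export
niche_regression <- function(fit, network, covariate, prob = 0.95) {
  stopifnot(inherits(fit, "gllvm_fit"), inherits(network, "residual_network"))
  kk <- match(covariate, fit$covariate_names)
  if (is.na(kk)) stop("unknown covariate: ", covariate, call. = FALSE)
  t <- nrow(fit$taxa)
  widths <- vapply(seq_len(t), function(j)
    hpd(fit$draws$beta[, j, kk], prob)$width, 0)
  if (sd(widths) == 0) stop("zero variance in HPD widths", call. = FALSE)
  fit_one <- function(y) {
    ok <- is.finite(y) & is.finite(widths)
    if (sum(ok) < 3) return(data.frame(slope = NA_real_, intercept = NA_real_,
                                       r_squared = NA_real_, n_taxa = sum(ok)))
    m <- lm(y[ok] ~ widths[ok])
    data.frame(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
               r_squared = summary(m)$r.squared, n_taxa = sum(ok))
  }
  out <- rbind(fit_one(network$closeness),
               fit_one(network$median_cooccurrence))
  out <- cbind(response = c("closeness", "median_cooccurrence"),
               covariate = covariate, out)
  rownames(out) <- NULL
  out
}

#' Export a network as an edge-list TSV (and optionally GraphML)
#' @param network a `residual_network`.
#' @param path output TSV path.
#' @param graphml optional GraphML output path.
#' @export
write_network <- function(network, path, graphml = NULL) {
  el <- igraph::as_edgelist(network$graph)
  rho <- if (nrow(el)) network$rho[cbind(el[, 1], el[, 2])] else numeric()
  out <- data.frame(taxon_a = el[, 1], taxon_b = el[, 2], rho = rho,
                    sign = sign(rho))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml)) {
    g <- network$graph
    igraph::V(g)$closeness <- unname(network$closeness)
    if (nrow(el)) igraph::E(g)$rho <- rho
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}
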
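# Shared fixtures.  Everything is generated in code; the one moderately
# expensive GLLVM fit is memoized so several test files can reuse it.

.cache <- new.env(parent = emptyenv())

shared_fit <- function() {
  if (is.null(.cache$shared)) {
    sim <- simulate_environment(43, seed = 7,
                                covariates = c("elevation", "pH", "TC", "TN"))
    truth <- make_ground_truth(sim$env, n_taxa = 15, d = 2, seed = 7)
    comm <- simulate_community(sim$env, truth, seed = 8)
    fit <- suppressWarnings(
      fit_gllvm(comm, sim$env, d = 2, n_chains = 2, n_draws = 300,
                n_warmup = 600, seed = 9))
    .cache$shared <- list(sim = sim, truth = truth, comm = comm, fit = fit)
  }
  .cache$shared
}

# minimal hand-built fit object for arithmetic-level tests of the posterior
# summary operations (no MCMC involved)
fake_fit <- function(beta, lambda = NULL, z = NULL, X,
                     groups = NULL, n_draws = 20, jitter = 0,
                     kingdom = NULL) {
  t <- nrow(beta); k <- ncol(beta)
  d <- if (is.null(lambda)) 0 else ncol(lambda)
  covn <- colnames(X)
  if (is.null(covn)) covn <- paste0("x", seq_len(k))
  taxa <- data.frame(
    display_name = paste0("T", seq_len(t)),
    kingdom = if (is.null(kingdom)) rep("Bacteria", t) else kingdom,
    phylum = paste0("P", 1 + (seq_len(t) - 1) %% 3),
    class = paste0("C", seq_len(t)), order = paste0("T", seq_len(t)),
    resolution_flag = "order", lineage = paste0("L", seq_len(t)),
    stringsAsFactors = FALSE)
  rep_jitter <- function(m) {
    out <- array(rep(as.vector(m), each = n_draws),
                 dim = c(n_draws, nrow(m), ncol(m)))
    if (jitter > 0) out <- out + rnorm(length(out), 0, jitter)
    out
  }
  draws <- list(
    alpha = matrix(0, n_draws, nrow(X)),
    beta0 = matrix(0, n_draws, t),
    beta = rep_jitter(beta),
    lambda = if (d > 0) rep_jitter(lambda),
    z = if (d > 0) rep_jitter(z),
    phi = matrix(2, n_draws, t))
  dimnames(draws$beta) <- list(NULL, taxa$display_name, covn)
  if (is.null(groups)) groups <- setNames(covn, covn)
  structure(list(
    draws = draws, chain_id = rep(1:2, length.out = n_draws),
    n_chains = 2, n_draws = n_draws / 2,
    diagnostics = data.frame(), converged = TRUE,
    taxa = taxa, site_ids = rownames(X),
    covariate_names = covn, groups = groups, env_values = X,
    model_spec = list(family = "negative_binomial", d = d, prior_sd = 10,
                      n_chains = 2, n_draws = n_draws / 2)),
    class = "gllvm_fit")
}

# write a small taxon-by-site counts file (text fixture built in code)
write_counts_fixture <- function(path, lineages, counts, sites) {
  df <- data.frame(taxonomy = lineages, counts, check.names = FALSE)
  colnames(df) <- c("taxonomy", sites)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent all-pairs shortest-path oracle (Floyd-Warshall)
floyd_distances <- function(adj) {
  n <- ncol(adj)
  D <- matrix(Inf, n, n)
  D[adj != 0] <- 1
  diag(D) <- 0
  for (m in seq_len(n))
    D <- pmin(D, outer(D[, m], D[m, ], "+"))
  D
}

# closeness oracle from first principles on the oracle distances
closeness_oracle <- function(adj) {
  n <- ncol(adj)
  D <- floyd_distances(adj)
  vapply(seq_len(n), function(v) {
    comp <- which(is.finite(D[v, ]))
    nc <- length(comp)
    if (nc <= 1 || n <= 1) return(0)
    ((nc - 1) / sum(D[v, comp])) * ((nc - 1) / (n - 1))
  }, 0)
}

# all undirected graphs on n nodes, as adjacency matrices
all_graphs <- function(n) {
  ne <- n * (n - 1) / 2
  ut <- which(upper.tri(matrix(0, n, n)))
  lapply(seq_len(2^ne) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(ne)]
    a <- matrix(0L, n, n)
    a[ut] <- bits
    a + t(a)
  })
}
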
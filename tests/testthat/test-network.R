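test_that("residual correlations follow Lambda Lambda' arithmetic", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  lam <- rbind(c(1, 0), c(1, 0), c(0, 1), c(1, 1))
  ff <- fake_fit(beta = matrix(0, 4, 2), lambda = lam,
                 z = matrix(rnorm(20), 10, 2), X = X, n_draws = 20)
  rc <- residual_correlation(ff)
  expect_equal(rc$rho[1, 2], 1)                    # identical loadings
  expect_equal(rc$rho[1, 3], 0)                    # orthogonal loadings
  expect_equal(rc$rho[1, 4], 1 / sqrt(2))          # (1,1) vs (1,0)
  expect_true(isSymmetric(rc$rho))
  expect_true(all(diag(rc$rho) == 1))
})

test_that("rho is invariant to orthogonal rotation of the loadings", {
  set.seed(30)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  lam <- matrix(rnorm(12), 6, 2)
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  z <- matrix(rnorm(20), 10, 2)
  r1 <- residual_correlation(fake_fit(matrix(0, 6, 2), lam, z, X))$rho
  r2 <- residual_correlation(fake_fit(matrix(0, 6, 2), lam %*% R, z, X))$rho
  expect_lt(max(abs(r1 - r2)), 1e-10)
})

test_that("the edge set shrinks weakly as the credible level rises", {
  fit <- shared_fit()$fit
  n90 <- sum(residual_correlation(fit, 0.90)$significant)
  n95 <- sum(residual_correlation(fit, 0.95)$significant)
  n99 <- sum(residual_correlation(fit, 0.99)$significant)
  expect_true(n90 >= n95 && n95 >= n99)
})

test_that("closeness matches hand-computed values on canonical graphs", {
  # path A-B-C
  p3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(unname(closeness_centrality(p3)), c(2 / 3, 1, 2 / 3))
  # isolated node gets zero; a connected pair is scaled by component size
  g4 <- matrix(0, 4, 4); g4[1, 2] <- g4[2, 1] <- 1
  expect_equal(unname(closeness_centrality(g4)), c(1 / 3, 1 / 3, 0, 0))
  # complete graph: all equal to 1
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  expect_equal(unname(closeness_centrality(k5)), rep(1, 5))
})

test_that("build_network assembles graph, closeness and median co-occurrence", {
  fit <- shared_fit()$fit
  net <- build_network(fit)
  expect_s3_class(net, "residual_network")
  expect_equal(length(net$closeness), nrow(fit$taxa))
  expect_true(all(net$closeness >= 0 & net$closeness <= 1))
  expect_false(any(diag(net$significant)))
  iso <- colSums(net$significant) == 0
  expect_true(all(net$closeness[iso] == 0))
  expect_true(all(is.na(net$median_cooccurrence[iso])))
  expect_equal(igraph::vcount(net$graph), nrow(fit$taxa))
})

test_that("niche_regression recovers an exact linear relationship", {
  set.seed(31)
  t <- 12
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  ff <- fake_fit(matrix(0, t, 2), X = X, n_draws = 100)
  widths <- seq(0.2, 1.5, length.out = t)
  for (j in seq_len(t))   # uniform draws -> hpd width ~ 0.95 * span
    ff$draws$beta[, j, 1] <- seq(0, widths[j] / 0.95, length.out = 100)
  w_real <- vapply(seq_len(t), function(j) hpd(ff$draws$beta[, j, 1])$width, 0)
  net <- list(closeness = 1 - 0.5 * w_real,
              median_cooccurrence = rep(NA_real_, t))
  class(net) <- "residual_network"
  nr <- suppressWarnings(niche_regression(ff, net, "a"))
  row <- nr[nr$response == "closeness", ]
  expect_equal(row$slope, -0.5, tolerance = 1e-8)
  expect_equal(row$r_squared, 1, tolerance = 1e-8)
})

test_that("shuffled widths give near-zero r-squared", {
  set.seed(32)
  t <- 200
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  ff <- fake_fit(matrix(0, t, 2), X = X, n_draws = 50)
  for (j in seq_len(t))
    ff$draws$beta[, j, 1] <- rnorm(50, 0, runif(1, 0.1, 2))
  net <- list(closeness = runif(t), median_cooccurrence = rep(NA_real_, t))
  class(net) <- "residual_network"
  nr <- niche_regression(ff, net, "a")
  expect_lt(nr$r_squared[nr$response == "closeness"], 0.05)
})

test_that("niche_regression validates inputs", {
  fit <- shared_fit()$fit
  net <- build_network(fit)
  expect_error(niche_regression(fit, net, "nope"), "unknown covariate")
})

test_that("network edge export writes a well-formed TSV", {
  net <- build_network(shared_fit()$fit)
  p <- withr::local_tempfile(fileext = ".tsv")
  g <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, p, graphml = g)
  el <- read.delim(p)
  expect_named(el, c("taxon_a", "taxon_b", "rho", "sign"))
  if (nrow(el)) expect_true(all(abs(el$rho) <= 1))
  expect_true(file.exists(g))
  g2 <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::vcount(g2), ncol(net$rho))
})
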
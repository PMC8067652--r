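test_that("generators are deterministic under a fixed seed", {
  a <- simulate_environment(12, seed = 42)
  b <- simulate_environment(12, seed = 42)
  expect_identical(a$env$values, b$env$values)
  tra <- make_ground_truth(a$env, n_taxa = 10, seed = 5)
  ca <- simulate_community(a$env, tra, seed = 6)
  cb <- simulate_community(b$env, make_ground_truth(b$env, n_taxa = 10, seed = 5),
                           seed = 6)
  expect_identical(ca$counts, cb$counts)
})

test_that("identity target correlation yields empirically uncorrelated covariates", {
  sim <- simulate_environment(10000, seed = 1,
                              covariates = c("elevation", "pH", "TC"),
                              correlation = diag(3))
  r <- cor(sim$env$values)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("default correlation structure is PD and reproduces a strong TC-TN link", {
  sim <- simulate_environment(5000, seed = 2)
  r <- cor(sim$env$values)
  expect_gt(r["TC", "TN"], 0.7)
  expect_lt(r["TC", "pH"], -0.3)
  bad <- matrix(c(1, 2, 2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(simulate_environment(10, covariates = c("a", "b"),
                                    correlation = bad), "positive definite")
})

test_that("NB margins have the requested mean (phi -> infinity limit)", {
  sim <- simulate_environment(2000, seed = 3, covariates = c("elevation", "pH"))
  truth <- make_ground_truth(sim$env, n_taxa = 3, d = 0, seed = 3,
                             beta_sparsity = 0, lambda_sd = 0,
                             mean_log_abundance = log(50), alpha_sd = 0)
  truth$beta0 <- rep(log(50), 3)
  truth$phi <- rep(1e6, 3)
  comm <- simulate_community(sim$env, truth, seed = 4)
  m <- colMeans(comm$counts)
  se <- apply(comm$counts, 2, sd) / sqrt(2000)
  expect_true(all(abs(m - 50) < 3 * se))
})

test_that("shared latent loadings induce co-occurrence", {
  sim <- simulate_environment(500, seed = 5, covariates = c("elevation", "pH"))
  truth <- make_ground_truth(sim$env, n_taxa = 2, d = 2, seed = 5,
                             beta_sparsity = 0, lambda_sd = 0, alpha_sd = 0)
  truth$lambda <- rbind(c(1, 0), c(1, 0))
  comm <- simulate_community(sim$env, truth, seed = 6)
  expect_gt(cor(log1p(comm$counts[, 1]), log1p(comm$counts[, 2])), 0.3)
})

test_that("overflowing linear predictors raise a helpful error", {
  sim <- simulate_environment(10, seed = 7, covariates = c("elevation", "pH"))
  truth <- make_ground_truth(sim$env, n_taxa = 3, d = 0, seed = 7,
                             mean_log_abundance = 40)
  expect_error(simulate_community(sim$env, truth, seed = 8), "overflow")
})

test_that("zero-correlation copula injection preserves NB margins", {
  sim <- simulate_environment(500, seed = 9, covariates = c("elevation", "CN"))
  truth <- make_ground_truth(sim$env, n_taxa = 4, d = 0, seed = 9,
                             beta_sparsity = 0, lambda_sd = 0, alpha_sd = 0)
  comm <- simulate_community(sim$env, truth, seed = 10)
  spec <- list(taxon_a = "Order001", taxon_b = "Order002", modifier = "CN",
               rho_low = 0, rho_high = 0)
  inj <- inject_conditional_dependence(comm, sim$env, spec, seed = 11)
  ks <- suppressWarnings(stats::ks.test(inj$counts[, 1], comm$counts[, 1]))
  expect_gt(ks$p.value, 0.01)
})

test_that("copula injection controls conditional dependence by tercile", {
  sim <- simulate_environment(300, seed = 12, covariates = c("elevation", "CN"))
  truth <- make_ground_truth(sim$env, n_taxa = 2, d = 0, seed = 12,
                             beta_sparsity = 0, lambda_sd = 0, alpha_sd = 0)
  comm <- simulate_community(sim$env, truth, seed = 13)
  spec <- list(taxon_a = "Order001", taxon_b = "Order002", modifier = "CN",
               rho_low = 0.8, rho_high = -0.8)
  inj <- inject_conditional_dependence(comm, sim$env, spec, seed = 14)
  m <- sim$env$values[, "CN"]
  terc <- cut(rank(m, ties.method = "first"), 3, labels = FALSE)
  rlo <- cor(inj$counts[terc == 1, 1], inj$counts[terc == 1, 2],
             method = "spearman")
  rhi <- cor(inj$counts[terc == 3, 1], inj$counts[terc == 3, 2],
             method = "spearman")
  expect_gt(rlo, 0.4)
  expect_lt(rhi, -0.4)
})

test_that("copula injection validates its inputs", {
  sim <- simulate_environment(30, seed = 15, covariates = c("elevation", "CN"))
  truth <- make_ground_truth(sim$env, n_taxa = 2, d = 0, seed = 15)
  comm <- simulate_community(sim$env, truth, seed = 16)
  expect_error(inject_conditional_dependence(
    comm, sim$env, list(taxon_a = "nope", taxon_b = "Order002",
                        modifier = "CN", rho_low = 0, rho_high = 0)),
    "non-existent taxon")
  expect_error(inject_conditional_dependence(
    comm, sim$env, list(taxon_a = "Order001", taxon_b = "Order002",
                        modifier = "CN", rho_low = 1, rho_high = 0)),
    "rho")
  expect_error(inject_conditional_dependence(
    comm, sim$env, list(taxon_a = "Order001", taxon_b = "Order002",
                        modifier = "DOC", rho_low = 0, rho_high = 0)),
    "modifier")
})

test_that("specialist/generalist structure has the designed contrast", {
  ns <- simulate_niche_structure(43, 20, seed = 17)
  expect_equal(sum(ns$is_specialist), 10)
  spec_mean <- mean(ns$counts$counts[, ns$is_specialist])
  gen_mean <- mean(ns$counts$counts[, !ns$is_specialist])
  expect_gt(spec_mean, 5 * gen_mean)
})
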
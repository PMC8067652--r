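test_that("hpd returns the minimal-width interval", {
  expect_equal(unclass(hpd(rep(3, 20)))[c("lower", "upper", "width")],
               list(lower = 3, upper = 3, width = 0))
  x <- rnorm(500)
  h1 <- hpd(x, prob = 1)
  expect_equal(c(h1$lower, h1$upper), range(x))
  expect_error(hpd(x, prob = 0), "prob")
  # skewed draws: HPD must be narrower than the equal-tailed interval
  set.seed(1)
  y <- rexp(20000)
  h <- hpd(y, 0.9)
  et <- unname(diff(quantile(y, c(0.05, 0.95))))
  expect_lt(h$width, et)
  expect_equal(h$lower, min(y))  # mode at zero for exponential draws
})

test_that("hpd endpoints match the analytic normal interval", {
  set.seed(42)
  x <- rnorm(1e5)
  h <- hpd(x, 0.95)
  expect_lt(abs(h$lower + 1.96), 0.05)
  expect_lt(abs(h$upper - 1.96), 0.05)
})

test_that("hpd width is non-decreasing in prob", {
  set.seed(2)
  for (x in list(rnorm(500), rexp(500), sample(1:5, 500, TRUE))) {
    expect_lte(hpd(x, 0.5)$width, hpd(x, 0.95)$width)
  }
})

test_that("classify_coefficients applies the HPD-excludes-zero rule", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  beta <- rbind(c(0.65, 0), c(-0.65, 0), c(0.05, 0))
  ff <- fake_fit(beta, X = X, n_draws = 200)
  # spread draws uniformly so the intervals are known windows
  ff$draws$beta[, 1, 1] <- seq(0.2, 1.1, length.out = 200)    # positive
  ff$draws$beta[, 2, 1] <- seq(-1.1, -0.2, length.out = 200)  # negative
  ff$draws$beta[, 3, 1] <- seq(-0.3, 0.4, length.out = 200)   # spans zero
  cl <- classify_coefficients(ff, prob = 0.95)
  got <- cl$direction[cl$covariate == "a"]
  expect_equal(got, c("positive", "negative", "ns"))
  expect_equal(cl$estimate[cl$covariate == "a"][1],
               median(ff$draws$beta[, 1, 1]))
})

test_that("fit_gllvm validates inputs", {
  sh <- shared_fit()
  expect_error(fit_gllvm(sh$comm, sh$sim$env, d = -1), "d must")
  small <- community_table(sh$comm$counts[1:3, ], sh$comm$taxa,
                           sh$comm$site_ids[1:3])
  env3 <- sh$sim$env; env3$values <- env3$values[1:3, ]
  expect_error(fit_gllvm(small, env3, d = 2), "d \\+ 2")
  zc <- sh$comm; zc$counts[, 2] <- 0L
  expect_error(fit_gllvm(zc, sh$sim$env), "all-zero")
})

test_that("posterior draws respect structural constraints", {
  fit <- shared_fit()$fit
  lam <- fit$draws$lambda
  expect_true(all(lam[, 1, 2] == 0))        # upper triangle fixed at zero
  expect_true(all(lam[, 1, 1] > 0))         # diagonals positive
  expect_true(all(lam[, 2, 2] > 0))
  expect_true(all(fit$draws$phi > 0))
  # reported row effects satisfy the sum-to-zero convention
  expect_lt(max(abs(rowSums(fit$draws$alpha))), 1e-8)
  expect_true(is.data.frame(fit$diagnostics))
  expect_true(all(c("rhat", "ess") %in% names(fit$diagnostics)))
})

test_that("fits are reproducible under a fixed seed", {
  sim <- simulate_environment(20, seed = 30, covariates = c("elevation", "pH"))
  truth <- make_ground_truth(sim$env, n_taxa = 6, d = 1, seed = 30)
  comm <- simulate_community(sim$env, truth, seed = 31)
  f1 <- suppressWarnings(fit_gllvm(comm, sim$env, d = 1, n_chains = 1,
                                   n_draws = 50, n_warmup = 100, seed = 5))
  f2 <- suppressWarnings(fit_gllvm(comm, sim$env, d = 1, n_chains = 1,
                                   n_draws = 50, n_warmup = 100, seed = 5))
  expect_identical(f1$draws$beta, f2$draws$beta)
  expect_identical(f1$draws$lambda, f2$draws$lambda)
})

test_that("d = 0 degenerates to NB regression and downstream latent ops raise", {
  sim <- simulate_environment(20, seed = 33, covariates = c("elevation", "pH"))
  truth <- make_ground_truth(sim$env, n_taxa = 5, d = 0, seed = 33)
  comm <- simulate_community(sim$env, truth, seed = 34)
  fit <- suppressWarnings(fit_gllvm(comm, sim$env, d = 0, n_chains = 1,
                                    n_draws = 50, n_warmup = 100, seed = 6))
  expect_null(fit$draws$lambda)
  expect_error(residual_correlation(fit), "d >= 1")
})

test_that("a strong simulated coefficient is recovered as significant", {
  sim <- simulate_environment(43, seed = 35, covariates = c("elevation", "pH"))
  truth <- make_ground_truth(sim$env, n_taxa = 10, d = 2, seed = 35,
                             beta_sparsity = 0, lambda_sd = 0.5)
  truth$beta[1, "elevation"] <- 2
  comm <- simulate_community(sim$env, truth, seed = 36)
  fit <- suppressWarnings(fit_gllvm(comm, sim$env, d = 2, n_chains = 2,
                                    n_draws = 250, n_warmup = 600, seed = 7))
  cl <- classify_coefficients(fit)
  expect_equal(cl$direction[cl$taxon == "Order001" &
                              cl$covariate == "elevation"], "positive")
})

test_that("well-identified coefficients are robust to the prior SD (10 vs 100)", {
  sim <- simulate_environment(43, seed = 37, covariates = c("elevation", "pH"))
  truth <- make_ground_truth(sim$env, n_taxa = 8, d = 0, seed = 37,
                             beta_sparsity = 0.5, beta_values = c(1, 2))
  comm <- simulate_community(sim$env, truth, seed = 38)
  med <- lapply(c(10, 100), function(ps) {
    fit <- suppressWarnings(
      fit_gllvm(comm, sim$env, d = 0, n_chains = 2, n_draws = 300,
                n_warmup = 600, prior_sd = ps, seed = 10))
    apply(fit$draws$beta, c(2, 3), median)
  })
  expect_lt(max(abs(med[[1]] - med[[2]])), 0.1)
})

test_that("write_fit serializes draws and spec", {
  fit <- shared_fit()$fit
  dir <- withr::local_tempdir()
  write_fit(fit, dir)
  expect_true(all(file.exists(file.path(dir, c("alpha.tsv", "beta.tsv",
                                               "lambda.tsv", "phi.tsv",
                                               "model_spec.json")))))
  spec <- jsonlite::read_json(file.path(dir, "model_spec.json"))
  expect_equal(spec$d, 2)
})
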
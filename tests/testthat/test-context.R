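test_that("intercept-only CPM reproduces the empirical CDF", {
  set.seed(40)
  y <- rnbinom(80, mu = 15, size = 1.5)
  f <- fit_cpm(y)
  emp <- cumsum(table(factor(y, levels = f$yvals))) / length(y)
  expect_lt(max(abs(plogis(f$gamma) - head(emp, -1))), 1e-6)
  expect_false(is.unsorted(f$gamma))
  expect_error(fit_cpm(rep(3, 20)), "constant")
  expect_error(fit_cpm(c(y, NA)), "non-finite")
  expect_error(fit_cpm(y[1:5]), "at least 10")
})

test_that("binary-response CPM equals ordinary logistic regression", {
  set.seed(41)
  z <- rnorm(150)
  y <- rbinom(150, 1, plogis(0.3 + 0.9 * z))
  f <- fit_cpm(y, Z = cbind(z))
  g <- glm(y ~ z, family = binomial)
  expect_equal(unname(f$theta), unname(coef(g)[2]), tolerance = 1e-5)
  expect_equal(-f$gamma, unname(coef(g)[1]), tolerance = 1e-5)
})

test_that("probability-scale residuals obey their closed-form properties", {
  set.seed(42)
  # tie-free sample: PSR at the maximum is (n-1)/n; median point is 0
  x <- sample(seq_len(101))
  f <- fit_cpm(x)
  p <- psr(f, x)
  expect_equal(p[which.max(x)], 100 / 101)
  expect_equal(p[x == 51], 0)        # empirical median of odd tie-free sample
  expect_true(all(p >= -1 & p <= 1))
  # intercept-only PSR equals twice the mid-rank CDF minus one
  y <- rnbinom(100, mu = 10, size = 2)
  fy <- fit_cpm(y)
  r <- rank(y, ties.method = "average")
  expect_equal(psr(fy, y), (2 * r - length(y) - 1) / length(y),
               tolerance = 1e-6)
  expect_lt(abs(mean(psr(fy, y))), 0.02)
})

test_that("partial Spearman with empty Z matches classical Spearman", {
  set.seed(43)
  x <- rnorm(100)
  y <- x + 0.8 * rnorm(100)
  ps <- partial_spearman(x, y, n_boot = 0)
  expect_lt(abs(ps$rho - cor(x, y, method = "spearman")), 0.02)
  # symmetry and monotone invariance
  expect_equal(ps$rho, partial_spearman(y, x, n_boot = 0)$rho)
  expect_equal(ps$rho, partial_spearman(exp(x), y^3 + 2 * y, n_boot = 0)$rho,
               tolerance = 1e-10)
  expect_error(partial_spearman(rep(1, 50), rnorm(50)), "constant")
})

test_that("adjusting for a shared confounder removes spurious correlation", {
  set.seed(44)
  z <- rnorm(500)
  x <- z + 0.3 * rnorm(500)
  y <- z + 0.3 * rnorm(500)
  expect_gt(cor(x, y, method = "spearman"), 0.8)
  ps <- partial_spearman(x, y, Z = cbind(z), n_boot = 200, seed = 4)
  expect_lt(abs(ps$rho), 0.1)
  expect_true(ps$ci[1] <= ps$rho && ps$rho <= ps$ci[2])
})

test_that("null variables stay uncorrelated after adjustment", {
  set.seed(45)
  x <- rnorm(1000); y <- rnorm(1000); z <- rnorm(1000)
  expect_lt(abs(partial_spearman(x, y, Z = cbind(z), n_boot = 0)$rho), 0.07)
})

test_that("conditional_spearman validates inputs and honours n_boot = 0", {
  set.seed(46)
  x <- rnbinom(60, mu = 10, size = 2)
  y <- rnbinom(60, mu = 10, size = 2)
  m <- rnorm(60)
  expect_error(conditional_spearman(x, y, m, grid = c(min(m) - 1)), "range")
  expect_error(conditional_spearman(x, y, m, bandwidth = 0), "bandwidth")
  cur <- conditional_spearman(x, y, m, n_boot = 0)
  expect_true(all(is.na(cur$lower)))
  expect_null(cur$boot)
  expect_true(all(abs(cur$rho) <= 1))
})

test_that("detect_shift classifies direction and significance from the boot draws", {
  modifier <- seq(-1, 1, length.out = 21)
  grid <- unname(quantile(modifier, c(0.1, 0.5, 0.9)))
  mk_curve <- function(lo, hi, spread) {
    boot <- cbind(rnorm(400, lo, spread), rnorm(400, (lo + hi) / 2, spread),
                  rnorm(400, hi, spread))
    structure(list(grid = grid, rho = c(lo, (lo + hi) / 2, hi),
                   lower = apply(boot, 2, quantile, 0.025),
                   upper = apply(boot, 2, quantile, 0.975),
                   boot = boot, bandwidth = 1, modifier = modifier,
                   conf = 0.95, n_boot = 400),
              class = "conditional_curve")
  }
  set.seed(47)
  up <- detect_shift(mk_curve(-0.5, 0.5, 0.05))
  expect_equal(up$direction, "positive")
  expect_true(up$significant)
  expect_true(up$sign_change)
  flat <- detect_shift(mk_curve(0.3, 0.3, 0.1))
  expect_false(flat$significant)
  weaken <- detect_shift(mk_curve(0.6, 0.1, 0.05))
  expect_equal(weaken$direction, "negative")
  expect_true(weaken$significant)
  expect_false(weaken$sign_change)
})

test_that("count_shifts tabulates significant records only", {
  rec <- data.frame(
    phylum_a = "A", phylum_b = "B",
    pairing = c(rep("Bact-Bact", 4), "Fung-Fung"),
    modifier = c(rep("CN", 4), "pH"),
    rho_low = 0, rho_high = 0.5,
    direction = c(rep("positive", 4), "negative"),
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    sign_change = FALSE, diff_lo = 0.1, diff_hi = 0.9)
  tab <- count_shifts(rec)
  expect_equal(tab["Bact-Bact", "CN.positive"], 3L)
  expect_equal(tab["Fung-Fung", "pH.negative"], 1L)
  expect_equal(sum(tab), 4L)
  empty <- count_shifts(rec[0, ])
  expect_true(all(empty == 0))
})

test_that("phylum aggregation sums order counts within phylum", {
  sim <- simulate_environment(12, seed = 48, covariates = c("elevation", "pH"))
  truth <- make_ground_truth(sim$env, n_taxa = 9, d = 0, seed = 48)
  comm <- simulate_community(sim$env, truth, seed = 49)
  agg <- aggregate_phyla(comm)
  expect_equal(sum(agg$counts), sum(comm$counts))
  ph <- comm$taxa$phylum[1]
  expect_equal(unname(agg$counts[, ph]),
               unname(rowSums(comm$counts[, comm$taxa$phylum == ph, drop = FALSE])))
  expect_setequal(unname(agg$kingdom), c("Bacteria", "Fungi"))
})

test_that("shift_analysis adjusts each modifier for the other two", {
  set.seed(50)
  sim <- simulate_environment(60, seed = 50,
                              covariates = c("elevation", "pH", "CN"))
  truth <- make_ground_truth(sim$env, n_taxa = 6, d = 0, seed = 50,
                             beta_sparsity = 0, lambda_sd = 0)
  comm <- simulate_community(sim$env, truth, seed = 51)
  out <- shift_analysis(comm, sim$raw, n_boot = 50, seed = 52)
  expect_true(all(c("pairing", "modifier", "significant") %in% names(out)))
  expect_setequal(unique(out$modifier), c("elevation", "CN", "pH"))
  expect_true(all(out$direction == ifelse(out$rho_high >= out$rho_low,
                                          "positive", "negative")))
})
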
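test_that("read_community aggregates OTUs to the requested rank by summing", {
  p <- write_counts_fixture(
    withr::local_tempfile(fileext = ".tsv"),
    c("k__Bacteria;p__P1;c__C1;o__O1",
      "k__Bacteria;p__P1;c__C1;o__O1",
      "k__Bacteria;p__P1;c__C2;o__O2"),
    rbind(c(3, 4), c(1, 0), c(2, 2)), c("S1", "S2"))
  ct <- read_community(p, rank = "order")
  expect_equal(ncol(ct$counts), 2)
  expect_equal(unname(ct$counts[, "O1"]), c(4, 4))
  # aggregation conserves total count
  expect_equal(sum(ct$counts), 3 + 4 + 1 + 0 + 2 + 2)
})

test_that("taxa unclassified at the target rank fall back with resolution flags", {
  p <- write_counts_fixture(
    withr::local_tempfile(fileext = ".tsv"),
    c("k__Bacteria;p__P1;c__C1;o__O1",
      "k__Bacteria;p__P1;c__C1",          # class-level only -> **
      "k__Bacteria;p__P2"),               # phylum-level only -> *
    rbind(c(1, 1), c(2, 0), c(0, 3)), c("S1", "S2"))
  ct <- read_community(p, rank = "order")
  expect_setequal(ct$taxa$display_name, c("O1", "C1**", "P2*"))
  expect_equal(ct$taxa$resolution_flag[ct$taxa$display_name == "C1**"], "class")
  expect_equal(ct$taxa$resolution_flag[ct$taxa$display_name == "P2*"], "phylum")
})

test_that("read_community rejects malformed input", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("", bad)
  expect_error(read_community(bad))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxonomy\tS1\tS1", "k__B;p__P;c__C;o__O\t1\t2"), p)
  expect_error(read_community(p), "duplicate site")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxonomy\tS1", "k__B;p__P;c__C;o__O\t-3"), p2)
  expect_error(read_community(p2), "non-negative")
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxonomy\tS1", "k__B;p__P;c__C;o__O\t1.5"), p3)
  expect_error(read_community(p3), "integer")
})

test_that("write_community / read_community round-trips counts and lineages", {
  sim <- simulate_environment(8, seed = 3, covariates = c("elevation", "pH"))
  truth <- make_ground_truth(sim$env, n_taxa = 6, d = 0, seed = 3)
  comm <- simulate_community(sim$env, truth, seed = 4)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_community(comm, p)
  back <- read_community(p, rank = "order")
  expect_equal(sum(back$counts), sum(comm$counts))
  expect_setequal(back$taxa$order, comm$taxa$order)
})

test_that("filter_prevalence keeps taxa in >= min_sites sites, boundary inclusive", {
  counts <- cbind(a = c(1, 1, 1, 1, 0, 0), b = c(1, 1, 1, 1, 1, 0),
                  c = c(5, 0, 0, 0, 0, 0))
  taxa <- data.frame(display_name = c("a", "b", "c"), kingdom = "Bacteria",
                     phylum = "P", class = "C", order = c("a", "b", "c"),
                     resolution_flag = "order", lineage = c("a", "b", "c"))
  ct <- community_table(counts, taxa, site_ids = paste0("S", 1:6))
  f5 <- filter_prevalence(ct, 5)
  expect_equal(colnames(f5$counts), "b")        # 4 sites removed, 5 kept
  expect_equal(f5$site_ids, ct$site_ids)        # site set unchanged
  # idempotence
  expect_identical(filter_prevalence(f5, 5)$counts, f5$counts)
  # min_sites = 1 with no all-zero taxa is the identity
  expect_identical(filter_prevalence(ct, 1)$counts, ct$counts)
  expect_error(filter_prevalence(ct, 7), "threshold")
})

test_that("derive_covariates computes C:N, E2/E3 and SUVA254", {
  raw <- data.frame(site = c("A", "B"), TC = c(10, 20), TN = c(5, 4),
                    DOC = c(2, 4), A250 = c(2, 3), A254 = c(1, 2),
                    A365 = c(0.5, 1))
  out <- derive_covariates(raw)
  expect_equal(out$CN, c(2, 5))
  expect_equal(out$E2E3, c(4, 3))
  expect_equal(out$SUVA254, c(0.5, 0.5))
  raw$DOC[2] <- 0
  expect_error(derive_covariates(raw), "DOC at site B")
})

test_that("standardize_env centers and scales with sample SD and round-trips", {
  raw <- data.frame(elevation = c(2, 4, 6), pH = c(7, 8, 9))
  env <- standardize_env(raw)
  expect_equal(unname(env$values[, "elevation"]), c(-1, 0, 1))
  expect_true(all(abs(colMeans(env$values)) < 1e-10))
  expect_true(all(abs(apply(env$values, 2, sd) - 1) < 1e-10))
  # idempotence on an already standardized column
  env2 <- standardize_env(as.data.frame(env$values))
  expect_lt(max(abs(env2$values - env$values)), 1e-10)
  # round-trip
  expect_lt(max(abs(unstandardize_env(env) -
                      as.matrix(raw[, c("elevation", "pH")]))), 1e-10)
  expect_error(standardize_env(data.frame(elevation = c(1, 1, 1))),
               "zero-variance")
  expect_error(standardize_env(data.frame(elevation = c(1, NA, 3))),
               "missing")
})

test_that("every covariate maps to exactly one group", {
  g <- default_covariate_groups()
  expect_true(all(table(names(g)) == 1))
  expect_setequal(unique(unname(g)),
                  c("elevation", "pH", "C&N", "organic matter", "P",
                    "geographic distance"))
})
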
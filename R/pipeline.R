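# End-to-end orchestration: read -> filter -> standardize -> fit ->
# classify/summarize -> variance partition -> residual network -> niche
# regression -> conditional shifts, with per-stage derived seeds, structured
# logging and a single text report.

#' Derive a stage seed from the master seed
#'
#' Deterministic fan-out so stages can be rerun independently yet
#' reproducibly; result is always below 2^31.
#'
#' @param seed master integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h * 2654435.0) %% 214748329)
}

default_config <- function() {
  list(counts = NULL, metadata = NULL, out_dir = "lvmnet_run",
       rank = "order", min_sites = 5, d = 2,
       covariates = c("elevation", "pH", "TC", "TN", "CN", "TP", "DOC",
                      "E2E3", "SUVA254", "latitude", "longitude"),
       n_chains = 2, n_draws = 500, n_warmup = 500, prior_sd = 10,
       credible_level = 0.95, modifiers = c("elevation", "CN", "pH"),
       n_boot = 500, seed = 1)
}

#' Load a run configuration from JSON
#' @param path JSON file with any subset of the config fields.
#' @return full config list (defaults filled in).
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg
}

log_stage <- function(log, stage, t0, ...) {
  entry <- list(stage = stage, seconds = round(as.numeric(Sys.time()) - t0, 2),
                ...)
  c(log, list(entry))
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a counts + metadata input pair (paths in the
#' config, or in-memory objects passed directly) and writes tidy TSV outputs
#' plus a text report to `config$out_dir`.
#'
#' @param config list as produced by [read_config()]; unset fields take
#'   defaults.  `counts`/`metadata` may be file paths or a `community_table`
#'   and data.frame.
#' @return invisibly, a list with every stage output.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- default_config()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  t0 <- as.numeric(Sys.time())

  stage <- "read"
  comm <- tryCatch({
    if (inherits(cfg$counts, "community_table")) cfg$counts
    else read_community(cfg$counts, rank = cfg$rank)
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  meta <- tryCatch({
    if (is.data.frame(cfg$metadata)) normalize_meta_names(cfg$metadata)
    else normalize_meta_names(read_delim_auto(cfg$metadata))
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  log <- log_stage(log, stage, t0, sites = nrow(comm$counts),
                   taxa = ncol(comm$counts))

  stage <- "filter"; t0 <- as.numeric(Sys.time())
  comm <- filter_prevalence(comm, cfg$min_sites)
  write_community(comm, file.path(cfg$out_dir, "counts_filtered.tsv"))
  log <- log_stage(log, stage, t0, taxa_kept = ncol(comm$counts))

  stage <- "standardize"; t0 <- as.numeric(Sys.time())
  if (all(c("TC", "TN", "DOC", "A250", "A254", "A365") %in% names(meta)) &&
      !all(c("CN", "E2E3", "SUVA254") %in% names(meta)))
    meta <- derive_covariates(meta)
  env <- tryCatch(standardize_env(meta, covariates = intersect(cfg$covariates,
                                                               names(meta))),
                  error = function(e) stop("stage 'standardize' failed: ",
                                           conditionMessage(e), call. = FALSE))
  miss <- setdiff(cfg$covariates, colnames(env$values))
  if (length(miss))
    stop("stage 'standardize' failed: missing covariate column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  log <- log_stage(log, stage, t0, covariates = ncol(env$values))

  stage <- "fit"; t0 <- as.numeric(Sys.time())
  fit <- fit_gllvm(comm, env, d = cfg$d, n_chains = cfg$n_chains,
                   n_draws = cfg$n_draws, n_warmup = cfg$n_warmup,
                   prior_sd = cfg$prior_sd,
                   seed = derive_seed(cfg$seed, "fit"))
  write_fit(fit, file.path(cfg$out_dir, "fit"))
  log <- log_stage(log, stage, t0, converged = fit$converged,
                   max_rhat = round(max(fit$diagnostics$rhat, na.rm = TRUE), 3))

  stage <- "summarize"; t0 <- as.numeric(Sys.time())
  classified <- classify_coefficients(fit, prob = cfg$credible_level)
  write.table(classified, file.path(cfg$out_dir, "coefficients.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- summarize_significant(classified, by = "covariate")
  write.table(summ, file.path(cfg$out_dir, "coefficient_summaries.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  responders <- count_responders(classified)
  write.table(responders, file.path(cfg$out_dir, "responder_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log <- log_stage(log, stage, t0, n_significant = sum(classified$direction != "ns"))

  stage <- "varpart"; t0 <- as.numeric(Sys.time())
  vp <- variance_partition(fit)
  vp_tidy <- data.frame(taxon = rep(rownames(vp$proportions),
                                    ncol(vp$proportions)),
                        group = rep(colnames(vp$proportions),
                                    each = nrow(vp$proportions)),
                        proportion = as.vector(vp$proportions))
  write.table(vp_tidy, file.path(cfg$out_dir, "variance_partition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  vps <- varpart_summaries(vp)
  log <- log_stage(log, stage, t0)

  stage <- "network"; t0 <- as.numeric(Sys.time())
  net <- build_network(fit, level = cfg$credible_level)
  write_network(net, file.path(cfg$out_dir, "network_edges.tsv"))
  nr <- do.call(rbind, lapply(fit$covariate_names, function(cv)
    niche_regression(fit, net, cv, prob = cfg$credible_level)))
  write.table(nr, file.path(cfg$out_dir, "niche_regression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log <- log_stage(log, stage, t0, n_edges = sum(net$significant) / 2)

  stage <- "shifts"; t0 <- as.numeric(Sys.time())
  mods <- intersect(cfg$modifiers, names(meta))
  shifts <- if (length(mods))
    shift_analysis(comm, meta, modifiers = mods, n_boot = cfg$n_boot,
                   seed = derive_seed(cfg$seed, "shifts")) else NULL
  if (!is.null(shifts)) {
    write.table(shifts, file.path(cfg$out_dir, "shift_records.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log <- log_stage(log, stage, t0,
                   n_significant = if (is.null(shifts)) 0 else sum(shifts$significant))

  outputs <- list(community = comm, env = env, fit = fit,
                  classified = classified, summaries = summ,
                  responders = responders, varpart = vp,
                  varpart_summaries = vps, network = net,
                  niche_regression = nr, shifts = shifts,
                  config = cfg, log = log)
  report <- make_report(outputs)
  writeLines(report, file.path(cfg$out_dir, "report.txt"))
  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outputs)
}

fmt_num <- function(x, d = 3) formatC(x, digits = d, format = "f")

#' Render a human-readable report from pipeline outputs
#'
#' @param outputs list from [run_pipeline()] (any subset of its stage
#'   outputs).
#' @return character vector of report lines.
#' @export
make_report <- function(outputs) {
  ln <- c("lvmnet analysis report", strrep("=", 30), "")
  if (!is.null(outputs$config)) {
    cfg <- outputs$config
    ln <- c(ln, "Settings:", sprintf("  d = %d latent variables; %d chains x %d draws (warmup %d)",
                                     cfg$d, cfg$n_chains, cfg$n_draws, cfg$n_warmup),
            sprintf("  credible level %.2f; prevalence filter >= %d sites; seed %d",
                    cfg$credible_level, cfg$min_sites, cfg$seed),
            sprintf("  quartile convention: R type %d", QUANTILE_TYPE), "")
  }
  if (!is.null(outputs$responders)) {
    ln <- c(ln, "Responder counts (significant orders per covariate):")
    r <- outputs$responders
    r <- r[r$n > 0, , drop = FALSE]
    if (nrow(r) == 0) ln <- c(ln, "  none detected")
    else ln <- c(ln, sprintf("  %-12s %-9s %-9s %d", r$covariate, r$direction,
                             r$kingdom, r$n))
    ln <- c(ln, "")
  }
  if (!is.null(outputs$summaries)) {
    s <- outputs$summaries
    ln <- c(ln, "Coefficient summaries (significant only):")
    if (nrow(s) == 0) ln <- c(ln, "  none detected")
    else ln <- c(ln, sprintf("  %-12s %-9s n=%-3d median %+0.2f IQR [%+0.2f, %+0.2f]",
                             s$group, s$direction, s$n_orders, s$median,
                             s$q25, s$q75))
    ln <- c(ln, "")
  }
  if (!is.null(outputs$varpart_summaries)) {
    ln <- c(ln, "Variance partitioning:")
    for (v in outputs$varpart_summaries) {
      ln <- c(ln, sprintf("  %s (n=%d): mean explained %.1f%% +/- %.1f%%; >50%%: %d (%.1f%%); skewness %s",
                          v$kingdom, v$n_taxa, 100 * v$mean_explained,
                          100 * v$sd_explained, v$n_above, v$pct_above,
                          ifelse(is.na(v$skewness), "NA", fmt_num(v$skewness, 2))))
    }
    ln <- c(ln, "")
  }
  if (!is.null(outputs$network)) {
    ln <- c(ln, sprintf("Residual network: %d significant edges among %d taxa",
                        sum(outputs$network$significant) / 2,
                        ncol(outputs$network$rho)), "")
  }
  if (!is.null(outputs$niche_regression)) {
    nr <- outputs$niche_regression
    nrc <- nr[nr$response == "closeness", , drop = FALSE]
    ln <- c(ln, "Niche regression (closeness ~ HPD width):")
    if (nrow(nrc) == 0) ln <- c(ln, "  none computed")
    else ln <- c(ln, sprintf("  %-12s slope %+0.3f  r^2 %.3f  (n=%d)",
                             nrc$covariate, nrc$slope, nrc$r_squared, nrc$n_taxa))
    ln <- c(ln, "")
  }
  if (!is.null(outputs$shifts)) {
    ln <- c(ln, "Interaction shifts (significant counts):")
    tab <- count_shifts(outputs$shifts)
    if (sum(tab) == 0) ln <- c(ln, "  none detected")
    else {
      ln <- c(ln, paste0("  ", paste(c(sprintf("%-10s", ""), colnames(tab)),
                                     collapse = "  ")))
      for (r in rownames(tab))
        ln <- c(ln, paste0("  ", paste(c(sprintf("%-10s", r),
                                         sprintf("%*d", nchar(colnames(tab)),
                                                 tab[r, ])), collapse = "  ")))
    }
    ln <- c(ln, "")
  }
  ln
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run-all`, `report`.  `simulate` writes a counts
#' TSV, metadata TSV and ground-truth JSON; `run-all` executes
#' [run_pipeline()] from a JSON config (`--config path`) with optional
#' `--seed` / `--out` overrides.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: lvmnet <simulate|run-all|report> [--key value ...]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  while (length(rest) >= 2 && startsWith(rest[1], "--")) {
    opts[[sub("^--", "", rest[1])]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  getopt <- function(name, default) if (!is.null(opts[[name]])) opts[[name]] else default
  if (cmd == "simulate") {
    seed <- as.integer(getopt("seed", 1))
    out <- getopt("out", "lvmnet_sim")
    n_sites <- as.integer(getopt("sites", 43))
    n_taxa <- as.integer(getopt("taxa", 80))
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    sim <- simulate_environment(n_sites, seed = seed)
    truth <- make_ground_truth(sim$env, n_taxa = n_taxa, seed = seed)
    comm <- simulate_community(sim$env, truth, seed = seed)
    write_community(comm, file.path(out, "counts.tsv"))
    write.table(sim$raw, file.path(out, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(alpha = truth$alpha, beta0 = truth$beta0, beta = truth$beta,
           lambda = truth$lambda, phi = truth$phi),
      file.path(out, "ground_truth.json"), digits = NA)
    cat("wrote", out, "\n")
    return(invisible(0L))
  }
  if (cmd == "run-all") {
    cfg <- if (!is.null(opts$config)) read_config(opts$config) else default_config()
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    if (!is.null(opts$out)) cfg$out_dir <- opts$out
    if (!is.null(opts$counts)) cfg$counts <- opts$counts
    if (!is.null(opts$meta)) cfg$metadata <- opts$meta
    run_pipeline(cfg)
    cat("pipeline complete:", cfg$out_dir, "\n")
    return(invisible(0L))
  }
  if (cmd == "report") {
    path <- file.path(getopt("dir", "lvmnet_run"), "report.txt")
    if (file.exists(path)) { cat(readLines(path), sep = "\n"); return(invisible(0L)) }
    cat("no report at", path, "\n")
    return(invisible(1L))
  }
  cat("unknown subcommand:", cmd, "\n")
  invisible(1L)
}
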
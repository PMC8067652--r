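#' @useDynLib lvmnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile sd var cor cor.test rnorm runif rnbinom
#'   qnbinom pnbinom pnorm qlogis plogis lm coef setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

RANKS <- c("kingdom", "phylum", "class", "order")
RANK_PREFIXES <- c(kingdom = "k__", phylum = "p__", class = "c__", order = "o__")

# canonical metadata covariates, matched case-insensitively
CANONICAL_COVARIATES <- c("elevation", "pH", "TC", "TN", "TP", "DOC",
                          "A250", "A254", "A365", "latitude", "longitude")

#' Default covariate-to-group map
#'
#' Groups covariates the way gradient studies report variance partitioning:
#' elevation, pH, C&N (TC, TN, C:N), organic matter (DOC, E2/E3, SUVA254),
#' P, and geographic distance (latitude + longitude as two standardized
#' covariates).
#'
#' @param covariates character vector of covariate names to map; defaults to
#'   the full derived set.
#' @return named character vector: covariate -> group label.
#' @export
default_covariate_groups <- function(covariates = NULL) {
  full <- c(elevation = "elevation", pH = "pH",
            TC = "C&N", TN = "C&N", CN = "C&N",
            DOC = "organic matter", E2E3 = "organic matter",
            SUVA254 = "organic matter",
            TP = "P",
            latitude = "geographic distance", longitude = "geographic distance")
  if (is.null(covariates)) return(full)
  missing <- setdiff(covariates, names(full))
  out <- full[intersect(names(full), covariates)]
  if (length(missing)) {
    extra <- setNames(missing, missing)  # unknown covariates get own group
    out <- c(out, extra)
  }
  out[covariates]
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.table(path, header = TRUE, sep = sep, check.names = FALSE,
             stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

parse_lineage <- function(lineage) {
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  out <- setNames(rep(NA_character_, length(RANKS)), RANKS)
  prefixed <- grepl("^[kdpco]__", parts)
  if (any(prefixed)) {
    for (p in parts) {
      pre <- substr(p, 1, 3)
      name <- substring(p, 4)
      if (!nzchar(name)) next
      rank <- switch(pre, "k__" = "kingdom", "d__" = "kingdom",
                     "p__" = "phylum", "c__" = "class", "o__" = "order", NA)
      if (!is.na(rank)) out[rank] <- name
    }
  } else {
    n <- min(length(parts), length(RANKS))
    keep <- nzchar(parts[seq_len(n)])
    out[seq_len(n)][keep] <- parts[seq_len(n)][keep]
  }
  # treat placeholders like "unclassified"/"unidentified" as missing
  out[!is.na(out) & grepl("^(unclassified|unidentified|uncultured|norank|NA)$",
                          out, ignore.case = TRUE)] <- NA_character_
  out
}

#' Construct a community table
#'
#' @param counts site x taxon matrix of non-negative integers (site IDs as
#'   rownames, taxon display names as colnames).
#' @param taxa data.frame with one row per taxon: `display_name`, the lineage
#'   ranks (`kingdom`, `phylum`, `class`, `order`) and `resolution_flag`.
#' @param site_ids character vector of site identifiers.
#' @return object of class `community_table`.
#' @export
community_table <- function(counts, taxa, site_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (anyDuplicated(site_ids)) stop("duplicate site ids", call. = FALSE)
  if (anyDuplicated(taxa$display_name)) {
    dup <- duplicated(taxa$display_name) | duplicated(taxa$display_name, fromLast = TRUE)
    taxa$display_name[dup] <- make.unique(taxa$display_name[dup], sep = "#")
  }
  rownames(counts) <- site_ids
  colnames(counts) <- taxa$display_name
  structure(list(counts = counts, taxa = taxa, site_ids = site_ids),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d sites x %d taxa (total count %.0f)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Read a taxon count table and aggregate to a taxonomic rank
#'
#' Expects a delimited file with taxa as rows: a `taxonomy` column holding a
#' semicolon-delimited lineage (`k__;p__;c__;o__` prefixes or bare names) and
#' one count column per site.  Counts are summed within the requested rank.
#' Taxa unclassified at that rank fall back to their deepest classified rank;
#' class-level fallbacks are marked `**` and phylum-level fallbacks `*` in the
#' display name.
#'
#' @param path file path (TSV or CSV, sniffed from the header line).
#' @param rank target rank, one of kingdom/phylum/class/order.
#' @return a [community_table()].
#' @export
read_community <- function(path, rank = "order") {
  rank <- match.arg(rank, RANKS)
  df <- read_delim_auto(path)
  tax_col <- which(tolower(names(df)) %in% c("taxonomy", "lineage", "taxon"))
  if (length(tax_col) != 1L)
    stop("expected exactly one taxonomy column (named 'taxonomy')", call. = FALSE)
  site_cols <- setdiff(seq_along(df), tax_col)
  if (length(site_cols) == 0L) stop("no site columns found", call. = FALSE)
  if (anyDuplicated(names(df)[site_cols]))
    stop("duplicate site columns: ",
         paste(unique(names(df)[site_cols][duplicated(names(df)[site_cols])]),
               collapse = ", "), call. = FALSE)
  cnt <- as.matrix(df[, site_cols, drop = FALSE])
  if (!is.numeric(cnt) || any(is.na(cnt)))
    stop("non-numeric or missing counts", call. = FALSE)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers", call. = FALSE)

  lineages <- lapply(df[[tax_col]], parse_lineage)
  rank_i <- match(rank, RANKS)
  agg_info <- lapply(lineages, function(ln) {
    depth <- max(c(0L, which(!is.na(ln[seq_len(rank_i)]))))
    if (depth == 0L) {
      list(key = "Unclassified", name = "Unclassified", flag = "kingdom",
           lineage = ln)
    } else {
      trunc <- ln
      if (depth < length(RANKS)) trunc[(depth + 1):length(RANKS)] <- NA
      key <- paste(trunc[seq_len(depth)], collapse = ";")
      deepest <- RANKS[depth]
      suffix <- if (deepest == rank) "" else if (deepest == "class") "**"
                else if (deepest == "phylum") "*" else "*"
      list(key = key, name = paste0(ln[depth], suffix), flag = deepest,
           lineage = trunc)
    }
  })
  keys <- vapply(agg_info, `[[`, "", "key")
  ukeys <- unique(keys)
  agg <- matrix(0L, nrow = length(ukeys), ncol = length(site_cols))
  for (r in seq_along(keys)) {
    i <- match(keys[r], ukeys)
    agg[i, ] <- agg[i, ] + as.integer(cnt[r, ])
  }
  first <- match(ukeys, keys)
  taxa <- data.frame(
    display_name = vapply(agg_info[first], `[[`, "", "name"),
    kingdom = vapply(agg_info[first], function(a) a$lineage[["kingdom"]], ""),
    phylum  = vapply(agg_info[first], function(a) a$lineage[["phylum"]], ""),
    class   = vapply(agg_info[first], function(a) a$lineage[["class"]], ""),
    order   = vapply(agg_info[first], function(a) a$lineage[["order"]], ""),
    resolution_flag = vapply(agg_info[first], `[[`, "", "flag"),
    lineage = ukeys,
    stringsAsFactors = FALSE)
  community_table(t(agg), taxa, site_ids = names(df)[site_cols])
}

#' Remove rare taxa by site prevalence
#'
#' Retains taxa with a nonzero count in at least `min_sites` sites (boundary
#' inclusive); the unreliable low-occurrence taxa are dropped before model
#' fitting.
#'
#' @param table a [community_table()].
#' @param min_sites minimum number of occupied sites, default 5.
#' @return filtered `community_table`.
#' @export
filter_prevalence <- function(table, min_sites = 5) {
  stopifnot(inherits(table, "community_table"), min_sites >= 1)
  prev <- colSums(table$counts > 0)
  keep <- prev >= min_sites
  if (!any(keep))
    stop("all taxa removed at min_sites = ", min_sites,
         "; reduce the prevalence threshold", call. = FALSE)
  community_table(table$counts[, keep, drop = FALSE],
                  table$taxa[keep, , drop = FALSE],
                  site_ids = table$site_ids)
}

#' Derive composite soil covariates
#'
#' Appends C:N = TC/TN, E2/E3 = A250/A365 (dissolved-organic-matter molecular
#' size proxy) and SUVA254 = A254/DOC (aromaticity proxy; raw ratio by
#' default, `suva_scale` multiplies it if units demand).
#'
#' @param raw data.frame of per-site metadata containing TC, TN, DOC, A250,
#'   A254, A365 (case-insensitive names).
#' @param suva_scale multiplier applied to A254/DOC, default 1.
#' @return `raw` with columns CN, E2E3, SUVA254 appended.
#' @export
derive_covariates <- function(raw, suva_scale = 1) {
  raw <- normalize_meta_names(raw)
  need <- c("TC", "TN", "DOC", "A250", "A254", "A365")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing metadata columns: ", paste(miss, collapse = ", "), call. = FALSE)
  sites <- site_labels(raw)
  check_pos <- function(col) {
    bad <- which(!is.finite(raw[[col]]) | raw[[col]] <= 0)
    if (length(bad))
      stop(sprintf("non-positive %s at site %s: cannot derive ratio",
                   col, sites[bad[1]]), call. = FALSE)
  }
  check_pos("TN"); check_pos("A365"); check_pos("DOC")
  raw$CN <- raw$TC / raw$TN
  raw$E2E3 <- raw$A250 / raw$A365
  raw$SUVA254 <- suva_scale * raw$A254 / raw$DOC
  raw
}

site_labels <- function(df) {
  id <- which(tolower(names(df)) %in% c("site", "site_id", "sample", "sample_id"))
  if (length(id) >= 1) as.character(df[[id[1]]]) else as.character(seq_len(nrow(df)))
}

normalize_meta_names <- function(df) {
  canon <- c(CANONICAL_COVARIATES, "CN", "E2E3", "SUVA254")
  idx <- match(tolower(names(df)), tolower(canon))
  names(df)[!is.na(idx)] <- canon[idx[!is.na(idx)]]
  df
}

#' Standardize environmental covariates
#'
#' Centers and scales each covariate to zero mean and unit sample SD
#' (n-1 denominator); the means and SDs are kept so values can be mapped back
#' to the measurement scale.
#'
#' @param env data.frame or matrix of raw per-site covariates.
#' @param covariates names of columns to use (default: all numeric columns).
#' @param groups named covariate->group map; defaults to
#'   [default_covariate_groups()].
#' @param impute if TRUE, missing cells are mean-imputed (logged via a
#'   message); default is a hard error.
#' @return object of class `env_matrix` with fields `values`, `means`, `sds`,
#'   `groups`.
#' @export
standardize_env <- function(env, covariates = NULL, groups = NULL,
                            impute = FALSE) {
  env <- normalize_meta_names(as.data.frame(env))
  if (is.null(covariates))
    covariates <- names(env)[vapply(env, is.numeric, TRUE)]
  miss <- setdiff(covariates, names(env))
  if (length(miss))
    stop("covariate not found in metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(env[, covariates, drop = FALSE])
  if (nrow(x) < 2) stop("need at least 2 sites to standardize", call. = FALSE)
  if (any(is.na(x))) {
    if (!impute) stop("missing values in covariates; set impute = TRUE to mean-impute",
                      call. = FALSE)
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) {
        x[nas, j] <- mean(x[, j], na.rm = TRUE)
        message("mean-imputed ", sum(nas), " cells in ", covariates[j])
      }
    }
  }
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("zero-variance covariate: ",
         paste(covariates[sds == 0], collapse = ", "), call. = FALSE)
  vals <- sweep(sweep(x, 2, mu), 2, sds, "/")
  rownames(vals) <- site_labels(env)
  if (is.null(groups)) groups <- default_covariate_groups(covariates)
  miss_g <- setdiff(covariates, names(groups))
  if (length(miss_g))
    stop("group map missing covariates: ", paste(miss_g, collapse = ", "),
         call. = FALSE)
  structure(list(values = vals, covariate_names = covariates,
                 means = mu, sds = sds, groups = groups[covariates]),
            class = "env_matrix")
}

#' Back-transform a standardized environment matrix
#'
#' @param env an `env_matrix`.
#' @return matrix on the original measurement scale.
#' @export
unstandardize_env <- function(env) {
  stopifnot(inherits(env, "env_matrix"))
  sweep(sweep(env$values, 2, env$sds, "*"), 2, env$means, "+")
}

#' @export
print.env_matrix <- function(x, ...) {
  cat(sprintf("env_matrix: %d sites x %d covariates (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$groups), collapse = ", ")))
  invisible(x)
}

#' Write a community table to TSV (taxa as rows, taxonomy first column)
#' @param table a `community_table`.
#' @param path output path.
#' @export
write_community <- function(table, path) {
  stopifnot(inherits(table, "community_table"))
  ln <- apply(table$taxa[, RANKS], 1, function(r) {
    r <- r[!is.na(r)]
    paste0(RANK_PREFIXES[names(r)], r, collapse = ";")
  })
  out <- data.frame(taxonomy = ln, t(table$counts), check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
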
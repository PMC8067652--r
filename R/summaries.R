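# Coefficient summaries (median/IQR of significant effects, responder counts)
# and the raw soil-variable Pearson correlation screen.

# Quartiles use the (n+1)p linear-interpolation convention (R type 6), which
# for n = 3 returns the extremes; recorded in the output attributes.
QUANTILE_TYPE <- 6

#' Summarize significant coefficients by group and direction
#'
#' Medians and interquartile ranges of the posterior-median coefficients of
#' significant entries only, split by sign and a grouping key.
#'
#' @param classified output of [classify_coefficients()].
#' @param by grouping column: "covariate" (default) or "phylum".
#' @return data.frame with group, direction, n_orders, median, q25, q75;
#'   attribute `quantile_type` records the quartile convention.
#' @export
summarize_significant <- function(classified, by = c("covariate", "phylum")) {
  by <- match.arg(by)
  sig <- classified[classified$direction != "ns", , drop = FALSE]
  if (nrow(sig) == 0) {
    out <- data.frame(group = character(), direction = character(),
                      n_orders = integer(), median = numeric(),
                      q25 = numeric(), q75 = numeric())
    attr(out, "quantile_type") <- QUANTILE_TYPE
    return(out)
  }
  keys <- split(seq_len(nrow(sig)),
                list(group = sig[[by]], direction = sig$direction),
                drop = TRUE)
  out <- do.call(rbind, lapply(names(keys), function(nm) {
    ix <- keys[[nm]]
    v <- sig$estimate[ix]
    q <- quantile(v, c(0.25, 0.75), type = QUANTILE_TYPE, names = FALSE)
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(group = paste(head(parts, -1), collapse = "."),
               direction = parts[length(parts)],
               n_orders = length(ix), median = median(v),
               q25 = q[1], q75 = q[2], stringsAsFactors = FALSE)
  }))
  out <- out[order(out$group, out$direction), ]
  rownames(out) <- NULL
  attr(out, "quantile_type") <- QUANTILE_TYPE
  out
}

#' Count significant responders per covariate, direction and kingdom
#'
#' @param classified output of [classify_coefficients()] (must carry a
#'   `kingdom` column).
#' @return data.frame: covariate, direction, kingdom, n.
#' @export
count_responders <- function(classified) {
  sig <- classified[classified$direction != "ns", , drop = FALSE]
  grid <- expand.grid(covariate = unique(classified$covariate),
                      direction = c("positive", "negative"),
                      kingdom = unique(classified$kingdom),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$n <- mapply(function(cv, dr, kg)
    sum(sig$covariate == cv & sig$direction == dr & sig$kingdom == kg),
    grid$covariate, grid$direction, grid$kingdom)
  grid
}

#' Pearson correlation screen of soil variables against a reference
#'
#' @param raw per-site metadata (numeric columns are screened).
#' @param reference covariate name to correlate against, default "TC".
#' @return data.frame: covariate, r, p (two-sided); constant columns give NA.
#' @export
soil_correlations <- function(raw, reference = "TC") {
  raw <- normalize_meta_names(as.data.frame(raw))
  if (!reference %in% names(raw))
    stop("reference covariate not found: ", reference, call. = FALSE)
  num <- names(raw)[vapply(raw, is.numeric, TRUE)]
  if (nrow(raw) < 3) stop("need at least 3 sites", call. = FALSE)
  x <- raw[[reference]]
  others <- setdiff(num, reference)
  out <- do.call(rbind, lapply(others, function(v) {
    y <- raw[[v]]
    if (sd(y) == 0 || sd(x) == 0)
      return(data.frame(covariate = v, r = NA_real_, p = NA_real_))
    ct <- cor.test(x, y, method = "pearson")
    data.frame(covariate = v, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
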
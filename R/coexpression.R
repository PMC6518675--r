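#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson correlation computed from explicit sums, with the
#' classical two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom. `|r| = 1` returns p = 0.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, neither constant.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  if (n < 3L) stopf("need n >= 3 observations")
  if (anyNA(x) || anyNA(y)) stopf("missing values are not allowed")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) stopf("correlation undefined for a constant vector")
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Thresholded lncRNA-mRNA correlation pairs
#'
#' Computes Pearson correlations on `log2(FPKM + 1)` between every lncRNA
#' feature and every mRNA feature across the shared samples, and keeps
#' pairs passing both strict thresholds: `r > r_min` (signed by default;
#' the published convention) and `p < p_max` (raw t-based p-values; BH
#' adjustment available by flag). Constant features have undefined
#' correlations and are dropped with a warning.
#'
#' @param lnc_expr,gene_expr [expression_matrix()] objects over the same
#'   samples in the same order.
#' @param r_min correlation threshold, strict (default 0.80).
#' @param p_max p-value threshold, strict (default 0.05).
#' @param use_abs if TRUE, threshold `|r|` instead of signed `r`.
#' @param adjust `"none"` (default) or `"BH"` across all tested pairs.
#' @return data frame `lncrna_id`, `gene_id`, `r`, `p_value`, `n`, sorted
#'   by descending `r`.
#' @export
correlated_pairs <- function(lnc_expr, gene_expr, r_min = 0.80, p_max = 0.05,
                             use_abs = FALSE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!identical(colnames(lnc_expr$values), colnames(gene_expr$values)))
    stopf("lncRNA and mRNA matrices must share identically ordered samples")
  n <- ncol(lnc_expr$values)
  if (n < 3L) stopf("need >= 3 shared samples")
  lx <- t(log2(lnc_expr$values + 1))
  gx <- t(log2(gene_expr$values + 1))
  const_l <- apply(lx, 2L, stats::sd) == 0
  const_g <- apply(gx, 2L, stats::sd) == 0
  if (any(const_l) || any(const_g))
    warnf("dropping %d constant feature(s) with undefined correlations",
          sum(const_l) + sum(const_g))
  lx <- lx[, !const_l, drop = FALSE]
  gx <- gx[, !const_g, drop = FALSE]
  if (ncol(lx) == 0L || ncol(gx) == 0L) {
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      r = numeric(0), p_value = numeric(0), n = integer(0),
                      stringsAsFactors = FALSE))
  }
  r <- stats::cor(lx, gx)
  r <- pmax(pmin(r, 1), -1)
  p <- matrix(0, nrow(r), ncol(r), dimnames = dimnames(r))
  nz <- abs(r) < 1
  t_stat <- r[nz] * sqrt((n - 2) / (1 - r[nz]^2))
  p[nz] <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  if (adjust == "BH") p[] <- stats::p.adjust(p, method = "BH")
  crit <- if (use_abs) abs(r) else r
  keep <- which(crit > r_min & p < p_max, arr.ind = TRUE)
  res <- data.frame(lncrna_id = rownames(r)[keep[, 1L]],
                    gene_id = colnames(r)[keep[, 2L]],
                    r = r[keep], p_value = p[keep],
                    n = rep.int(n, nrow(keep)), stringsAsFactors = FALSE)
  res <- res[order(-res$r, res$lncrna_id, res$gene_id), ]
  rownames(res) <- NULL
  res
}

#' Join correlated pairs with cis proximity and rank
#'
#' Intersects the correlated pairs with the cis-proximal pairs (from
#' [cis_candidates()]), annotates the signed distance, and returns the top
#' pairs ranked by descending `r`, ties broken by smaller absolute
#' distance, then lexicographic ids. Pairs correlated but outside the cis
#' window remain trans candidates and are excluded here.
#'
#' @param pairs data frame from [correlated_pairs()].
#' @param cis data frame from [cis_candidates()].
#' @param top_n number of pairs to return (default 10; `Inf` for all).
#' @return data frame `lncrna_id`, `gene_id`, `r`, `p_value`, `n`,
#'   `signed_distance`, `is_cis` (all `TRUE`).
#' @export
join_cis <- function(pairs, cis, top_n = 10) {
  res <- merge(pairs, cis[, c("lncrna_id", "gene_id", "signed_distance")],
               by = c("lncrna_id", "gene_id"))
  res$is_cis <- rep(TRUE, nrow(res))
  res <- res[order(-res$r, abs(res$signed_distance), res$lncrna_id,
                   res$gene_id), ]
  if (is.finite(top_n)) res <- utils::head(res, top_n)
  rownames(res) <- NULL
  res
}
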
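#' Expression matrices with sample metadata
#'
#' Container for FPKM-like, non-negative expression values: a numeric
#' matrix (features x samples) plus per-sample metadata giving tissue,
#' treatment (`"control"` or `"high_intake"`) and replicate. Column order
#' of the matrix must match the row order of the metadata.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param sample_meta data frame with columns `sample_id`, `tissue`,
#'   `treatment`, `replicate`.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("values must be a numeric matrix")
  if (is.null(colnames(values)) ||
      (nrow(values) > 0L && is.null(rownames(values))))
    stopf("values must have feature rownames and sample colnames")
  if (anyNA(values)) stopf("expression values must not contain missing values")
  if (any(values < 0)) stopf("expression values must be non-negative")
  required <- c("sample_id", "tissue", "treatment", "replicate")
  if (!all(required %in% names(sample_meta)))
    stopf("sample_meta must have columns %s", paste(required, collapse = ", "))
  sample_meta <- as.data.frame(sample_meta)[, required]
  sample_meta$sample_id <- as.character(sample_meta$sample_id)
  sample_meta$tissue <- as.character(sample_meta$tissue)
  sample_meta$treatment <- as.character(sample_meta$treatment)
  if (!identical(colnames(values), sample_meta$sample_id))
    stopf("colnames(values) must equal sample_meta$sample_id in order")
  if (!all(sample_meta$treatment %in% c("control", "high_intake")))
    stopf("treatment must be 'control' or 'high_intake'")
  structure(list(values = values, sample_meta = sample_meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples (%d tissues, %d treatments)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_meta$tissue)),
              length(unique(x$sample_meta$treatment))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

## subset samples, preserving class
subset_samples <- function(m, keep) {
  expression_matrix(m$values[, keep, drop = FALSE], m$sample_meta[keep, ])
}

#' Keep features expressed above a threshold
#'
#' A feature counts as expressed when its summary statistic across samples
#' strictly exceeds `threshold` (FPKM > 0.1 by default). The maximum is the
#' default summary; the mean is available.
#'
#' @param m an [expression_matrix()].
#' @param threshold non-negative FPKM cutoff, strict.
#' @param stat `"max"` (default) or `"mean"`.
#' @return list with `matrix` (the filtered [expression_matrix()]) and
#'   `n_expressed` (number of surviving features).
#' @export
filter_expressed <- function(m, threshold = 0.1, stat = c("max", "mean")) {
  stat <- match.arg(stat)
  if (threshold < 0) stopf("threshold must be >= 0")
  if (nrow(m$values) == 0L) stopf("expression matrix has no features")
  s <- apply(m$values, 1L, if (stat == "max") max else mean)
  keep <- s > threshold
  list(matrix = expression_matrix(m$values[keep, , drop = FALSE], m$sample_meta),
       n_expressed = sum(keep))
}

#' Treatment-vs-control differential expression for one tissue
#'
#' Per feature: Welch's two-sample t-test on `log2(FPKM + 1)` between the
#' high-intake and control groups of the requested tissue, Benjamini-
#' Hochberg q-values across features, and a pseudo-count fold change
#' `(mean_treated + 1e-6) / (mean_control + 1e-6)` on the FPKM scale.
#' A feature with zero variance in both groups gets p = 1 when the group
#' means are equal and p = 0 otherwise.
#'
#' @param m an [expression_matrix()].
#' @param tissue tissue label to test.
#' @param alpha FDR level; `is_de` is `q_value < alpha`.
#' @return data frame (class `de_result`) with columns `feature_id`,
#'   `mean_control`, `mean_treated`, `fold_change`, `log2fc`, `p_value`,
#'   `q_value`, `is_de`.
#' @export
differential_expression <- function(m, tissue, alpha = 0.05) {
  meta <- m$sample_meta
  if (!tissue %in% meta$tissue) stopf("tissue '%s' not present", tissue)
  ctrl <- meta$tissue == tissue & meta$treatment == "control"
  trt <- meta$tissue == tissue & meta$treatment == "high_intake"
  if (sum(ctrl) < 2L || sum(trt) < 2L)
    stopf("both treatment groups need >= 2 replicates in tissue '%s'", tissue)
  eps <- 1e-6
  vc <- m$values[, ctrl, drop = FALSE]
  vt <- m$values[, trt, drop = FALSE]
  lc <- log2(vc + 1)
  lt <- log2(vt + 1)
  p <- vapply(seq_len(nrow(lc)), function(i) {
    x <- lc[i, ]; y <- lt[i, ]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    stats::t.test(y, x)$p.value
  }, numeric(1))
  mean_control <- rowMeans(vc)
  mean_treated <- rowMeans(vt)
  fold_change <- (mean_treated + eps) / (mean_control + eps)
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(feature_id = rownames(m$values),
                    mean_control = mean_control, mean_treated = mean_treated,
                    fold_change = fold_change, log2fc = log2(fold_change),
                    p_value = p, q_value = q, is_de = q < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "tissue") <- tissue
  attr(res, "alpha") <- alpha
  class(res) <- c("de_result", "data.frame")
  res
}

#' Percentage of differentially expressed features
#'
#' `100 * n_de / n_expressed`, rounded half-up to two decimals, matching
#' conventional printed DE percentages.
#'
#' @param n_de number of DE features (0 <= n_de <= n_expressed).
#' @param n_expressed size of the expressed universe (> 0).
#' @return percentage with two decimals.
#' @examples
#' percent_de(1930, 13815)  # 13.97
#' @export
percent_de <- function(n_de, n_expressed) {
  if (!is_count(n_de) || !is_count(n_expressed))
    stopf("counts must be single integers")
  if (n_expressed <= 0) stopf("n_expressed must be > 0")
  if (n_de < 0 || n_de > n_expressed)
    stopf("n_de must satisfy 0 <= n_de <= n_expressed")
  round_half_up(100 * n_de / n_expressed, 2)
}

#' Venn region counts for DE sets
#'
#' Counts the elements of every non-empty intersection region of k >= 2
#' sets. Regions are disjoint and their counts sum to the union size.
#'
#' @param de_sets named list of >= 2 character vectors.
#' @return named integer vector over the `2^k - 1` regions; names join the
#'   member set names with `"&"`. Attribute `union_size` carries the union
#'   cardinality.
#' @export
de_overlap_counts <- function(de_sets) {
  if (!is.list(de_sets) || length(de_sets) < 2L || is.null(names(de_sets)))
    stopf("de_sets must be a named list of >= 2 sets")
  de_sets <- lapply(de_sets, unique)
  universe <- unique(unlist(de_sets))
  k <- length(de_sets)
  member <- vapply(de_sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, ncol = k, dimnames = list(NULL, names(de_sets)))
  counts <- integer(0)
  for (mask in 1:(2^k - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
    region <- if (length(universe) == 0L) 0L else
      sum(apply(member, 1L, function(row) all(row == inset)))
    counts <- c(counts, region)
    names(counts)[length(counts)] <- paste(names(de_sets)[inset], collapse = "&")
  }
  attr(counts, "union_size") <- length(universe)
  counts
}

#' Sample-level Pearson correlation overview
#'
#' Pearson correlations between samples on `log2(FPKM + 1)` values, plus
#' the mean cross-tissue correlation within each treatment group (all
#' sample pairs from two different tissues sharing a treatment). A
#' constant sample yields undefined correlations; these are set to `NA`,
#' excluded from the means, and flagged with a warning.
#'
#' @param m an [expression_matrix()].
#' @return list with `sample_cor` (samples x samples matrix) and
#'   `within_group` (data frame: `treatment`, `tissue_a`, `tissue_b`,
#'   `mean_r`, `n_pairs`).
#' @export
correlation_overview <- function(m) {
  if (ncol(m$values) < 2L) stopf("need >= 2 samples")
  lv <- log2(m$values + 1)
  const <- apply(lv, 2L, function(x) stats::var(x) == 0)
  if (any(const))
    warnf("constant sample(s) excluded from correlation means: %s",
          paste(colnames(lv)[const], collapse = ", "))
  r <- suppressWarnings(stats::cor(lv))
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  meta <- m$sample_meta
  tissues <- unique(meta$tissue)
  rows <- list()
  for (trt in unique(meta$treatment)) {
    if (length(tissues) < 2L) break
    for (i in seq_len(length(tissues) - 1L)) {
      for (j in (i + 1L):length(tissues)) {
        a <- which(meta$treatment == trt & meta$tissue == tissues[i])
        b <- which(meta$treatment == trt & meta$tissue == tissues[j])
        vals <- r[a, b]
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = trt, tissue_a = tissues[i], tissue_b = tissues[j],
          mean_r = mean(vals, na.rm = TRUE), n_pairs = sum(!is.na(vals)),
          stringsAsFactors = FALSE)
      }
    }
  }
  within_group <- if (length(rows)) do.call(rbind, rows) else
    data.frame(treatment = character(0), tissue_a = character(0),
               tissue_b = character(0), mean_r = numeric(0),
               n_pairs = integer(0))
  list(sample_cor = r, within_group = within_group)
}

#' Principal variance component analysis
#'
#' Attributes expression variance to tissue, treatment, their interaction
#' and residual noise. Features are standardized across samples; principal
#' components of the samples are extracted; on each retained PC's scores a
#' balanced two-way ANOVA gives method-of-moments variance components
#' (expected-mean-square equations for a crossed random-effects design).
#' Components are pooled across the retained PCs with eigenvalue-share
#' weights *before* truncating negatives to zero and normalizing, so that
#' with the full spectrum retained (the default) the decomposition is the
#' exact sums-of-squares decomposition of the standardized data and is
#' well calibrated on null data. Retaining fewer PCs (via `n_pcs` or
#' `min_var_explained < 1`) denoises at the cost of some upward bias in
#' the factor shares.
#'
#' @param m an [expression_matrix()] with a balanced tissue x treatment
#'   design (use `method = "means"` otherwise).
#' @param n_pcs number of leading PCs to retain; overrides
#'   `min_var_explained` when given.
#' @param min_var_explained retain the smallest PC set explaining at least
#'   this fraction of variance (default 1 = full spectrum).
#' @param method `"anova"` (balanced method of moments, default) or
#'   `"means"` (group-mean fallback usable on unbalanced designs).
#' @return object of class `pvca_result`: list with `weighted_proportions`
#'   (named over tissue, treatment, tissue:treatment, residual, summing to
#'   1), `n_pcs_used`, `var_explained`.
#' @export
pvca <- function(m, n_pcs = NULL, min_var_explained = 1,
                 method = c("anova", "means")) {
  method <- match.arg(method)
  meta <- m$sample_meta
  tissue <- factor(meta$tissue)
  treatment <- factor(meta$treatment)
  if (nlevels(tissue) < 2L || nlevels(treatment) < 2L)
    stopf("pvca needs >= 2 tissues and >= 2 treatments")
  cell_n <- table(tissue, treatment)
  balanced <- length(unique(as.vector(cell_n))) == 1L && all(cell_n > 0L)
  if (method == "anova" && !balanced)
    stopf(paste("design is unbalanced; the balanced ANOVA estimator does not",
                "apply -- use method = 'means'"))
  lv <- log2(m$values + 1)
  sds <- apply(lv, 1L, stats::sd)
  z <- lv[sds > 0, , drop = FALSE]
  z <- t(scale(t(z)))
  if (nrow(z) < 2L) stopf("fewer than 2 variable features")
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- ev > max(ev) * 1e-12
  ev <- ev[keep]
  evs <- ev / sum(ev)
  k <- if (!is.null(n_pcs)) min(n_pcs, length(ev)) else
    which(cumsum(evs) >= min_var_explained - 1e-12)[1L]
  w <- evs[seq_len(k)] / sum(evs[seq_len(k)])
  a <- nlevels(tissue)
  b <- nlevels(treatment)
  n <- as.vector(cell_n)[1L]
  comp_one <- function(s) {
    s <- s / stats::sd(s)
    if (method == "anova") {
      fit <- stats::aov(s ~ tissue * treatment)
      ms <- summary(fit)[[1L]][["Mean Sq"]]
      msa <- ms[1L]; msb <- ms[2L]; msab <- ms[3L]; mse <- ms[4L]
      c(tissue = (msa - msab) / (b * n),
        treatment = (msb - msab) / (a * n),
        `tissue:treatment` = (msab - mse) / n,
        residual = mse)
    } else {
      cell_means <- tapply(s, list(tissue, treatment), mean)
      tis_means <- rowMeans(cell_means)
      trt_means <- colMeans(cell_means)
      grand <- mean(cell_means)
      inter <- sweep(sweep(cell_means, 1L, tis_means), 2L, trt_means) + grand
      resid_var <- mean(tapply(s, list(tissue, treatment), stats::var),
                        na.rm = TRUE)
      c(tissue = stats::var(tis_means),
        treatment = stats::var(trt_means),
        `tissue:treatment` = stats::var(as.vector(inter)),
        residual = resid_var)
    }
  }
  raw <- vapply(seq_len(k), function(i) comp_one(pc$x[, i]), numeric(4))
  pooled <- as.vector(raw %*% w)
  names(pooled) <- rownames(raw)
  v <- pmax(pooled, 0)
  props <- v / sum(v)
  structure(list(weighted_proportions = props, n_pcs_used = k,
                 var_explained = sum(evs[seq_len(k)]), method = method),
            class = "pvca_result")
}

#' @export
print.pvca_result <- function(x, ...) {
  cat(sprintf("pvca_result (%s, %d PCs, %.1f%% variance retained)\n",
              x$method, x$n_pcs_used, 100 * x$var_explained))
  p <- x$weighted_proportions
  for (nm in names(p)) cat(sprintf("  %-18s %6.3f\n", nm, p[[nm]]))
  invisible(x)
}
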
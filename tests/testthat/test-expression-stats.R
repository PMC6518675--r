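test_that("expressed-feature filter is strict at the threshold", {
  v <- rbind(all_at = rep(0.1, 4), one_above = c(0.2, 0, 0, 0),
             zero = rep(0, 4))
  m <- make_expr(v, tissues = "liver",
                 treatments = rep(c("control", "high_intake"), each = 2))
  fe <- filter_expressed(m, threshold = 0.1)
  expect_equal(fe$n_expressed, 1L)
  expect_equal(rownames(fe$matrix$values), "one_above")
  expect_error(filter_expressed(
    expression_matrix(m$values[0, , drop = FALSE], m$sample_meta)),
    "features")
})

test_that("differential expression handles identical and degenerate groups", {
  v <- rbind(flat = c(2, 2, 2, 2, 2, 2),
             shifted = c(1, 1, 1, 63, 63, 63),
             const_diff = c(0, 0, 0, 7, 7, 7))
  m <- make_expr(v, tissues = "liver",
                 treatments = rep(c("control", "high_intake"), each = 3),
                 reps = rep(1:3, 2))
  de <- differential_expression(m, "liver")
  flat <- de[de$feature_id == "flat", ]
  expect_equal(flat$p_value, 1)
  expect_equal(flat$log2fc, 0)
  expect_false(flat$is_de)
  ## exact fold change on the FPKM scale with the 1e-6 pseudo-abundance
  shifted <- de[de$feature_id == "shifted", ]
  expect_equal(shifted$fold_change, (63 + 1e-6) / (1 + 1e-6))
  ## zero variance in both groups, different means -> p = 0
  expect_equal(de$p_value[de$feature_id == "const_diff"], 0)
  expect_error(differential_expression(m, "adipose"), "not present")
})

test_that("DE calls are invariant to feature and sample order", {
  set.seed(88)
  v <- matrix(2^rnorm(50 * 6, 3), 50, 6)
  m <- make_expr(v, tissues = "liver",
                 treatments = rep(c("control", "high_intake"), each = 3),
                 reps = rep(1:3, 2))
  de1 <- differential_expression(m, "liver")
  perm_f <- sample(nrow(v))
  perm_s <- sample(ncol(v))
  m2 <- expression_matrix(m$values[perm_f, perm_s], m$sample_meta[perm_s, ])
  de2 <- differential_expression(m2, "liver")
  de2 <- de2[match(de1$feature_id, de2$feature_id), ]
  expect_equal(de2$p_value, de1$p_value)
  expect_equal(de2$q_value, de1$q_value)
  expect_equal(de2$fold_change, de1$fold_change)
})

test_that("BH adjustment matches the step-up oracle", {
  ## worked four-value example, by hand: all three small p share 0.04
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(stats::p.adjust(p, "BH"), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(oracle_bh(p), c(0.04, 0.04, 0.04, 0.5))
  set.seed(31)
  for (i in 1:25) {
    pv <- runif(sample(3:40, 1))
    expect_equal(stats::p.adjust(pv, "BH"), oracle_bh(pv), tolerance = 1e-12)
  }
})

test_that("percent_de reproduces printed two-decimal percentages", {
  expect_identical(percent_de(1930, 13815), 13.97)
  expect_identical(percent_de(302, 1570), 19.24)
  expect_identical(percent_de(0, 100), 0)
  ## half-up, not banker's rounding
  expect_identical(percent_de(1, 800), 0.13)
  expect_error(percent_de(5, 0), "n_expressed")
  expect_error(percent_de(10, 5), "n_de")
})

test_that("Venn regions are disjoint, complete, and match enumeration", {
  counts <- de_overlap_counts(list(A = c("1", "2"), B = c("2", "3")))
  expect_equal(counts[["A"]], 1L)
  expect_equal(counts[["B"]], 1L)
  expect_equal(counts[["A&B"]], 1L)
  same <- de_overlap_counts(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same[["A&B"]], 2L)
  expect_equal(same[["A"]] + same[["B"]], 0L)
  set.seed(404)
  for (i in 1:20) {
    sets <- list(A = sample(letters, 8), B = sample(letters, 12),
                 C = sample(letters, 5))
    counts <- de_overlap_counts(sets)
    ## brute-force region of every element
    uni <- unique(unlist(sets))
    for (el in uni) {
      membership <- names(sets)[vapply(sets, function(s) el %in% s,
                                       logical(1))]
      region <- paste(membership, collapse = "&")
      expect_true(counts[[region]] >= 1L)
    }
    expect_equal(sum(counts), length(uni))
  }
})

test_that("sample correlations match hand-computed Pearson values", {
  ## 4 samples, 3 features; correlations computed on log2(v+1)
  v <- cbind(s1 = c(0, 1, 3), s2 = c(0, 1, 3), s3 = c(3, 1, 0),
             s4 = c(1, 7, 31))
  rownames(v) <- c("fa", "fb", "fc")
  m <- make_expr(v, tissues = c("liver", "liver", "fat", "fat"),
                 treatments = rep("control", 4), reps = c(1, 2, 1, 2))
  co <- correlation_overview(m)
  expect_equal(co$sample_cor["s1", "s2"], 1)
  ## log2(v+1) of s1 is (0,1,2) and of s4 is (1,3,5): exact linear map
  expect_equal(co$sample_cor["s1", "s4"], 1)
  ## s3 reverses s1 -> r = -1
  expect_equal(co$sample_cor["s1", "s3"], -1)
  ## hand value for the within-group liver-fat mean:
  ## pairs (s1,s3), (s1,s4), (s2,s3), (s2,s4) -> (-1 + 1 - 1 + 1)/4 = 0
  wg <- co$within_group
  expect_equal(wg$mean_r[wg$tissue_a == "liver" & wg$tissue_b == "fat"], 0)
})

test_that("constant samples are excluded from correlation means", {
  v <- cbind(s1 = c(1, 2, 4), s2 = c(2, 2, 2), s3 = c(1, 2, 4))
  rownames(v) <- c("fa", "fb", "fc")
  m <- make_expr(v, tissues = c("liver", "fat", "fat"),
                 treatments = rep("control", 3), reps = c(1, 1, 2))
  expect_warning(co <- correlation_overview(m), "constant")
  expect_true(is.na(co$sample_cor["s1", "s2"]))
  wg <- co$within_group
  expect_equal(wg$n_pairs, 1L)
  expect_equal(wg$mean_r, 1)
})

test_that("pvca attributes pure tissue signal entirely to tissue", {
  set.seed(11)
  meta <- expand.grid(replicate = 1:3, treatment = c("control", "high_intake"),
                      tissue = c("liver", "aa", "sa"),
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("s%02d", seq_len(nrow(meta)))
  tis_eff <- matrix(rnorm(200 * 3, sd = 2), 200, 3)
  v <- 2^(tis_eff[, as.integer(factor(meta$tissue))] + 4)
  dimnames(v) <- list(sprintf("f%03d", 1:200), meta$sample_id)
  m <- expression_matrix(v, meta[, c("sample_id", "tissue", "treatment",
                                     "replicate")])
  res <- pvca(m)
  expect_equal(sum(res$weighted_proportions), 1, tolerance = 1e-9)
  expect_equal(unname(res$weighted_proportions[["tissue"]]), 1,
               tolerance = 1e-6)
})

test_that("pvca recovers a planted 3:1 tissue:treatment variance ratio", {
  set.seed(23)
  meta <- expand.grid(replicate = 1:3, treatment = c("control", "high_intake"),
                      tissue = c("liver", "aa", "sa"),
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("s%02d", seq_len(nrow(meta)))
  ratios <- replicate(10, {
    nf <- 600
    tis <- matrix(rnorm(nf * 3, sd = sqrt(3)), nf, 3)
    trt <- matrix(rnorm(nf * 2, sd = 1), nf, 2)
    noise <- matrix(rnorm(nf * 18), nf, 18)
    lv <- tis[, as.integer(factor(meta$tissue))] +
      trt[, as.integer(factor(meta$treatment))] + noise + 4
    v <- 2^lv
    dimnames(v) <- list(sprintf("f%03d", seq_len(nf)), meta$sample_id)
    m <- expression_matrix(v, meta[, c("sample_id", "tissue", "treatment",
                                       "replicate")])
    p <- pvca(m)$weighted_proportions
    p[["tissue"]] / p[["treatment"]]
  })
  expect_gt(mean(ratios), 3 * 0.75)
  expect_lt(mean(ratios), 3 * 1.25)
})

test_that("pvca rejects unbalanced designs and offers the means fallback", {
  set.seed(3)
  meta <- expand.grid(replicate = 1:3, treatment = c("control", "high_intake"),
                      tissue = c("liver", "aa"), stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("s%02d", seq_len(nrow(meta)))
  v <- 2^matrix(rnorm(100 * 12, 3), 100, 12,
                dimnames = list(sprintf("f%03d", 1:100), meta$sample_id))
  m <- expression_matrix(v, meta[, c("sample_id", "tissue", "treatment",
                                     "replicate")])
  drop <- m$sample_meta$sample_id != "s01"
  unb <- expression_matrix(m$values[, drop], m$sample_meta[drop, ])
  expect_error(pvca(unb), "means")
  res <- pvca(unb, method = "means")
  expect_equal(sum(res$weighted_proportions), 1, tolerance = 1e-9)
})
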
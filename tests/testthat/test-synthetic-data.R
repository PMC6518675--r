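small_cfg <- function(seed = 42, ...) {
  simulation_config(seed = seed, n_genes = 60, n_lncrna_per_category = 2,
                    n_planted_pairs = 3, chromosome_length = 2.2e6,
                    n_chromosomes = 2, n_families = 30, ...)
}

test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(de_fraction = 1.2), "de_fraction")
  expect_error(simulation_config(pair_correlation = 1), "pair_correlation")
  expect_error(simulation_config(noise_sd = -1), "standard deviations")
  expect_error(simulation_config(
    family_proportions = c(one_to_one = 0.9, expansion = 0.3)), "sum")
})

test_that("annotation generator plants the requested counts and geometry", {
  ann <- simulate_annotation(small_cfg())
  expect_equal(nrow(transcript_spans(ann$lncrna)), 10L)
  expect_equal(unname(table(ann$truth$lncrna_category)[
    c("sense_intergenic", "sense_genic", "convergent", "divergent",
      "antisense_intergenic")]), rep(2L, 5), ignore_attr = TRUE)
  ## genes have >= 2 exons, are non-overlapping, and keep the minimum gap
  gsp <- gene_spans(ann$genes)
  tsp <- transcript_spans(ann$genes)
  expect_true(all(tsp$n_exons >= 2))
  for (ch in unique(gsp$chrom)) {
    g <- gsp[gsp$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1)
      expect_true(all(g$start[-1] - g$end[-nrow(g)] - 1 >= 25000))
  }
  ## every planted entity exists in the emitted candidate set
  csp <- transcript_spans(ann$candidates)
  expect_true(all(names(ann$truth$lncrna_category) %in% csp$transcript_id))
  expect_true(all(names(ann$truth$decoy_expectation) %in% csp$transcript_id))
  expect_true(all(names(ann$sequences) == csp$transcript_id))
  expect_equal(unname(nchar(ann$sequences)), csp$spliced_length)
})

test_that("a chromosome too short for the requested genes is an error", {
  expect_error(simulate_annotation(
    simulation_config(n_genes = 100, chromosome_length = 5e5,
                      n_chromosomes = 1)), "capacity")
})

test_that("planted categories round-trip through the classifier", {
  ann <- simulate_annotation(small_cfg(seed = 1234))
  cls <- classify_lncrnas(ann$lncrna, ann$genes)
  expect_equal(cls$category,
               unname(ann$truth$lncrna_category[cls$transcript_id]))
  ## hand geometry on one planted convergent instance: opposite strand,
  ## non-overlapping, lncRNA on the gene's 3' side
  conv_id <- names(ann$truth$lncrna_category)[
    ann$truth$lncrna_category == "convergent"][1]
  rec <- cls[cls$transcript_id == conv_id, ]
  lsp <- transcript_spans(subset_transcripts(ann$lncrna, conv_id))
  g <- gene_spans(ann$genes)
  g <- g[g$gene_id == rec$nearest_gene_id, ]
  expect_true(lsp$strand != g$strand)
  expect_lt(rec$signed_distance, 0)          # downstream of the 3' end
  expect_gte(abs(rec$signed_distance), 2000)
  expect_lte(abs(rec$signed_distance), 8000)
  if (g$strand == "+") expect_gt(lsp$start, g$end) else
    expect_lt(lsp$end, g$start)
})

test_that("same seed gives byte-identical fixture files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulated_data(simulate_dataset(small_cfg(seed = 99)), d1)
  write_simulated_data(simulate_dataset(small_cfg(seed = 99)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  ## a different seed changes the expression fixture
  d3 <- withr::local_tempdir()
  write_simulated_data(simulate_dataset(small_cfg(seed = 100)), d3)
  expect_false(identical(readLines(file.path(d1, "expression.tsv")),
                         readLines(file.path(d3, "expression.tsv"))))
})

test_that("emitted GTF round-trips through the annotation reader", {
  ann <- simulate_annotation(small_cfg(seed = 77))
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann$genes, path)
  back <- read_gtf(path)
  norm <- function(a) {
    d <- as.data.frame(a)
    d <- d[order(d$transcript_id, d$start), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(norm(back), norm(ann$genes))
})

test_that("planted DE genes carry the configured fold ratio", {
  cfg <- simulation_config(seed = 11, de_log2fc = 2, noise_sd = 0.02,
                           de_fraction = 0.9, n_genes = 150,
                           n_lncrna_per_category = 2, n_planted_pairs = 3,
                           n_families = 20, chromosome_length = 5e6,
                           n_chromosomes = 2)
  sim <- simulate_dataset(cfg)
  meta <- sim$expression$sample_meta
  t1 <- cfg$tissues[1]
  truth <- sim$truth$de_genes[[t1]]
  expect_gte(length(truth), 100)
  ctrl <- meta$tissue == t1 & meta$treatment == "control"
  trt <- meta$tissue == t1 & meta$treatment == "high_intake"
  ratios <- vapply(truth, function(g) {
    mean(sim$expression$values[g, trt]) / mean(sim$expression$values[g, ctrl])
  }, numeric(1))
  ## fold ratio is 4 or 1/4 depending on the randomized sign
  folded <- ifelse(ratios > 1, ratios, 1 / ratios)
  expect_equal(mean(folded), 4, tolerance = 0.05)
  ## non-DE genes sit near ratio 1
  null_genes <- setdiff(gene_spans(sim$genes)$gene_id,
                        c(truth, sim$truth$planted_pairs$gene_id))
  null_ratios <- vapply(null_genes, function(g) {
    mean(sim$expression$values[g, trt]) / mean(sim$expression$values[g, ctrl])
  }, numeric(1))
  expect_equal(unname(mean(null_ratios)), 1, tolerance = 0.05)
})

test_that("zero noise with no planted effects gives identical replicates", {
  cfg <- small_cfg(seed = 3, noise_sd = 0, de_fraction = 0,
                   pair_correlation = 0)
  sim <- simulate_dataset(cfg)
  meta <- sim$expression$sample_meta
  for (t in unique(meta$tissue)) {
    for (g in unique(meta$treatment)) {
      cols <- which(meta$tissue == t & meta$treatment == g)
      block <- sim$expression$values[, cols]
      expect_equal(block - block[, 1], block * 0)
    }
  }
})

test_that("planted pairs reach the target correlation at modest sample size", {
  cfg <- small_cfg(seed = 21)
  ann <- simulate_annotation(cfg)
  hits <- 0L
  total <- 0L
  for (r in 1:50) {
    ex <- simulate_expression(cfg, ann, seed = 5000 + r)
    lv <- log2(ex$expression$values + 1)
    for (i in seq_len(nrow(ann$truth$planted_pairs))) {
      p <- ann$truth$planted_pairs[i, ]
      total <- total + 1L
      if (stats::cor(lv[p$lncrna_id, ], lv[p$gene_id, ]) > 0.80)
        hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("family generator realizes the planted category counts", {
  cfg <- simulation_config(seed = 8, n_families = 100)
  fam <- simulate_family_table(cfg)
  got <- table(fam$truth)
  pr <- cfg$family_proportions
  for (cc in names(pr)[names(pr) != "one_to_one"])
    expect_equal(unname(got[[cc]]), round(pr[[cc]] * 100))
  expect_equal(sum(got), 100L)
})
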
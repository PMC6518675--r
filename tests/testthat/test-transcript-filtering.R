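test_that("class codes cover the canonical structural relations", {
  ref <- one_tx("r1", "chr1", "+", list(c(1001L, 1600L), c(5401L, 6000L)),
                gene = "g1")
  ## identical intron chain, different terminal ends
  eq <- one_tx("c1", "chr1", "+", list(c(901L, 1600L), c(5401L, 6100L)))
  expect_equal(assign_class_code(eq, ref)$code, "=")
  expect_equal(assign_class_code(eq, ref)$matched_reference_id, "r1")
  ## mono-exon inside a reference exon, same strand
  contained <- one_tx("c2", "chr1", "+", list(c(1101L, 1400L)))
  expect_equal(assign_class_code(contained, ref)$code, "c")
  ## different chromosome -> unknown
  u <- one_tx("c3", "chr9", "+", list(c(1001L, 1500L)))
  expect_equal(assign_class_code(u, ref)$code, "u")
  ## opposite strand exonic overlap only
  x <- one_tx("c4", "chr1", "-", list(c(1201L, 1500L), c(2001L, 2300L)))
  expect_equal(assign_class_code(x, ref)$code, "x")
  ## partial same-strand overlap
  o <- one_tx("c5", "chr1", "+", list(c(1401L, 2500L)))
  expect_equal(assign_class_code(o, ref)$code, "o")
  ## intronic same-strand transcript: no exonic overlap -> 'u'
  intronic <- one_tx("c6", "chr1", "+", list(c(2001L, 2400L)))
  expect_equal(assign_class_code(intronic, ref)$code, "u")
})

test_that("class-code assignment agrees with the base-set oracle", {
  set.seed(1203)
  mismatches <- 0L
  for (rep in 1:1000) {
    n_ref_ex <- sample(1:3, 1L)
    r_starts <- sort(sample(seq(1L, 3000L, by = 50L), n_ref_ex))
    r_ex <- cbind(r_starts, r_starts + sample(20:45, n_ref_ex, replace = TRUE))
    r_strand <- sample(c("+", "-"), 1L)
    style <- sample(c("random", "copy", "fragment"), 1L)
    if (style == "copy") {
      c_ex <- r_ex
      c_ex[1L, 1L] <- max(1L, c_ex[1L, 1L] - sample(0:10, 1L))
      c_ex[nrow(c_ex), 2L] <- c_ex[nrow(c_ex), 2L] + sample(0:10, 1L)
      c_strand <- sample(c(r_strand, "+"), 1L)
    } else if (style == "fragment") {
      i <- sample(nrow(r_ex), 1L)
      s <- r_ex[i, 1L] + sample(0:5, 1L)
      c_ex <- cbind(s, min(r_ex[i, 2L], s + sample(5:30, 1L)))
      c_strand <- sample(c("+", "-"), 1L)
    } else {
      n_c_ex <- sample(1:3, 1L)
      c_starts <- sort(sample(seq(1L, 3200L, by = 40L), n_c_ex))
      c_ex <- cbind(c_starts, c_starts + sample(15:50, n_c_ex, replace = TRUE))
      c_strand <- sample(c("+", "-"), 1L)
    }
    ## keep exons disjoint with a gap (drop degenerate draws)
    if (nrow(c_ex) > 1L && any(c_ex[-1L, 1L] <= c_ex[-nrow(c_ex), 2L] + 1L))
      next
    if (nrow(r_ex) > 1L && any(r_ex[-1L, 1L] <= r_ex[-nrow(r_ex), 2L] + 1L))
      next
    ref <- one_tx("r", "chr1", r_strand, asplit(r_ex, 1L), gene = "gr")
    cand <- one_tx("cand", "chr1", c_strand, asplit(c_ex, 1L))
    got <- assign_class_code(cand, ref)$code
    want <- oracle_class_code(c_ex, c_strand,
                              list(list(exons = r_ex, strand = r_strand)))
    if (got != want) mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("ORF coding score matches the brute-force codon scan", {
  ## engineered 150-codon ORF (ATG + 149 sense codons, stop excluded) -> 1.5
  set.seed(7)
  orf <- paste0("ATG", paste(sample(c("GCC", "GAA", "CTT", "AAA"), 149,
                                    replace = TRUE), collapse = ""), "TAA")
  seqn <- paste0(orf, paste(rep("T", 200), collapse = ""))
  expect_equal(builtin_coding_score(seqn)$score, 1.5)
  expect_equal(oracle_orf_score(seqn), 1.5)
  ## repeated stops: no start codon at all -> score 0
  stops_only <- paste(rep("TAA", 100), collapse = "")
  expect_equal(builtin_coding_score(stops_only)$score, 0)
  ## below the 200-nt scoring precondition
  expect_error(builtin_coding_score(paste(rep("A", 150), collapse = "")),
               "200")
  ## random sequences against the oracle
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(200:600, 1L),
                      replace = TRUE), collapse = "")
    expect_equal(builtin_coding_score(s)$score, oracle_orf_score(s))
  }
})

test_that("external score tables parse with last-wins duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tscore", "tx1\t2.3", "tx2\t0.4", "tx1\t0.9"),
             path)
  expect_warning(sc <- load_external_scores(path), "duplicate")
  expect_equal(sc$score[sc$transcript_id == "tx1"], 0.9)
  expect_equal(unique(sc$source), "external")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tx1\t2.3", "tx2\tnot_a_number"), bad)
  expect_error(load_external_scores(bad), "line 2")

  short <- withr::local_tempfile(fileext = ".tsv")
  writeLines("tx_only_one_field", short)
  expect_error(load_external_scores(short), "malformed")
})

test_that("the cascade attributes each removal to its first failing stage", {
  fx <- hand_cascade_fixture()
  res <- filter_candidates(fx$candidates, fx$reference, scores = fx$scores)
  rep <- res$report
  expect_equal(rep$input_count, 6L)
  expect_setequal(rep$surviving_ids, c("F5_x", "F6_u"))
  expect_equal(rep$removed_by[["class_code"]], 1L)
  expect_equal(rep$removed_by[["unstranded"]], 0L)
  expect_equal(rep$removed_by[["min_length"]], 1L)
  expect_equal(rep$removed_by[["coding_score"]], 1L)
  expect_equal(rep$removed_by[["mono_exonic"]], 1L)
  det <- rep$details
  expect_equal(det$class_code[det$transcript_id == "F5_x"], "x")
  expect_equal(det$class_code[det$transcript_id == "F6_u"], "u")
})

test_that("cascade handles empty input and all-reference input", {
  fx <- hand_cascade_fixture()
  empty <- subset_transcripts(fx$candidates, character(0))
  res <- filter_candidates(empty, fx$reference, scores = fx$scores)
  expect_equal(res$report$input_count, 0L)
  expect_equal(sum(res$report$removed_by), 0L)
  expect_length(res$report$surviving_ids, 0L)

  dup <- subset_transcripts(fx$candidates, "F1_eq")
  res2 <- filter_candidates(dup, fx$reference)
  expect_equal(res2$report$removed_by[["class_code"]], 1L)
  expect_length(res2$report$surviving_ids, 0L)
})

test_that("cascade errors when a scored candidate lacks sequence and score", {
  fx <- hand_cascade_fixture()
  no_f6 <- fx$scores[fx$scores$transcript_id != "F6_u", ]
  expect_error(filter_candidates(fx$candidates, fx$reference, scores = no_f6),
               "F6_u")
})

test_that("unstranded candidates are removed under their own counter", {
  fx <- hand_cascade_fixture()
  dotted <- as.data.frame(fx$candidates)
  dotted$strand[dotted$transcript_id == "F6_u"] <- "."
  res <- filter_candidates(annotation_set(dotted), fx$reference,
                           scores = fx$scores)
  expect_equal(res$report$removed_by[["unstranded"]], 1L)
  expect_setequal(res$report$surviving_ids, "F5_x")
})

test_that("report accounting holds and survivors satisfy every filter", {
  set.seed(2931)
  sim <- simulate_dataset(simulation_config(seed = 17, n_genes = 60,
                                            n_lncrna_per_category = 2,
                                            n_planted_pairs = 3,
                                            chromosome_length = 2.2e6,
                                            n_chromosomes = 2,
                                            n_families = 30))
  res <- filter_candidates(sim$candidates, sim$genes,
                           sequences = sim$sequences)
  rep <- res$report
  expect_equal(rep$input_count,
               sum(rep$removed_by) + length(rep$surviving_ids))
  surv <- rep$details[rep$details$status == "retained", ]
  expect_true(all(!surv$class_code %in% c("=", "c")))
  expect_true(all(surv$spliced_length >= 200))
  expect_true(all(surv$coding_score <= 1))
  expect_true(all(surv$n_exons >= 2))
  ## every planted decoy is removed at exactly its engineered stage
  truth <- sim$truth$decoy_expectation
  stage_of <- c(class_eq = "class_code", class_contained = "class_code",
                short = "min_length", coding = "coding_score",
                mono_exonic = "mono_exonic")
  det <- rep$details
  for (tx in names(truth))
    expect_equal(det$status[det$transcript_id == tx],
                 unname(stage_of[[truth[[tx]]]]), label = tx)
})
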
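#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the seeded simulator in one validated object.
#' The defaults mirror the study design the package targets: 3 tissues
#' (liver and two adipose depots) x 2 feeding treatments x 3 biological
#' replicates = 18 samples, FPKM-like expression with log-normal replicate
#' noise, and planted ground truth for every downstream stage (lncRNA
#' positional categories, DE genes, correlated lncRNA-mRNA pairs, ortholog
#' family categories).
#'
#' @param seed integer RNG seed; a fixed config is guaranteed to produce
#'   byte-identical outputs.
#' @param n_chromosomes,chromosome_length toy genome shape (bp).
#' @param n_genes number of non-overlapping protein-coding genes.
#' @param n_lncrna_per_category planted lncRNAs per positional category
#'   (5 categories).
#' @param n_samples_per_group biological replicates per tissue x treatment
#'   cell (default 3).
#' @param tissues tissue labels.
#' @param de_fraction fraction of genes planted as DE per tissue.
#' @param de_log2fc planted treatment effect on the log2 scale (sign
#'   randomized per gene).
#' @param pair_correlation target Pearson r of planted lncRNA-mRNA pairs,
#'   induced by a shared Gaussian latent factor with loading
#'   `noise_sd * sqrt(r / (1 - r))` so the expected correlation equals the
#'   target.
#' @param noise_sd log2-scale replicate noise standard deviation.
#' @param n_planted_pairs number of planted correlated lncRNA-mRNA pairs
#'   (drawn from cis-proximal planted lncRNAs and their anchor genes).
#' @param baseline_log2_mean,baseline_log2_sd log2 FPKM baseline
#'   distribution across features.
#' @param tissue_sd per-feature tissue effect standard deviation (log2).
#' @param min_intergenic_gap minimum gap between gene spans (bp); the
#'   default 25 kb keeps 10 kb cis windows unambiguous.
#' @param n_decoys_per_type candidates planted to fail each cascade stage
#'   (reference-matching, contained, short, coding, mono-exonic).
#' @param n_families,family_proportions ortholog family table size and
#'   planted category mix (proportions must sum to <= 1; any remainder
#'   goes to one-to-one families).
#' @param focal_species,reference_species species labels of the family
#'   table.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 3L,
                              chromosome_length = 7e6,
                              n_genes = 300L,
                              n_lncrna_per_category = 6L,
                              n_samples_per_group = 3L,
                              tissues = c("liver", "abdominal_adipose",
                                          "subcutaneous_adipose"),
                              de_fraction = 0.2,
                              de_log2fc = 3,
                              pair_correlation = 0.95,
                              noise_sd = 0.25,
                              n_planted_pairs = 8L,
                              baseline_log2_mean = 3,
                              baseline_log2_sd = 1.5,
                              tissue_sd = 1,
                              min_intergenic_gap = 25000L,
                              n_decoys_per_type = 3L,
                              n_families = 150L,
                              family_proportions = c(one_to_one = 0.5,
                                                     expansion = 0.12,
                                                     contraction = 0.12,
                                                     many_to_many = 0.1,
                                                     focal_specific = 0.08,
                                                     reference_specific = 0.08),
                              focal_species = "goose",
                              reference_species = "human") {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.numeric(chromosome_length),
              n_genes = as.integer(n_genes),
              n_lncrna_per_category = as.integer(n_lncrna_per_category),
              n_samples_per_group = as.integer(n_samples_per_group),
              tissues = as.character(tissues), de_fraction = de_fraction,
              de_log2fc = de_log2fc, pair_correlation = pair_correlation,
              noise_sd = noise_sd, n_planted_pairs = as.integer(n_planted_pairs),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd, tissue_sd = tissue_sd,
              min_intergenic_gap = as.integer(min_intergenic_gap),
              n_decoys_per_type = as.integer(n_decoys_per_type),
              n_families = as.integer(n_families),
              family_proportions = family_proportions,
              focal_species = focal_species,
              reference_species = reference_species)
  counts <- c("n_chromosomes", "n_genes", "n_lncrna_per_category",
              "n_samples_per_group", "n_families")
  for (nm in counts) if (cfg[[nm]] <= 0L) stopf("%s must be > 0", nm)
  if (cfg$chromosome_length <= 0) stopf("chromosome_length must be > 0")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stopf("de_fraction must lie in [0, 1]")
  if (cfg$pair_correlation < 0 || cfg$pair_correlation >= 1)
    stopf("pair_correlation must lie in [0, 1)")
  if (cfg$noise_sd < 0 || cfg$tissue_sd < 0)
    stopf("noise and effect standard deviations must be >= 0")
  if (length(cfg$tissues) < 1L) stopf("need at least one tissue")
  pr <- cfg$family_proportions
  if (is.null(names(pr)) || !all(names(pr) %in% family_categories))
    stopf("family_proportions must be named by category")
  if (any(pr < 0) || sum(pr) > 1 + 1e-9)
    stopf("family_proportions must be >= 0 and sum to <= 1")
  structure(cfg, class = "simulation_config")
}

lnc_categories <- c("sense_intergenic", "sense_genic", "convergent",
                    "divergent", "antisense_intergenic")

## deterministic feature id schemes
gene_ids_for <- function(n) sprintf("G%04d", seq_len(n))

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## noncoding-by-construction sequence: rejection-sample until the ORF score
## stays at or below 1 (ORF <= 100 codons)
benign_seq <- function(len) {
  for (i in 1:100) {
    s <- random_seq(len)
    if (len < 200L) return(s)  # scored sequences are always >= 200 nt
    if (builtin_coding_score(s)$score <= 1) return(s)
  }
  stopf("failed to draw a noncoding sequence of length %d", len)
}

## coding sequence: a guaranteed 150-codon ORF (ATG + 149 sense codons)
coding_seq <- function(len) {
  sense <- setdiff(apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")), 1L, paste,
                         collapse = ""),
                   c("TAA", "TAG", "TGA"))
  orf <- paste0("ATG", paste(sample(sense, 149, replace = TRUE), collapse = ""),
                "TAA")
  pad <- len - nchar(orf)
  if (pad < 0) stopf("coding decoy length too short")
  paste0(orf, random_seq(pad))
}

#' Generate a toy annotated genome with planted lncRNAs
#'
#' Places non-overlapping two-exon protein-coding genes on fixed-width
#' slots (guaranteeing at least `min_intergenic_gap` between gene spans
#' and an unambiguous nearest gene for every planted lncRNA), then
#' constructs `n_lncrna_per_category` lncRNAs per positional category by
#' explicit geometry around randomly chosen anchor genes. Candidate
#' transcripts for the discovery cascade comprise the planted lncRNAs plus
#' decoys engineered to fail each filter stage (a reference copy, a
#' contained mono-exon, a short transcript, a coding transcript, a benign
#' mono-exon). Spliced candidate sequences are generated alongside
#' (noncoding by construction except the coding decoys).
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed override (defaults to `config$seed`).
#' @return list with `genes` (reference [annotation_set()]), `lncrna`
#'   (planted lncRNA [annotation_set()]), `candidates` (lncRNAs plus
#'   decoys), `sequences` (named character vector of spliced candidate
#'   sequences), and `truth` (list with `lncrna_category`,
#'   `decoy_expectation`, `planted_pairs`, `anchor_gene`).
#' @export
simulate_annotation <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(seed + 11L, {
    gene_len <- 5000L
    margin <- 10000L
    slot_width <- config$min_intergenic_gap + 35000L
    per_chrom <- floor((config$chromosome_length - 2 * margin) / slot_width)
    capacity <- config$n_chromosomes * per_chrom
    if (capacity < config$n_genes)
      stopf(paste("chromosomes too short: capacity %d gene slot(s) < %d genes;",
                  "increase chromosome_length"), capacity, config$n_genes)
    n_lnc <- 5L * config$n_lncrna_per_category
    if (config$n_genes < n_lnc + 5L * config$n_decoys_per_type)
      stopf("need n_genes >= planted lncRNAs + decoys (one anchor gene each)")
    gid <- gene_ids_for(config$n_genes)
    slot_idx <- seq_len(config$n_genes) - 1L
    chrom_i <- slot_idx %/% per_chrom + 1L
    within <- slot_idx %% per_chrom
    slot_start <- margin + within * slot_width + 1L
    gs <- slot_start + 25000L
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    chrom <- sprintf("chr%d", chrom_i)
    ## two exons of 600 bp around a 3800 bp intron
    gene_ex <- do.call(rbind, lapply(seq_len(config$n_genes), function(i) {
      data.frame(chrom = chrom[i],
                 start = c(gs[i], gs[i] + gene_len - 600L),
                 end = c(gs[i] + 599L, gs[i] + gene_len - 1L),
                 strand = strand[i], gene_id = gid[i],
                 transcript_id = paste0(gid[i], ".t1"),
                 biotype = "protein_coding", stringsAsFactors = FALSE)
    }))
    genes <- annotation_set(gene_ex)
    ge <- gs + gene_len - 1L

    ## plant lncRNAs around distinct anchor genes
    anchors <- sample(config$n_genes, n_lnc)
    categories <- rep(lnc_categories, each = config$n_lncrna_per_category)
    lnc_rows <- list()
    lnc_category <- character(0)
    anchor_of <- character(0)
    for (k in seq_len(n_lnc)) {
      i <- anchors[k]
      cat_k <- categories[k]
      e1 <- 300L; e2 <- 400L
      intron <- sample(300:800, 1L)
      span <- e1 + intron + e2
      opp <- if (strand[i] == "+") "-" else "+"
      if (cat_k == "sense_genic") {
        l_start <- gs[i] + 700L        # inside the gene's intron
        l_strand <- strand[i]
      } else {
        gap <- if (cat_k == "antisense_intergenic") sample(12000:18000, 1L) else
          sample(2000:8000, 1L)
        side <- switch(cat_k,
                       sense_intergenic = sample(c("left", "right"), 1L),
                       convergent = if (strand[i] == "+") "right" else "left",
                       divergent = if (strand[i] == "+") "left" else "right",
                       antisense_intergenic = sample(c("left", "right"), 1L))
        l_strand <- if (cat_k == "sense_intergenic") strand[i] else opp
        l_start <- if (side == "right") ge[i] + gap + 1L else
          gs[i] - gap - span
      }
      tx <- sprintf("LNC%04d", k)
      lnc_rows[[k]] <- data.frame(
        chrom = chrom[i],
        start = c(l_start, l_start + e1 + intron),
        end = c(l_start + e1 - 1L, l_start + span - 1L),
        strand = l_strand, gene_id = tx, transcript_id = tx,
        biotype = "lncRNA", stringsAsFactors = FALSE)
      lnc_category <- c(lnc_category, cat_k)
      anchor_of <- c(anchor_of, gid[i])
    }
    lnc_ids <- sprintf("LNC%04d", seq_len(n_lnc))
    names(lnc_category) <- lnc_ids
    names(anchor_of) <- lnc_ids
    lncrna <- annotation_set(do.call(rbind, lnc_rows))

    ## decoys in the slots of genes without a planted lncRNA
    free <- setdiff(seq_len(config$n_genes), anchors)
    decoy_rows <- list()
    decoy_expectation <- character(0)
    nd <- config$n_decoys_per_type
    decoy_types <- rep(c("class_eq", "class_contained", "short", "coding",
                         "mono_exonic"), each = nd)
    for (k in seq_along(decoy_types)) {
      i <- free[k]
      ty <- decoy_types[k]
      tx <- sprintf("DEC%03d", k)
      row <- switch(ty,
        class_eq = data.frame(        # identical intron chain, longer ends
          chrom = chrom[i], start = c(gs[i] - 50L, gs[i] + gene_len - 600L),
          end = c(gs[i] + 599L, gs[i] + gene_len + 49L), strand = strand[i],
          gene_id = tx, transcript_id = tx, biotype = "candidate",
          stringsAsFactors = FALSE),
        class_contained = data.frame( # mono-exon inside the first gene exon
          chrom = chrom[i], start = gs[i] + 100L, end = gs[i] + 499L,
          strand = strand[i], gene_id = tx, transcript_id = tx,
          biotype = "candidate", stringsAsFactors = FALSE),
        short = data.frame(           # spliced length 170 < 200
          chrom = chrom[i], start = gs[i] - c(23000L, 22500L),
          end = gs[i] - c(23000L, 22500L) + c(89L, 79L), strand = "+",
          gene_id = tx, transcript_id = tx, biotype = "candidate",
          stringsAsFactors = FALSE),
        coding = data.frame(          # carries a 150-codon ORF
          chrom = chrom[i], start = gs[i] - c(21000L, 20200L),
          end = gs[i] - c(21000L, 20200L) + c(299L, 299L), strand = "+",
          gene_id = tx, transcript_id = tx, biotype = "candidate",
          stringsAsFactors = FALSE),
        mono_exonic = data.frame(     # single benign exon
          chrom = chrom[i], start = gs[i] - 19000L, end = gs[i] - 18501L,
          strand = "+", gene_id = tx, transcript_id = tx,
          biotype = "candidate", stringsAsFactors = FALSE))
      decoy_rows[[k]] <- row
      decoy_expectation <- c(decoy_expectation, ty)
      names(decoy_expectation)[length(decoy_expectation)] <- tx
    }
    candidates_ex <- rbind(as.data.frame(lncrna),
                           do.call(rbind, decoy_rows))
    candidates <- annotation_set(candidates_ex)

    ## spliced sequences for every candidate
    csp <- transcript_spans(candidates)
    sequences <- character(nrow(csp))
    names(sequences) <- csp$transcript_id
    for (j in seq_len(nrow(csp))) {
      tx <- csp$transcript_id[j]
      len <- csp$spliced_length[j]
      ty <- if (tx %in% names(decoy_expectation)) decoy_expectation[[tx]] else "lnc"
      sequences[[tx]] <- if (ty == "coding") coding_seq(len) else benign_seq(len)
    }

    ## planted correlated pairs: cis-proximal lncRNAs with their anchors
    cis_cats <- c("sense_intergenic", "convergent", "divergent")
    eligible <- lnc_ids[lnc_category %in% cis_cats]
    if (config$n_planted_pairs > length(eligible))
      stopf("n_planted_pairs exceeds the %d cis-proximal planted lncRNAs",
            length(eligible))
    pair_lnc <- sort(sample(eligible, config$n_planted_pairs))
    planted_pairs <- data.frame(lncrna_id = pair_lnc,
                                gene_id = unname(anchor_of[pair_lnc]),
                                target_r = config$pair_correlation,
                                stringsAsFactors = FALSE)

    list(genes = genes, lncrna = lncrna, candidates = candidates,
         sequences = sequences,
         truth = list(lncrna_category = lnc_category,
                      decoy_expectation = decoy_expectation,
                      planted_pairs = planted_pairs,
                      anchor_gene = anchor_of))
  })
}

#' Simulate an FPKM expression matrix with planted effects
#'
#' Per feature: a log-normal baseline (`log2` mean and sd from the
#' config), an additive per-tissue effect, a treatment effect of
#' `de_log2fc` (sign randomized) on the planted DE genes of each tissue,
#' and i.i.d. Gaussian replicate noise on the log2 scale. Each planted
#' lncRNA-mRNA pair shares a per-sample latent factor whose loading is
#' chosen analytically so the expected Pearson correlation equals
#' `pair_correlation`; pair members carry no tissue or treatment effects
#' so the planted correlation is not confounded. FPKM values are
#' `2^log2x`, hence non-negative.
#'
#' @param config a [simulation_config()].
#' @param annotation output of [simulate_annotation()].
#' @param seed RNG seed override (defaults to `config$seed`).
#' @return list with `expression` (an [expression_matrix()] over genes and
#'   lncRNAs) and `truth` (the annotation truth extended with `de_genes`,
#'   a per-tissue list of planted DE feature ids).
#' @export
simulate_expression <- function(config, annotation, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  gsp <- gene_spans(annotation$genes)
  lsp <- transcript_spans(annotation$lncrna)
  features <- c(gsp$gene_id, lsp$transcript_id)
  if (anyDuplicated(features)) stopf("duplicate feature ids in annotation")
  tissues <- config$tissues
  reps <- config$n_samples_per_group
  meta <- expand.grid(replicate = seq_len(reps),
                      treatment = c("control", "high_intake"),
                      tissue = tissues, stringsAsFactors = FALSE)
  meta <- meta[, c("tissue", "treatment", "replicate")]
  meta$sample_id <- sprintf("%s_%s_%d", meta$tissue, meta$treatment,
                            meta$replicate)
  ns <- nrow(meta)
  nf <- length(features)
  pair <- annotation$truth$planted_pairs
  pair_members <- unique(c(pair$lncrna_id, pair$gene_id))
  with_seed(seed + 22L, {
    base <- stats::rnorm(nf, config$baseline_log2_mean, config$baseline_log2_sd)
    tissue_eff <- matrix(stats::rnorm(nf * length(tissues), 0, config$tissue_sd),
                         nf, length(tissues),
                         dimnames = list(features, tissues))
    tissue_eff[features %in% pair_members, ] <- 0
    ## planted DE genes per tissue, signs randomized; pair members excluded
    de_pool <- setdiff(gsp$gene_id, pair_members)
    n_de <- round(config$de_fraction * length(de_pool))
    de_genes <- list()
    de_sign <- list()
    for (t in tissues) {
      ids <- sort(sample(de_pool, n_de))
      de_genes[[t]] <- ids
      de_sign[[t]] <- stats::setNames(sample(c(-1, 1), n_de, replace = TRUE), ids)
    }
    ## shared latent factors for planted pairs
    loading <- if (config$pair_correlation > 0) {
      config$noise_sd * sqrt(config$pair_correlation /
                             (1 - config$pair_correlation))
    } else 0
    latent <- matrix(stats::rnorm(nrow(pair) * ns), nrow(pair), ns)
    log2x <- matrix(base, nf, ns)
    rownames(log2x) <- features
    colnames(log2x) <- meta$sample_id
    for (s in seq_len(ns)) {
      t <- meta$tissue[s]
      log2x[, s] <- log2x[, s] + tissue_eff[, t]
      if (meta$treatment[s] == "high_intake" && n_de > 0L) {
        ids <- de_genes[[t]]
        log2x[ids, s] <- log2x[ids, s] + config$de_log2fc * de_sign[[t]][ids]
      }
    }
    if (nrow(pair) > 0L && loading > 0) {
      for (p in seq_len(nrow(pair))) {
        log2x[pair$lncrna_id[p], ] <- log2x[pair$lncrna_id[p], ] +
          loading * latent[p, ]
        log2x[pair$gene_id[p], ] <- log2x[pair$gene_id[p], ] +
          loading * latent[p, ]
      }
    }
    noise <- matrix(stats::rnorm(nf * ns, 0, config$noise_sd), nf, ns)
    values <- 2^(log2x + noise)
    truth <- annotation$truth
    truth$de_genes <- de_genes
    list(expression = expression_matrix(values, meta[, c("sample_id", "tissue",
                                                         "treatment",
                                                         "replicate")]),
         truth = truth)
  })
}

#' Simulate an ortholog family table with planted categories
#'
#' Emits a long-format family table (`family_id`, `species`, `gene_id`)
#' whose per-family copy counts realize the planted category mix of the
#' config. Focal-species gene ids reuse the simulator's gene id scheme so
#' family genes line up with the expression features where counts permit.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed override (defaults to `config$seed`).
#' @return list with `family` (long data frame) and `truth` (named
#'   category vector per family id).
#' @export
simulate_family_table <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  pr <- config$family_proportions
  n <- config$n_families
  counts <- stats::setNames(integer(length(family_categories)),
                            family_categories)
  counts[names(pr)] <- round(pr * n)
  counts["one_to_one"] <- counts["one_to_one"] + (n - sum(counts))
  if (any(counts < 0)) stopf("family category counts must be >= 0")
  with_seed(seed + 33L, {
    cats <- rep(names(counts), counts)
    rows <- list()
    truth <- stats::setNames(character(n), sprintf("FAM%04d", seq_len(n)))
    focal_counter <- 0L
    ref_counter <- 0L
    for (i in seq_len(n)) {
      fam <- sprintf("FAM%04d", i)
      cc <- cats[i]
      nf <- switch(cc, one_to_one = 1L, many_to_many = sample(2:4, 1L),
                   expansion = sample(2:4, 1L),
                   contraction = sample(1:3, 1L),
                   focal_specific = sample(1:3, 1L), reference_specific = 0L)
      nr <- switch(cc, one_to_one = 1L, many_to_many = nf,
                   expansion = sample(seq_len(nf - 1L), 1L),
                   contraction = nf + sample(1:3, 1L),
                   focal_specific = 0L, reference_specific = sample(1:3, 1L))
      truth[[fam]] <- cc
      if (nf > 0L) {
        ids <- sprintf("G%04d", focal_counter + seq_len(nf))
        focal_counter <- focal_counter + nf
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = fam, species = config$focal_species, gene_id = ids,
          stringsAsFactors = FALSE)
      }
      if (nr > 0L) {
        ids <- sprintf("REF%04d", ref_counter + seq_len(nr))
        ref_counter <- ref_counter + nr
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = fam, species = config$reference_species, gene_id = ids,
          stringsAsFactors = FALSE)
      }
    }
    list(family = do.call(rbind, rows), truth = truth)
  })
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: annotation + candidates, expression, and the
#' family table, with a combined ground-truth list.
#'
#' @param config a [simulation_config()].
#' @return list with `genes`, `lncrna`, `candidates`, `sequences`,
#'   `expression`, `family`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  ann <- simulate_annotation(config)
  expr <- simulate_expression(config, ann)
  fam <- simulate_family_table(config)
  truth <- expr$truth
  truth$family_category <- fam$truth
  list(genes = ann$genes, lncrna = ann$lncrna, candidates = ann$candidates,
       sequences = ann$sequences, expression = expr$expression,
       family = fam$family, truth = truth, config = config)
}

#' Write a simulated dataset to plain-text fixture files
#'
#' Emits `reference.gtf`, `candidates.gtf`, `expression.tsv` (feature id
#' plus one column per sample), `samples.tsv` (sample metadata sidecar),
#' `families.tsv` and `truth.json` into a directory. Output is
#' deterministic for a fixed config.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulated_data <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gtf(sim$genes, file.path(dir, "reference.gtf"))
  write_gtf(sim$candidates, file.path(dir, "candidates.gtf"))
  expr <- data.frame(feature_id = rownames(sim$expression$values),
                     sim$expression$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$expression$sample_meta, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$family, file.path(dir, "families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$lncrna_category <- as.list(truth$lncrna_category)
  truth$decoy_expectation <- as.list(truth$decoy_expectation)
  truth$family_category <- as.list(truth$family_category)
  truth$anchor_gene <- as.list(truth$anchor_gene)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
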
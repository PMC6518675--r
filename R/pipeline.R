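#' Configuration for an end-to-end pipeline run
#'
#' Bundles the simulation config, every analysis threshold, per-stage
#' toggles and the top-level seed. All randomness in a run flows from
#' `seed`.
#'
#' @param seed integer seed driving the whole run.
#' @param sim a [simulation_config()]; its seed is overridden by `seed`.
#' @param out_dir optional directory for fixture files and the JSON
#'   report.
#' @param stages named logical vector toggling `simulate`, `discover`,
#'   `classify`, `de`, `pairs`, `orthologs`, `energy`.
#' @param min_length,max_score,min_exons discovery cascade thresholds.
#' @param fpkm_threshold expressed-feature threshold (strict >).
#' @param cis_window,orientation_window classification windows in bp.
#' @param r_min,p_max correlation pair thresholds (strict).
#' @param alpha DE FDR level.
#' @param top_n_pairs size of the ranked cis-pair table.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = simulation_config(),
                            out_dir = NULL,
                            stages = c(simulate = TRUE, discover = TRUE,
                                       classify = TRUE, de = TRUE,
                                       pairs = TRUE, orthologs = TRUE,
                                       energy = TRUE),
                            min_length = 200, max_score = 1, min_exons = 2,
                            fpkm_threshold = 0.1, cis_window = 10000,
                            orientation_window = 10000, r_min = 0.80,
                            p_max = 0.05, alpha = 0.05, top_n_pairs = 10) {
  all_stages <- c("simulate", "discover", "classify", "de", "pairs",
                  "orthologs", "energy")
  st <- stats::setNames(rep(TRUE, length(all_stages)), all_stages)
  st[names(stages)] <- stages
  if (min_length < 0 || max_score < 0 || min_exons < 1 ||
      fpkm_threshold < 0 || cis_window < 0 || orientation_window < 0 ||
      r_min < -1 || r_min > 1 || p_max <= 0 || p_max > 1 || alpha <= 0 ||
      alpha > 1)
    stopf("a pipeline threshold is outside its documented range")
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, out_dir = out_dir,
                 stages = st, min_length = min_length, max_score = max_score,
                 min_exons = min_exons, fpkm_threshold = fpkm_threshold,
                 cis_window = cis_window,
                 orientation_window = orientation_window, r_min = r_min,
                 p_max = p_max, alpha = alpha, top_n_pairs = top_n_pairs),
            class = "pipeline_config")
}

require_stage <- function(state, key, dep, stage) {
  if (is.null(state[[key]]))
    stopf("stage '%s' requires output of stage '%s'; enable it or supply its files",
          stage, dep)
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Executes simulate -> discover -> classify -> de -> pairs -> orthologs
#' -> energy in dependency order, collecting a machine-readable report.
#' A failure inside a stage aborts with a stage-prefixed error; a disabled
#' stage makes its dependants fail with a clear dependency message rather
#' than silently reusing stale results.
#'
#' @param config a [pipeline_config()].
#' @return object of class `lncflux_report` (also written as
#'   `report.json` plus fixture files when `config$out_dir` is set).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  state <- new.env(parent = emptyenv())
  report <- list(schema_version = "1.0",
                 tool = paste0("lncflux ",
                               as.character(utils::packageVersion("lncflux"))),
                 seed = config$seed, stages = list())
  run <- function(stage, fun) {
    if (!config$stages[[stage]]) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e)
      stopf("stage '%s': %s", stage, conditionMessage(e)))
    report$stages[[stage]] <<- res
  }

  run("simulate", function() {
    state$sim <- simulate_dataset(config$sim)
    if (!is.null(config$out_dir))
      write_simulated_data(state$sim, file.path(config$out_dir, "simulated"))
    list(n_genes = nrow(gene_spans(state$sim$genes)),
         n_planted_lncrna = nrow(transcript_spans(state$sim$lncrna)),
         n_candidates = nrow(transcript_spans(state$sim$candidates)))
  })

  run("discover", function() {
    require_stage(state, "sim", "simulate", "discover")
    disc <- filter_candidates(state$sim$candidates, state$sim$genes,
                              sequences = state$sim$sequences,
                              min_length = config$min_length,
                              max_score = config$max_score,
                              min_exons = config$min_exons)
    state$lnc_set <- disc$lncrna
    list(input_count = disc$report$input_count,
         removed_by = as.list(disc$report$removed_by),
         n_lncrna = length(disc$report$surviving_ids))
  })

  run("classify", function() {
    require_stage(state, "lnc_set", "discover", "classify")
    cls <- classify_lncrnas(state$lnc_set, state$sim$genes,
                            orientation_window = config$orientation_window,
                            cis_window = config$cis_window)
    state$classification <- cls
    state$cis <- cis_candidates(state$lnc_set, state$sim$genes,
                                window = config$cis_window)
    list(category_counts = as.list(table(cls$category)),
         n_cis_candidates = sum(cls$cis_candidate),
         n_cis_pairs = nrow(state$cis))
  })

  run("de", function() {
    require_stage(state, "sim", "simulate", "de")
    require_stage(state, "lnc_set", "discover", "de")
    expr <- state$sim$expression
    lnc_ids <- transcript_spans(state$lnc_set)$transcript_id
    gene_ids <- gene_spans(state$sim$genes)$gene_id
    split_one <- function(ids) expression_matrix(
      expr$values[rownames(expr$values) %in% ids, , drop = FALSE],
      expr$sample_meta)
    summarise_de <- function(m) {
      fe <- filter_expressed(m, threshold = config$fpkm_threshold)
      per_tissue <- list()
      de_sets <- list()
      for (t in unique(m$sample_meta$tissue)) {
        de <- differential_expression(fe$matrix, t, alpha = config$alpha)
        de_sets[[t]] <- de$feature_id[de$is_de]
        per_tissue[[t]] <- list(n_de = sum(de$is_de),
                                n_expressed = fe$n_expressed,
                                percent_de = percent_de(sum(de$is_de),
                                                        fe$n_expressed))
      }
      list(matrix = fe$matrix, per_tissue = per_tissue, de_sets = de_sets)
    }
    mrna <- summarise_de(split_one(gene_ids))
    lnc <- summarise_de(split_one(lnc_ids))
    state$mrna_expr <- mrna$matrix
    state$lnc_expr <- lnc$matrix
    state$de_sets <- mrna$de_sets
    pv <- pvca(state$sim$expression)
    venn <- de_overlap_counts(mrna$de_sets)
    list(mrna = mrna$per_tissue, lncrna = lnc$per_tissue,
         venn_mrna = as.list(venn),
         pvca = as.list(pv$weighted_proportions))
  })

  run("pairs", function() {
    require_stage(state, "mrna_expr", "de", "pairs")
    require_stage(state, "cis", "classify", "pairs")
    pairs <- correlated_pairs(state$lnc_expr, state$mrna_expr,
                              r_min = config$r_min, p_max = config$p_max)
    top <- join_cis(pairs, state$cis, top_n = config$top_n_pairs)
    state$pairs <- pairs
    list(n_correlated_pairs = nrow(pairs), n_cis_correlated = nrow(
           join_cis(pairs, state$cis, top_n = Inf)),
         top_pairs = top)
  })

  run("orthologs", function() {
    require_stage(state, "sim", "simulate", "orthologs")
    require_stage(state, "de_sets", "de", "orthologs")
    fam <- categorize_families(state$sim$family, config$sim$focal_species,
                               config$sim$reference_species)
    focal_map <- state$sim$family[
      state$sim$family$species == config$sim$focal_species,
      c("gene_id", "family_id")]
    de_prop <- de_proportion_by_category(fam$records,
                                         state$de_sets[[1L]], focal_map)
    universe <- rownames(state$mrna_expr$values)
    gene_set <- intersect(focal_map$gene_id, universe)
    enrich <- if (length(gene_set) > 0L && length(gene_set) < length(universe)) {
      ce <- contingency_enrichment(gene_set, state$de_sets[[1L]], universe)
      list(chi_square = ce$chi_square, p_value = ce$p_value,
           odds_ratio = ce$odds_ratio)
    } else NULL
    list(category_proportions = as.list(fam$proportions),
         de_proportion_by_category = as.list(de_prop),
         enrichment = enrich)
  })

  run("energy", function() {
    sched <- goose_fattening_schedule()
    ctrl <- goose_control_intake()
    list(total_force_fed_g = total_intake(sched),
         total_control_g = ctrl$daily_g * ctrl$days,
         energy_difference_mj = energy_difference(sched, ctrl))
  })

  report$config <- config[setdiff(names(unclass(config)), c("sim", "out_dir"))]
  class(report) <- "lncflux_report"
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir))
      dir.create(config$out_dir, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' @export
print.lncflux_report <- function(x, ...) {
  cat(sprintf("lncflux pipeline report (schema %s, seed %d)\n",
              x$schema_version, x$seed))
  s <- x$stages
  if (!is.null(s$simulate))
    cat(sprintf("  simulate:  %d genes, %d planted lncRNAs, %d candidates\n",
                s$simulate$n_genes, s$simulate$n_planted_lncrna,
                s$simulate$n_candidates))
  if (!is.null(s$discover))
    cat(sprintf("  discover:  %d candidates -> %d lncRNAs\n",
                s$discover$input_count, s$discover$n_lncrna))
  if (!is.null(s$classify))
    cat(sprintf("  classify:  %s; %d cis candidates\n",
                paste(sprintf("%s=%d", names(s$classify$category_counts),
                              unlist(s$classify$category_counts)),
                      collapse = ", "),
                s$classify$n_cis_candidates))
  if (!is.null(s$de)) {
    for (t in names(s$de$mrna))
      cat(sprintf("  de (%s): %d/%d mRNA DE (%.2f%%)\n", t,
                  s$de$mrna[[t]]$n_de, s$de$mrna[[t]]$n_expressed,
                  s$de$mrna[[t]]$percent_de))
  }
  if (!is.null(s$pairs))
    cat(sprintf("  pairs:     %d correlated, %d cis-correlated\n",
                s$pairs$n_correlated_pairs, s$pairs$n_cis_correlated))
  if (!is.null(s$energy))
    cat(sprintf("  energy:    %.2f MJ intake difference\n",
                s$energy$energy_difference_mj))
  invisible(x)
}
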
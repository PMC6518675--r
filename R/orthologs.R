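#' Gene-set enrichment among DE genes by contingency chi-square
#'
#' Builds the 2x2 table (in-set / not-in-set) x (DE / not-DE) over an
#' explicit universe and applies Pearson's chi-square test (without Yates
#' continuity correction by default). The odds ratio uses a 0.5 continuity
#' adjustment only when the table has a zero cell, flagged in the result.
#' An expected cell below 5 triggers a warning recommending an exact test.
#'
#' @param gene_set,de_set character vectors, both subsets of `universe`.
#' @param universe non-empty character vector of all eligible features.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return object of class `contingency_result`: `table` (2x2 counts),
#'   `chi_square`, `p_value`, `odds_ratio`, `odds_continuity` (logical),
#'   `expected`.
#' @export
contingency_enrichment <- function(gene_set, de_set, universe,
                                   correct = FALSE) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stopf("universe must be non-empty")
  gene_set <- unique(as.character(gene_set))
  de_set <- unique(as.character(de_set))
  if (!all(gene_set %in% universe)) stopf("gene_set must be a subset of universe")
  if (!all(de_set %in% universe)) stopf("de_set must be a subset of universe")
  in_set <- universe %in% gene_set
  is_de <- universe %in% de_set
  tab <- matrix(c(sum(in_set & is_de), sum(in_set & !is_de),
                  sum(!in_set & is_de), sum(!in_set & !is_de)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(set = c("in_set", "not_in_set"),
                                de = c("de", "not_de")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    stopf("degenerate margin: a row or column of the 2x2 table is empty")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5))
    warnf("an expected cell count is below 5; consider an exact test")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  odds_continuity <- any(tab == 0L)
  otab <- if (odds_continuity) tab + 0.5 else tab
  odds_ratio <- (otab[1L, 1L] * otab[2L, 2L]) / (otab[1L, 2L] * otab[2L, 1L])
  structure(list(table = tab, chi_square = unname(ct$statistic),
                 p_value = ct$p.value, odds_ratio = odds_ratio,
                 odds_continuity = odds_continuity, expected = expected),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("contingency_result (Pearson chi-square)\n")
  print(x$table)
  cat(sprintf("  chi-square = %.4g, p = %.3g, odds ratio = %.3g%s\n",
              x$chi_square, x$p_value, x$odds_ratio,
              if (x$odds_continuity) " (0.5 continuity)" else ""))
  invisible(x)
}

#' Keep the longest-CDS transcript per gene
#'
#' One transcript per gene (longest `cds_length`, ties resolved by
#' lexicographically smaller `transcript_id`), then drop transcripts
#' coding for fewer than `min_peptide` amino acids (strict: 49 aa is
#' dropped, 50 aa is kept).
#'
#' @param records data frame with columns `gene_id`, `transcript_id`,
#'   `cds_length`, `peptide_length`.
#' @param min_peptide minimum peptide length in amino acids (default 50).
#' @return filtered data frame, one row per surviving gene.
#' @export
select_longest_cds <- function(records, min_peptide = 50) {
  required <- c("gene_id", "transcript_id", "cds_length", "peptide_length")
  if (!all(required %in% names(records)))
    stopf("records must have columns %s", paste(required, collapse = ", "))
  records <- records[order(records$gene_id, -records$cds_length,
                           records$transcript_id), ]
  best <- records[!duplicated(records$gene_id), ]
  best <- best[best$peptide_length >= min_peptide, ]
  rownames(best) <- NULL
  best
}

family_category_one <- function(f, r) {
  if (f < 0 || r < 0) stopf("copy counts must be >= 0")
  if (f == 0 && r == 0) stopf("family absent from both species")
  if (f == 1 && r == 1) "one_to_one"
  else if (r == 0) "focal_specific"
  else if (f == 0) "reference_specific"
  else if (f > r) "expansion"
  else if (f < r) "contraction"
  else "many_to_many"
}

family_categories <- c("one_to_one", "expansion", "contraction",
                       "many_to_many", "focal_specific", "reference_specific")

#' Categorize orthologous gene families by copy number
#'
#' Assigns each family a category from the focal/reference copy-count
#' pair: `(1,1)` one-to-one; more focal copies than reference, expansion;
#' fewer, contraction; equal multi-copy counts, many-to-many; reference
#' count zero, focal-specific; focal count zero, reference-specific.
#' Proportions are reported over the families containing the focal
#' species.
#'
#' @param table long-format data frame with columns `family_id`,
#'   `species`, `gene_id` (one row per gene copy), or a pre-counted data
#'   frame with columns `family_id`, plus one count column named per
#'   species.
#' @param focal,reference species labels.
#' @return list with `records` (data frame: `family_id`, `n_focal`,
#'   `n_reference`, `category`) and `proportions` (named over the
#'   focal-containing categories, summing to 1).
#' @export
categorize_families <- function(table, focal, reference) {
  if (all(c("family_id", "species", "gene_id") %in% names(table))) {
    fams <- unique(table$family_id)
    n_focal <- vapply(fams, function(f)
      sum(table$family_id == f & table$species == focal), integer(1))
    n_reference <- vapply(fams, function(f)
      sum(table$family_id == f & table$species == reference), integer(1))
  } else if (all(c("family_id", focal, reference) %in% names(table))) {
    fams <- table$family_id
    n_focal <- as.integer(table[[focal]])
    n_reference <- as.integer(table[[reference]])
  } else {
    stopf("table must be long (family_id, species, gene_id) or counts (family_id, %s, %s)",
          focal, reference)
  }
  category <- vapply(seq_along(fams), function(i)
    family_category_one(n_focal[i], n_reference[i]), character(1))
  records <- data.frame(family_id = as.character(fams), n_focal = n_focal,
                        n_reference = n_reference, category = category,
                        stringsAsFactors = FALSE)
  with_focal <- records[records$n_focal > 0L, ]
  focal_cats <- setdiff(family_categories, "reference_specific")
  counts <- vapply(focal_cats, function(cc) sum(with_focal$category == cc),
                   integer(1))
  proportions <- if (nrow(with_focal) > 0L) counts / nrow(with_focal) else
    stats::setNames(rep(NA_real_, length(focal_cats)), focal_cats)
  list(records = records, proportions = proportions)
}

#' DE proportion within each family category
#'
#' For each orthology category, the fraction of focal-species genes that
#' are differentially expressed; the denominator is the number of focal
#' genes mapped to families of that category. A category with no focal
#' genes reports `NA` (undefined), not 0.
#'
#' @param records `records` data frame from [categorize_families()].
#' @param de_set character vector of DE focal gene ids.
#' @param focal_gene_map data frame with columns `gene_id`, `family_id`
#'   mapping focal genes to families.
#' @return named numeric vector over all categories.
#' @export
de_proportion_by_category <- function(records, de_set, focal_gene_map) {
  if (!all(c("gene_id", "family_id") %in% names(focal_gene_map)))
    stopf("focal_gene_map must have columns gene_id, family_id")
  cat_of <- stats::setNames(records$category, records$family_id)
  gene_cat <- cat_of[as.character(focal_gene_map$family_id)]
  is_de <- focal_gene_map$gene_id %in% de_set
  out <- stats::setNames(rep(NA_real_, length(family_categories)),
                         family_categories)
  for (cc in family_categories) {
    idx <- which(gene_cat == cc)
    if (length(idx) > 0L) out[[cc]] <- mean(is_de[idx])
  }
  out
}
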
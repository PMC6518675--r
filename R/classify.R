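## Positional classification of putative lncRNAs relative to protein-coding
## genes. Distances are genomic-span gaps (bases strictly between the two
## spans; 0 for overlapping or abutting spans), and the sign convention is
## gene-strand-relative: negative when the lncRNA lies downstream of the
## gene's 3' end, positive when upstream of its 5' end.

## gap and side of span B relative to span A; side is "left"/"right"/"overlap"
span_gap <- function(a_start, a_end, b_start, b_end) {
  if (b_start > a_end) list(gap = b_start - a_end - 1L, side = "right")
  else if (b_end < a_start) list(gap = a_start - b_end - 1L, side = "left")
  else list(gap = 0L, side = "overlap")
}

## signed distance under the gene-strand convention
signed_gap <- function(gap, side, gene_strand) {
  if (side == "overlap") return(0L)
  downstream <- (gene_strand == "+" && side == "right") ||
    (gene_strand == "-" && side == "left")
  if (downstream) -gap else gap
}

#' Nearest protein-coding gene of a lncRNA
#'
#' Finds the gene (by genomic span) minimizing the gap to the lncRNA's
#' span, with ties broken by the lexicographically smaller `gene_id`. The
#' returned distance is 0 for overlap and otherwise signed relative to the
#' gene's strand: negative downstream of the gene's 3' end, positive
#' upstream of its 5' end (a lncRNA 5700 bp past the 3' end of a
#' plus-strand gene reports -5700).
#'
#' @param lnc one-transcript [annotation_set()] (or a transcript id with
#'   `lncs` supplied).
#' @param genes protein-coding gene [annotation_set()] (or a data frame
#'   from [gene_spans()]).
#' @param lncs optional [annotation_set()] resolving `lnc` ids.
#' @return list with `gene_id`, `signed_distance`, `gap`, `side`,
#'   `overlap`. With no gene on the lncRNA's chromosome, `gene_id` is `NA`
#'   and distances are `NA` (callers fall back to an intergenic label).
#' @export
nearest_gene <- function(lnc, genes, lncs = NULL) {
  if (is.character(lnc) && length(lnc) == 1L) {
    if (is.null(lncs)) stopf("supply `lncs` to resolve an id")
    lnc <- subset_transcripts(lncs, lnc)
  }
  lsp <- transcript_spans(lnc)
  if (nrow(lsp) != 1L) stopf("lnc must contain exactly one transcript")
  gsp <- if (inherits(genes, "annotation_set")) gene_spans(genes) else genes
  gsp <- gsp[gsp$chrom == lsp$chrom, , drop = FALSE]
  if (nrow(gsp) == 0L) {
    return(list(gene_id = NA_character_, signed_distance = NA_integer_,
                gap = NA_integer_, side = NA_character_, overlap = FALSE))
  }
  best <- NULL
  for (i in seq_len(nrow(gsp))) {
    sg <- span_gap(gsp$start[i], gsp$end[i], lsp$start, lsp$end)
    cand <- list(gene_id = gsp$gene_id[i], gap = sg$gap, side = sg$side,
                 strand = gsp$strand[i])
    if (is.null(best) || cand$gap < best$gap ||
        (cand$gap == best$gap && cand$gene_id < best$gene_id))
      best <- cand
  }
  list(gene_id = best$gene_id,
       signed_distance = signed_gap(best$gap, best$side, best$strand),
       gap = best$gap, side = best$side, overlap = best$side == "overlap")
}

## orientation class for an opposite-strand, non-overlapping pair given the
## lncRNA's side of the gene: facing ends are 3'-3' when the lncRNA sits on
## the gene's 3' side (convergent) and 5'-5' on its 5' side (divergent).
opposite_orientation <- function(gene_strand, side) {
  three_prime_side <- if (gene_strand == "+") "right" else "left"
  if (side == three_prime_side) "convergent" else "divergent"
}

#' Positionally classify one lncRNA
#'
#' Assigns one of the five positional categories relative to the nearest
#' protein-coding gene:
#' \itemize{
#'   \item same strand, overlapping -> `sense_genic`;
#'   \item same strand, non-overlapping -> `sense_intergenic`;
#'   \item opposite strand, non-overlapping, 3' ends facing within the
#'     orientation window -> `convergent`;
#'   \item opposite strand, non-overlapping, 5' ends facing within the
#'     window -> `divergent`;
#'   \item opposite strand beyond the window -> `antisense_intergenic`.
#' }
#' An opposite-strand *overlapping* lncRNA (the taxonomy has no antisense
#' genic class) is resolved by the same orientation rule evaluated on the
#' relative positions of the two midpoints, with the overlap flagged in the
#' result. A lncRNA on a chromosome without genes falls back to
#' `sense_intergenic` with a warning.
#'
#' @param lnc one-transcript [annotation_set()] (or an id with `lncs`).
#' @param genes gene [annotation_set()] or [gene_spans()] data frame.
#' @param orientation_window bp within which facing opposite-strand
#'   lncRNAs count as convergent/divergent rather than
#'   `antisense_intergenic` (default 10000).
#' @param lncs optional [annotation_set()] resolving ids.
#' @return one-row data frame: `transcript_id`, `category`,
#'   `nearest_gene_id`, `signed_distance`, `overlap`.
#' @export
classify_lncrna <- function(lnc, genes, orientation_window = 10000,
                            lncs = NULL) {
  if (is.character(lnc) && length(lnc) == 1L) {
    if (is.null(lncs)) stopf("supply `lncs` to resolve an id")
    lnc <- subset_transcripts(lncs, lnc)
  }
  lsp <- transcript_spans(lnc)
  if (nrow(lsp) != 1L) stopf("lnc must contain exactly one transcript")
  if (!lsp$strand %in% c("+", "-"))
    stopf("lncRNA '%s' has unknown strand; remove upstream", lsp$transcript_id)
  ng <- nearest_gene(lnc, genes)
  if (is.na(ng$gene_id)) {
    warnf("no gene on chromosome %s; '%s' labelled sense_intergenic by fallback",
          lsp$chrom, lsp$transcript_id)
    return(data.frame(transcript_id = lsp$transcript_id,
                      category = "sense_intergenic",
                      nearest_gene_id = NA_character_,
                      signed_distance = NA_integer_, overlap = FALSE,
                      stringsAsFactors = FALSE))
  }
  gsp <- if (inherits(genes, "annotation_set")) gene_spans(genes) else genes
  g <- gsp[gsp$gene_id == ng$gene_id, ]
  same_strand <- g$strand == lsp$strand
  if (same_strand) {
    category <- if (ng$overlap) "sense_genic" else "sense_intergenic"
  } else if (!ng$overlap) {
    orient <- opposite_orientation(g$strand, ng$side)
    category <- if (ng$gap <= orientation_window) orient else
      "antisense_intergenic"
  } else {
    ## overlap on the opposite strand: orientation from midpoint order,
    ## ties resolved toward the 3' side (convergent)
    g_mid <- (g$start + g$end) / 2
    l_mid <- (lsp$start + lsp$end) / 2
    side <- if (l_mid > g_mid) "right" else if (l_mid < g_mid) "left" else
      if (g$strand == "+") "right" else "left"
    category <- opposite_orientation(g$strand, side)
  }
  data.frame(transcript_id = lsp$transcript_id, category = category,
             nearest_gene_id = ng$gene_id,
             signed_distance = ng$signed_distance, overlap = ng$overlap,
             stringsAsFactors = FALSE)
}

#' Classify a full set of lncRNAs
#'
#' Vectorized wrapper around [classify_lncrna()]; additionally marks each
#' record as a cis candidate when the absolute distance to its nearest
#' gene is within the cis window.
#'
#' @param lncs lncRNA [annotation_set()].
#' @param genes gene [annotation_set()].
#' @param orientation_window see [classify_lncrna()].
#' @param cis_window bp window for the `cis_candidate` flag (default
#'   10000, boundary inclusive).
#' @return data frame with one row per lncRNA transcript: `transcript_id`,
#'   `category`, `nearest_gene_id`, `signed_distance`, `overlap`,
#'   `cis_candidate`.
#' @export
classify_lncrnas <- function(lncs, genes, orientation_window = 10000,
                             cis_window = 10000) {
  gsp <- gene_spans(genes)
  sp <- transcript_spans(lncs)
  res <- do.call(rbind, lapply(sp$transcript_id, function(tx)
    classify_lncrna(subset_transcripts(lncs, tx), gsp,
                    orientation_window = orientation_window)))
  res$cis_candidate <- !is.na(res$signed_distance) &
    abs(res$signed_distance) <= cis_window
  res
}

#' All cis-proximal (lncRNA, gene) pairs
#'
#' Returns every pair whose span gap is within the window (inclusive), not
#' only nearest-gene pairs; a lncRNA flanked by two genes within 10 kb
#' yields two pairs. Distances are signed by each gene's strand as in
#' [nearest_gene()].
#'
#' @param lncs lncRNA [annotation_set()].
#' @param genes gene [annotation_set()].
#' @param window bp window, inclusive (default 10000); must be >= 0.
#' @return data frame `lncrna_id`, `gene_id`, `signed_distance`.
#' @export
cis_candidates <- function(lncs, genes, window = 10000) {
  if (!is.numeric(window) || length(window) != 1L || window < 0)
    stopf("window must be a single non-negative number")
  gsp <- gene_spans(genes)
  lsp <- transcript_spans(lncs)
  rows <- list()
  for (i in seq_len(nrow(lsp))) {
    g <- gsp[gsp$chrom == lsp$chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(g))) {
      sg <- span_gap(g$start[j], g$end[j], lsp$start[i], lsp$end[i])
      if (sg$gap <= window) {
        rows[[length(rows) + 1L]] <- data.frame(
          lncrna_id = lsp$transcript_id[i], gene_id = g$gene_id[j],
          signed_distance = signed_gap(sg$gap, sg$side, g$strand[j]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      signed_distance = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
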
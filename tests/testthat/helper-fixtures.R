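## Shared fixtures and independent oracles. Oracles deliberately use a
## different computational route than the package (base-set interval
## arithmetic, explicit sums, day loops) so agreement is informative.

## build an annotation_set from a list of transcripts:
## list(list(id=, gene=, chrom=, strand=, exons=list(c(s,e), ...)), ...)
make_ann <- function(txs) {
  rows <- do.call(rbind, lapply(txs, function(t) {
    ex <- do.call(rbind, t$exons)
    data.frame(chrom = t$chrom %||% "chr1", start = ex[, 1], end = ex[, 2],
               strand = t$strand, gene_id = t$gene %||% t$id,
               transcript_id = t$id, stringsAsFactors = FALSE)
  }))
  annotation_set(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

one_tx <- function(id, chrom, strand, exons, gene = id) {
  make_ann(list(list(id = id, gene = gene, chrom = chrom, strand = strand,
                     exons = exons)))
}

## ---- class-code oracle: exhaustive base-set comparison -------------------

## introns of an exon matrix as maximal runs of the base-set complement
intron_runs <- function(exons) {
  if (nrow(exons) < 2L) return(list())
  span <- min(exons[, 1]):max(exons[, 2])
  bases <- sort(setdiff(span, unlist(apply(exons, 1L,
                                           function(e) e[1]:e[2],
                                           simplify = FALSE))))
  if (length(bases) == 0L) return(list())
  breaks <- c(0L, which(diff(bases) > 1L), length(bases))
  lapply(seq_len(length(breaks) - 1L), function(i)
    c(bases[breaks[i] + 1L], bases[breaks[i + 1L]]))
}

oracle_class_code <- function(cand_exons, cand_strand, refs) {
  cb <- unlist(apply(cand_exons, 1L, function(e) e[1]:e[2], simplify = FALSE))
  ci <- intron_runs(cand_exons)
  saw_same <- FALSE
  saw_opp <- FALSE
  best <- NULL
  for (r in refs) {
    rb <- unlist(apply(r$exons, 1L, function(e) e[1]:e[2], simplify = FALSE))
    if (length(intersect(cb, rb)) == 0L) next
    if (r$strand != cand_strand) {
      saw_opp <- TRUE
      next
    }
    saw_same <- TRUE
    ri <- intron_runs(r$exons)
    if (length(ci) == length(ri) &&
        (length(ci) == 0L || all(mapply(function(a, b) all(a == b), ci, ri)))) {
      if (is.null(best) || best != "=") best <- "="
      next
    }
    contained <- all(cb %in% rb)
    introns_ok <- all(vapply(ci, function(ii)
      any(vapply(ri, function(jj) all(ii == jj), logical(1))), logical(1)))
    if (contained && introns_ok && !identical(best, "=")) best <- "c"
  }
  if (!is.null(best)) return(best)
  if (saw_same) return("o")
  if (saw_opp) return("x")
  "u"
}

## ---- positional classification oracle: pure-geometry pairwise scan -------

oracle_classify <- function(l_start, l_end, l_strand, genes,
                            orientation_window = 10000) {
  gaps <- pmax(0L, pmax(genes$start, l_start) - pmin(genes$end, l_end) - 1L)
  ord <- order(gaps, genes$gene_id)
  g <- genes[ord[1L], ]
  gap <- gaps[ord[1L]]
  overlap <- l_start <= g$end && g$start <= l_end
  three_prime_right <- g$strand == "+"
  if (overlap) {
    signed <- 0L
    if (g$strand == l_strand) {
      category <- "sense_genic"
    } else {
      l_mid <- (l_start + l_end) / 2
      g_mid <- (g$start + g$end) / 2
      lnc_right <- if (l_mid == g_mid) three_prime_right else l_mid > g_mid
      category <- if (lnc_right == three_prime_right) "convergent" else
        "divergent"
    }
  } else {
    lnc_right <- l_start > g$end
    downstream <- lnc_right == three_prime_right
    signed <- if (downstream) -gap else gap
    if (g$strand == l_strand) {
      category <- "sense_intergenic"
    } else if (gap > orientation_window) {
      category <- "antisense_intergenic"
    } else {
      category <- if (downstream) "convergent" else "divergent"
    }
  }
  list(category = category, gene_id = g$gene_id, signed_distance = signed)
}

## random gene layout + lncRNA placement on a toy chromosome
random_placement <- function() {
  n_genes <- sample(2:6, 1L)
  starts <- sort(sample(seq(1000L, 200000L, by = 500L), n_genes))
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n_genes)),
                      chrom = "chr1", start = starts,
                      end = starts + sample(1000:5000, n_genes, replace = TRUE),
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)
  l_start <- sample(1:220000, 1L)
  l_len <- sample(500:3000, 1L)
  list(genes = genes, l_start = l_start, l_end = l_start + l_len,
       l_strand = sample(c("+", "-"), 1L))
}

## ---- statistical oracles --------------------------------------------------

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}

oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

oracle_orf_score <- function(s) {
  s <- toupper(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (f in 0:2) {
    shifted <- substring(s, f + 1L)
    codons <- regmatches(shifted, gregexpr("...", shifted))[[1L]]
    n <- length(codons)
    i <- 1L
    while (i <= n) {
      if (codons[i] == "ATG") {
        j <- i + 1L
        while (j <= n && !codons[j] %in% stops) j <- j + 1L
        best <- max(best, j - i)  # ATG..last sense codon, stop excluded
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  best / 100
}

## small deterministic expression matrix builder
make_expr <- function(values, tissues, treatments, reps = NULL) {
  ns <- ncol(values)
  if (is.null(reps)) reps <- seq_len(ns)
  meta <- data.frame(sample_id = paste0("s", seq_len(ns)), tissue = tissues,
                     treatment = treatments, replicate = reps,
                     stringsAsFactors = FALSE)
  colnames(values) <- meta$sample_id
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  expression_matrix(values, meta)
}

## the 6-candidate hand fixture for the cascade accounting test:
## one removal per stage plus an 'x' and a 'u' survivor
hand_cascade_fixture <- function() {
  reference <- one_tx("ref1", "chr1", "+",
                      list(c(1001L, 1600L), c(5401L, 6000L)), gene = "gene1")
  candidates <- make_ann(list(
    list(id = "F1_eq", strand = "+",      # identical intron chain -> '='
         exons = list(c(951L, 1600L), c(5401L, 6050L))),
    list(id = "F2_short", strand = "+",   # spliced length 150 < 200
         exons = list(c(20001L, 20080L), c(20501L, 20570L))),
    list(id = "F3_coding", strand = "+",  # external score 1.5 > 1
         exons = list(c(30001L, 30300L), c(31001L, 31300L))),
    list(id = "F4_mono", strand = "+",    # single exon
         exons = list(c(40001L, 40500L))),
    list(id = "F5_x", strand = "-",       # opposite-strand overlap, survives
         exons = list(c(1201L, 1500L), c(2001L, 2300L))),
    list(id = "F6_u", strand = "+",       # no overlap, survives
         exons = list(c(50001L, 50300L), c(51001L, 51300L)))))
  scores <- data.frame(
    transcript_id = c("F3_coding", "F4_mono", "F5_x", "F6_u"),
    score = c(1.5, 0.3, 0.5, 0.1), stringsAsFactors = FALSE)
  list(reference = reference, candidates = candidates, scores = scores)
}
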
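#' Exon-level annotation sets
#'
#' An `annotation_set` is the package's container for stranded,
#' exon-structured transcript models: a data frame with one row per exon
#' and columns `chrom`, `start`, `end` (1-based, closed), `strand`
#' (`"+"`, `"-"`, or `"."` for unknown), `gene_id`, `transcript_id`, and
#' `biotype`. It is the unit flowing through the discovery cascade and the
#' positional classifier.
#'
#' @param exons data frame with the columns listed above (`biotype`
#'   optional, defaults to `"transcript"`).
#' @return An object of class `annotation_set`.
#' @examples
#' ann <- annotation_set(data.frame(
#'   chrom = "chr1", start = c(100, 700), end = c(300, 900),
#'   strand = "+", gene_id = "G1", transcript_id = "G1.t1"))
#' transcript_spans(ann)
#' @export
annotation_set <- function(exons) {
  required <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  missing <- setdiff(required, names(exons))
  if (length(missing) > 0L)
    stopf("annotation is missing column(s): %s", paste(missing, collapse = ", "))
  if (!"biotype" %in% names(exons)) exons$biotype <- "transcript"
  exons <- exons[, c(required, "biotype")]
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  exons$gene_id <- as.character(exons$gene_id)
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$biotype <- as.character(exons$biotype)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(is.na(exons$start)) || any(is.na(exons$end)))
    stopf("exon coordinates must be finite integers")
  if (any(exons$end < exons$start))
    stopf("exon end < start for transcript(s): %s",
          paste(unique(exons$transcript_id[exons$end < exons$start]), collapse = ", "))
  if (!all(exons$strand %in% c("+", "-", ".")))
    stopf("strand must be '+', '-' or '.'")
  ## sort exons within transcript; reject overlapping exons
  exons <- exons[order(exons$transcript_id, exons$start, exons$end), ]
  rownames(exons) <- NULL
  for (tx in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tx, ]
    if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)]))
      stopf("transcript %s has overlapping exons", tx)
    if (length(unique(e$strand)) != 1L || length(unique(e$chrom)) != 1L)
      stopf("transcript %s mixes strands or chromosomes", tx)
  }
  structure(exons, class = c("annotation_set", "data.frame"))
}

#' @export
print.annotation_set <- function(x, ...) {
  sp <- transcript_spans(x)
  cat(sprintf("annotation_set: %d transcripts (%d genes) on %d chromosome(s), %d exon rows\n",
              nrow(sp), length(unique(sp$gene_id)),
              length(unique(sp$chrom)), nrow(as.data.frame(x))))
  invisible(x)
}

#' Summarise transcripts of an annotation set
#'
#' Collapses an exon-level [annotation_set()] to one row per transcript with
#' its genomic span, exon count and spliced (summed-exon) length.
#'
#' @param ann an [annotation_set()].
#' @return data frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `n_exons`, `spliced_length`, `biotype`.
#' @export
transcript_spans <- function(ann) {
  ex <- as.data.frame(ann)
  ids <- unique(ex$transcript_id)
  if (length(ids) == 0L) {
    return(data.frame(transcript_id = character(0), gene_id = character(0),
                      chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      n_exons = integer(0), spliced_length = integer(0),
                      biotype = character(0), stringsAsFactors = FALSE))
  }
  idx <- split(seq_len(nrow(ex)), ex$transcript_id)[ids]
  res <- do.call(rbind, lapply(ids, function(tx) {
    e <- ex[idx[[tx]], ]
    data.frame(transcript_id = tx, gene_id = e$gene_id[1L],
               chrom = e$chrom[1L], strand = e$strand[1L],
               start = min(e$start), end = max(e$end),
               n_exons = nrow(e), spliced_length = sum(e$end - e$start + 1L),
               biotype = e$biotype[1L], stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Summarise genes of an annotation set
#'
#' One row per gene with the union span over its transcripts.
#' @param ann an [annotation_set()].
#' @return data frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `biotype`.
#' @export
gene_spans <- function(ann) {
  sp <- transcript_spans(ann)
  ids <- unique(sp$gene_id)
  if (length(ids) == 0L) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), biotype = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, lapply(ids, function(g) {
    s <- sp[sp$gene_id == g, ]
    data.frame(gene_id = g, chrom = s$chrom[1L], strand = s$strand[1L],
               start = min(s$start), end = max(s$end), biotype = s$biotype[1L],
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

## exon matrix (start,end) for one transcript id
exon_matrix <- function(ann, tx) {
  ex <- as.data.frame(ann)
  e <- ex[ex$transcript_id == tx, , drop = FALSE]
  cbind(e$start, e$end)
}

## intron matrix for an exon matrix sorted by start
intron_matrix <- function(em) {
  if (nrow(em) < 2L) return(matrix(integer(0), ncol = 2L))
  cbind(em[-nrow(em), 2L] + 1L, em[-1L, 1L] - 1L)
}

#' Read a GTF file into an annotation set
#'
#' Uses rtracklayer for parsing; only `exon` records are retained (or all
#' records when the file carries no `type` distinction). Attributes
#' `gene_id`, `transcript_id` and (optionally) `biotype` are kept.
#'
#' @param path path to a GTF file.
#' @return an [annotation_set()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if ("type" %in% names(df) && any(df$type == "exon"))
    df <- df[df$type == "exon", , drop = FALSE]
  if (!"biotype" %in% names(df)) df$biotype <- "transcript"
  annotation_set(data.frame(
    chrom = as.character(df$seqnames), start = df$start, end = df$end,
    strand = as.character(df$strand), gene_id = df$gene_id,
    transcript_id = df$transcript_id, biotype = df$biotype,
    stringsAsFactors = FALSE))
}

#' Write an annotation set as GTF
#'
#' Emits one `transcript` record plus its `exon` records per transcript,
#' 1-based closed coordinates, with `gene_id`, `transcript_id` and
#' `biotype` attributes. The writer is deterministic: identical input
#' yields byte-identical files.
#'
#' @param ann an [annotation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  ex <- as.data.frame(ann)
  sp <- transcript_spans(ann)
  sp <- sp[order(sp$chrom, sp$start, sp$transcript_id), ]
  lines <- character(0)
  for (i in seq_len(nrow(sp))) {
    tx <- sp$transcript_id[i]
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s"; biotype "%s";',
                        sp$gene_id[i], tx, sp$biotype[i])
    lines <- c(lines, paste(sp$chrom[i], "lncflux", "transcript", sp$start[i],
                            sp$end[i], ".", sp$strand[i], ".", attr_str,
                            sep = "\t"))
    e <- ex[ex$transcript_id == tx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      lines <- c(lines, paste(e$chrom[j], "lncflux", "exon", e$start[j],
                              e$end[j], ".", e$strand[j], ".", attr_str,
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Subset an annotation set by transcript id
#' @param ann an [annotation_set()].
#' @param transcript_ids character vector of ids to keep.
#' @return an [annotation_set()] restricted to the requested transcripts.
#' @export
subset_transcripts <- function(ann, transcript_ids) {
  ex <- as.data.frame(ann)
  annotation_set(ex[ex$transcript_id %in% transcript_ids, , drop = FALSE])
}
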
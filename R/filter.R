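#' Structural class code of a candidate transcript
#'
#' Compares one candidate transcript against a reference annotation and
#' assigns the class code the discovery cascade acts on:
#' \describe{
#'   \item{`=`}{some same-strand reference transcript overlaps the
#'     candidate exonically and has an identical intron chain (terminal
#'     exon ends may differ);}
#'   \item{`c`}{the candidate's exons are contained in the exonic union of
#'     a same-strand reference transcript and every candidate intron
#'     matches a reference intron exactly (intron-compatible containment);}
#'   \item{`o`}{other partial same-strand exonic overlap;}
#'   \item{`x`}{exonic overlap with opposite-strand reference transcripts
#'     only;}
#'   \item{`u`}{no exonic overlap with any reference transcript.}
#' }
#'
#' @param candidate an [annotation_set()] holding exactly one transcript,
#'   or a transcript id present in `candidates`.
#' @param reference reference [annotation_set()].
#' @param candidates optional [annotation_set()] to resolve `candidate`
#'   when it is given as an id.
#' @return list with `code` (one of `=`, `c`, `o`, `x`, `u`) and
#'   `matched_reference_id` (non-empty for `=` and `c`).
#' @export
assign_class_code <- function(candidate, reference, candidates = NULL) {
  if (is.character(candidate) && length(candidate) == 1L) {
    if (is.null(candidates)) stopf("supply `candidates` to resolve an id")
    candidate <- subset_transcripts(candidates, candidate)
  }
  csp <- transcript_spans(candidate)
  if (nrow(csp) != 1L) stopf("candidate must contain exactly one transcript")
  cem <- exon_matrix(candidate, csp$transcript_id)
  if (nrow(cem) == 0L) stopf("candidate transcript has zero exons")
  cim <- intron_matrix(cem)
  rsp <- transcript_spans(reference)
  rsp <- rsp[rsp$chrom == csp$chrom, , drop = FALSE]
  contained_in <- character(0)
  same_overlap <- FALSE
  opp_overlap <- FALSE
  for (i in seq_len(nrow(rsp))) {
    ## cheap span test before exon-level work
    if (rsp$end[i] < csp$start || rsp$start[i] > csp$end) next
    rem <- exon_matrix(reference, rsp$transcript_id[i])
    if (!intervals_overlap(cem, rem)) next
    if (csp$strand == rsp$strand[i] && csp$strand %in% c("+", "-")) {
      rim <- intron_matrix(rem)
      if (identical(dim(cim), dim(rim)) && all(cim == rim))
        return(list(code = "=", matched_reference_id = rsp$transcript_id[i]))
      if (intervals_contained(cem, rem) &&
          (nrow(cim) == 0L ||
           all(apply(cim, 1L, function(ii)
             any(rim[, 1L] == ii[1L] & rim[, 2L] == ii[2L])))))
        contained_in <- c(contained_in, rsp$transcript_id[i])
      same_overlap <- TRUE
    } else {
      opp_overlap <- TRUE
    }
  }
  if (length(contained_in) > 0L)
    return(list(code = "c", matched_reference_id = contained_in[1L]))
  if (same_overlap) return(list(code = "o", matched_reference_id = ""))
  if (opp_overlap) return(list(code = "x", matched_reference_id = ""))
  list(code = "u", matched_reference_id = "")
}

#' ORF-length coding-potential score
#'
#' A deliberately simple, deterministic stand-in for database-backed coding
#' potential classifiers: the longest open reading frame (ATG through the
#' codon before the next in-frame stop, or through the sequence end for an
#' open ORF) is found across the three forward frames and its length in
#' codons is divided by 100, so the conventional "score > 1" cutoff
#' corresponds to an ORF of more than 100 codons. Externally computed
#' score tables (see [load_external_scores()]) are the fidelity path and
#' override this heuristic.
#'
#' @param sequence nucleotide string (A/C/G/T, case-insensitive), length
#'   >= 200.
#' @param transcript_id optional id recorded in the result.
#' @return list with `transcript_id`, `score`, `source = "builtin"`.
#' @examples
#' # 150 codons: ATG + 149 sense codons (stop excluded) -> score 1.5
#' orf <- paste0("ATG", strrep("GCC", 149), "TAA")
#' seqn <- paste0(orf, strrep("T", 200))
#' builtin_coding_score(seqn)$score
#' @export
builtin_coding_score <- function(sequence, transcript_id = NA_character_) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stopf("sequence must be a single string")
  sequence <- toupper(sequence)
  if (nchar(sequence) < 200L)
    stopf("sequence shorter than 200 nt; provide an external score table instead")
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (frame in 0:2) {
    n_codons <- (nchar(sequence) - frame) %/% 3L
    if (n_codons < 1L) next
    codons <- substring(sequence, frame + 1L + 3L * (seq_len(n_codons) - 1L),
                        frame + 3L * seq_len(n_codons))
    open <- FALSE
    len <- 0L
    for (cd in codons) {
      if (!open) {
        if (cd == "ATG") {
          open <- TRUE
          len <- 1L
        }
      } else if (cd %in% stops) {
        best <- max(best, len)
        open <- FALSE
        len <- 0L
      } else {
        len <- len + 1L
      }
    }
    if (open) best <- max(best, len)
  }
  list(transcript_id = transcript_id, score = best / 100, source = "builtin")
}

#' Load an external coding-potential score table
#'
#' Reads a two-column TSV (`transcript_id`, `score`; a header row with
#' those names is accepted and skipped). External scores take precedence
#' over the built-in heuristic for the same transcript; duplicated ids
#' resolve last-wins with a warning.
#'
#' @param path TSV file path.
#' @return data frame with columns `transcript_id`, `score`, `source`
#'   (`"external"`).
#' @export
load_external_scores <- function(path) {
  if (!file.exists(path)) stopf("score table not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(transcript_id = character(0), score = numeric(0),
                      source = character(0), stringsAsFactors = FALSE))
  start <- 1L
  first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(first) >= 2L && identical(tolower(first[1:2]),
                                       c("transcript_id", "score")))
    start <- 2L
  ids <- character(0)
  scores <- numeric(0)
  for (i in seq(start, length.out = length(lines) - start + 1L)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L)
      stopf("malformed score row at line %d: expected 2 tab-separated fields", i)
    val <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(val) || !is.finite(val))
      stopf("non-numeric score at line %d: '%s'", i, f[2L])
    ids <- c(ids, f[1L])
    scores <- c(scores, val)
  }
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    warnf("duplicate transcript_id(s) in score table (last wins): %s",
          paste(dups, collapse = ", "))
    keep <- !duplicated(ids, fromLast = TRUE)
    ids <- ids[keep]
    scores <- scores[keep]
  }
  data.frame(transcript_id = ids, score = scores, source = "external",
             stringsAsFactors = FALSE)
}

#' The lncRNA discovery filter cascade
#'
#' Applies, in order: (1) removal of candidates whose class code against
#' the reference is `=` or `c` (unknown-strand candidates are removed here
#' too, under their own counter); (2) minimum spliced length (>= 200 bp);
#' (3) coding-potential score (drop score > 1, external scores overriding
#' the built-in ORF heuristic); (4) minimum exon count (drop mono-exonic).
#' Each removed candidate is attributed to the first failing stage, so the
#' report's counts plus the survivors account for every input.
#'
#' @param candidates candidate [annotation_set()].
#' @param reference reference [annotation_set()].
#' @param scores optional external score table from
#'   [load_external_scores()] (or any data frame with `transcript_id`,
#'   `score`).
#' @param sequences optional named character vector of spliced transcript
#'   sequences, used for the built-in score where no external score exists.
#'   A candidate reaching the score stage with neither is an error.
#' @param min_length minimum spliced length in bp (default 200).
#' @param max_score maximum retained coding score (default 1; strict >
#'   removes).
#' @param min_exons minimum exon count (default 2).
#' @return list with `lncrna` (surviving [annotation_set()]) and `report`
#'   (a `filter_report`: `input_count`, `removed_by` per-stage counts,
#'   `surviving_ids`, and a per-transcript `details` data frame).
#' @export
filter_candidates <- function(candidates, reference, scores = NULL,
                              sequences = NULL, min_length = 200,
                              max_score = 1, min_exons = 2) {
  sp <- transcript_spans(candidates)
  stages <- c("class_code", "unstranded", "min_length", "coding_score",
              "mono_exonic")
  removed_by <- stats::setNames(integer(length(stages)), stages)
  score_lookup <- if (!is.null(scores))
    stats::setNames(scores$score, scores$transcript_id) else numeric(0)
  n <- nrow(sp)
  status <- character(n)
  class_codes <- character(n)
  score_vals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tx <- sp$transcript_id[i]
    if (sp$strand[i] == ".") {
      status[i] <- "unstranded"
      class_codes[i] <- NA_character_
      next
    }
    cc <- assign_class_code(subset_transcripts(candidates, tx), reference)
    class_codes[i] <- cc$code
    if (cc$code %in% c("=", "c")) {
      status[i] <- "class_code"
      next
    }
    if (sp$spliced_length[i] < min_length) {
      status[i] <- "min_length"
      next
    }
    sc <- if (tx %in% names(score_lookup)) {
      score_lookup[[tx]]
    } else if (!is.null(sequences) && tx %in% names(sequences)) {
      builtin_coding_score(sequences[[tx]], tx)$score
    } else {
      stopf("candidate '%s' has neither a sequence nor an external coding score", tx)
    }
    score_vals[i] <- sc
    if (sc > max_score) {
      status[i] <- "coding_score"
      next
    }
    if (sp$n_exons[i] < min_exons) {
      status[i] <- "mono_exonic"
      next
    }
    status[i] <- "retained"
  }
  for (st in stages) removed_by[[st]] <- sum(status == st)
  surviving <- sp$transcript_id[status == "retained"]
  details <- data.frame(transcript_id = sp$transcript_id,
                        class_code = class_codes,
                        spliced_length = sp$spliced_length,
                        n_exons = sp$n_exons, coding_score = score_vals,
                        status = status, stringsAsFactors = FALSE)
  report <- structure(list(input_count = n, removed_by = removed_by,
                           surviving_ids = surviving, details = details),
                      class = "filter_report")
  lnc <- if (length(surviving)) subset_transcripts(candidates, surviving) else
    annotation_set(as.data.frame(candidates)[0, ])
  list(lncrna = lnc, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d candidates -> %d putative lncRNAs\n",
              x$input_count, length(x$surviving_ids)))
  for (st in names(x$removed_by))
    cat(sprintf("  removed at %-13s %d\n", paste0(st, ":"), x$removed_by[[st]]))
  invisible(x)
}
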
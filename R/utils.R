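## Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded generators do not
#' disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Round half away from zero at `digits` decimals
#'
#' Printed percentages use conventional half-up rounding, not the IEEE
#' round-half-even of base round().
#' @noRd
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x)

## Merge a set of closed integer intervals (two-column matrix start,end)
## into a disjoint sorted union. Used by the class-code assigner.
merge_intervals <- function(m) {
  if (nrow(m) == 0L) return(m)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  if (nrow(m) > 1L) {
    for (i in 2L:nrow(m)) {
      k <- nrow(out)
      if (m[i, 1L] <= out[k, 2L] + 1L) {
        out[k, 2L] <- max(out[k, 2L], m[i, 2L])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  out
}

## TRUE if any interval in `a` overlaps any interval in `b` (closed coords).
intervals_overlap <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(FALSE)
  for (i in seq_len(nrow(a))) {
    if (any(a[i, 1L] <= b[, 2L] & a[i, 2L] >= b[, 1L])) return(TRUE)
  }
  FALSE
}

## TRUE if every interval in `a` lies inside the union of intervals in `b`.
intervals_contained <- function(a, b) {
  if (nrow(a) == 0L) return(TRUE)
  u <- merge_intervals(b)
  for (i in seq_len(nrow(a))) {
    if (!any(u[, 1L] <= a[i, 1L] & u[, 2L] >= a[i, 2L])) return(FALSE)
  }
  TRUE
}
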
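#' Homolog screening criteria
#'
#' The acceptance rules for putative PSY homologs: BLAST expect value at
#' most `evalue_max`, full-length precursor between `min_len` and `max_len`
#' residues (both ends inclusive), a motif beginning with Asp-Tyr, and the
#' motif located in the second half of the precursor.
#'
#' @param evalue_max maximum BLAST expect value (ignored when no hit is
#'   supplied).
#' @param min_len,max_len inclusive precursor length bounds in residues.
#' @param require_dy_start re-check that the matched motif starts with
#'   `DY` (relevant for user-supplied patterns; the built-in PSY patterns
#'   are DY-anchored already).
#' @param require_second_half require the motif to start in the second half
#'   of the sequence.
#' @return a `screen_criteria` list.
#' @export
screen_criteria <- function(evalue_max = 20, min_len = 60L, max_len = 200L,
                            require_dy_start = TRUE,
                            require_second_half = TRUE) {
  stopifnot(evalue_max > 0, min_len > 0, min_len <= max_len)
  structure(list(evalue_max = evalue_max, min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 require_dy_start = isTRUE(require_dy_start),
                 require_second_half = isTRUE(require_second_half)),
            class = "screen_criteria")
}

# A motif starting at 1-based position `start` in a sequence of length L is
# "in the second half" iff its 0-based offset is >= ceiling(L/2); for odd
# lengths the motif must start strictly within the latter floor(L/2)
# residues.
in_second_half <- function(start, L) {
  (start - 1L) >= ceiling(L / 2)
}

#' Apply the screening criteria to one candidate
#'
#' Produces a verdict, never an exception: `passed` is `TRUE` iff the
#' failure-code list is empty. Codes: `EVALUE` (hit present with expect
#' value above threshold), `LENGTH` (precursor outside the length window),
#' `NO_MOTIF` (no DY-anchored motif match at all), `MOTIF_FIRST_HALF`
#' (motif matches, but never in the second half). `NO_MOTIF` and
#' `MOTIF_FIRST_HALF` are mutually exclusive.
#'
#' @param record one-row `precursor_set` (or list with `id`, `sequence`).
#' @param matches match table from [scan_motif()] for this record (rows for
#'   other records are ignored).
#' @param hit optional one-row BLAST hit (list or data frame with
#'   `evalue`); `NULL` for pure motif screening, in which case the E-value
#'   criterion is vacuously satisfied.
#' @param criteria a [screen_criteria()].
#' @return a `screen_verdict` list: `record_id`, `passed`, `reasons`,
#'   `motif_start`, `motif_end` (leftmost qualifying match; `NA` when
#'   failing on the motif).
#' @export
apply_criteria <- function(record, matches, hit = NULL,
                           criteria = screen_criteria()) {
  id <- record$id[1]
  L <- nchar(record$sequence[1])
  reasons <- character(0)
  if (!is.null(hit) && is.finite(hit$evalue[1]) &&
      hit$evalue[1] > criteria$evalue_max) {
    reasons <- c(reasons, "EVALUE")
  }
  if (L < criteria$min_len || L > criteria$max_len) {
    reasons <- c(reasons, "LENGTH")
  }
  m <- matches[matches$record_id == id, , drop = FALSE]
  if (criteria$require_dy_start && nrow(m) > 0L) {
    m <- m[substr(m$matched, 1L, 2L) == "DY", , drop = FALSE]
  }
  motif_start <- NA_integer_
  motif_end <- NA_integer_
  if (nrow(m) == 0L) {
    reasons <- c(reasons, "NO_MOTIF")
  } else {
    ok <- if (criteria$require_second_half) {
      in_second_half(m$start, L)
    } else {
      rep(TRUE, nrow(m))
    }
    if (!any(ok)) {
      reasons <- c(reasons, "MOTIF_FIRST_HALF")
    } else {
      i <- which(ok)[which.min(m$start[ok])]
      motif_start <- m$start[i]
      motif_end <- m$end[i]
    }
  }
  structure(list(record_id = id, passed = length(reasons) == 0L,
                 reasons = reasons, motif_start = motif_start,
                 motif_end = motif_end),
            class = "screen_verdict")
}

#' Screen a collection of candidate precursors
#'
#' Scans every record with the given DY-anchored pattern, applies
#' [apply_criteria()], and splits the collection into passing records and a
#' verdict table.
#'
#' @param records a `precursor_set`.
#' @param hits optional BLAST hit table ([read_blast_tab()]); matched to
#'   records by `subject_id == id`. Records without a hit are judged on
#'   sequence criteria only.
#' @param criteria a [screen_criteria()].
#' @param pattern a `motif_pattern` (default: strict PSY motif).
#' @return list with `passing` (subset of `records`) and `verdicts` (data
#'   frame: `record_id`, `passed`, `reasons` as a comma-joined string,
#'   `motif_start`, `motif_end`).
#' @export
screen_collection <- function(records, hits = NULL,
                              criteria = screen_criteria(),
                              pattern = psy_motif_pattern()) {
  if (nrow(records) == 0L) {
    return(list(passing = records,
                verdicts = data.frame(record_id = character(),
                                      passed = logical(),
                                      reasons = character(),
                                      motif_start = integer(),
                                      motif_end = integer(),
                                      stringsAsFactors = FALSE)))
  }
  matches <- scan_motif(records, pattern)
  verdicts <- lapply(seq_len(nrow(records)), function(i) {
    hit <- NULL
    if (!is.null(hits)) {
      h <- hits[hits$subject_id == records$id[i], , drop = FALSE]
      if (nrow(h) > 0L) hit <- h[which.min(h$evalue), , drop = FALSE]
    }
    v <- apply_criteria(records[i, , drop = FALSE], matches, hit, criteria)
    data.frame(record_id = v$record_id, passed = v$passed,
               reasons = paste(v$reasons, collapse = ","),
               motif_start = v$motif_start, motif_end = v$motif_end,
               stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, verdicts)
  passing <- records[verdicts$passed, , drop = FALSE]
  class(passing) <- class(records)
  list(passing = passing, verdicts = verdicts)
}
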
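#' Built-in subtilase recognition motifs
#'
#' Three subtilases implicated in the processing of tyrosine-sulfated
#' peptide precursors:
#' \describe{
#'   \item{SBT1.1}{literal 10-mer `RRSLVLHTDY`; cleaves between positions 6
#'     and 7 of the match (`RRSLVL / HTDY`), three residues upstream of the
#'     mature-peptide N-terminus.}
#'   \item{SBT6.1}{two generalized 4-mers, `RXLX` and `RXXL` (X = any
#'     residue); no cut position is assigned.}
#'   \item{SBT3.8}{the `DY` dipeptide that opens every mature PSY peptide;
#'     as an aspartate-specific phytaspase the cut is reported immediately
#'     N-terminal to the D (`cut_offset = 0`), flagged as a candidate site
#'     rather than an established cleavage.}
#' }
#'
#' @return list of `enzyme_motif` entries: `enzyme`, `pattern`
#'   (a `motif_pattern`), `cut_offset` (1-based position within the match
#'   after which the scissile bond lies; 0 = before the first residue;
#'   `NA` = unknown).
#' @export
builtin_enzyme_motifs <- function() {
  list(
    list(enzyme = "SBT1.1",
         pattern = parse_pattern("RRSLVLHTDY", name = "SBT1.1"),
         cut_offset = 6L),
    list(enzyme = "SBT6.1",
         pattern = parse_pattern("RXLX", name = "SBT6.1/RXLX"),
         cut_offset = NA_integer_),
    list(enzyme = "SBT6.1",
         pattern = parse_pattern("RXXL", name = "SBT6.1/RXXL"),
         cut_offset = NA_integer_),
    list(enzyme = "SBT3.8",
         pattern = parse_pattern("DY", name = "SBT3.8"),
         cut_offset = 0L)
  )
}

#' Annotate a precursor with subtilase recognition motifs
#'
#' Scans every built-in enzyme motif ([builtin_enzyme_motifs()]) across the
#' sequence; overlapping hits are all reported, ordered by (start, enzyme,
#' pattern). `cut_after` is the 1-based sequence position after which the
#' scissile bond lies (0 = before position 1), `NA` when unknown. DY hits
#' are candidate phytaspase sites, not asserted cleavages.
#'
#' @param record one-row `precursor_set` or a sequence string.
#' @param motifs enzyme motif list (default built-ins).
#' @param mask_signal optional integer vector `c(from, to)` (1-based span
#'   of an annotated signal peptide); hits overlapping the span are
#'   dropped.
#' @return data frame `record_id`, `enzyme`, `pattern`, `start`, `end`,
#'   `matched`, `cut_after`.
#' @export
annotate_cleavage <- function(record, motifs = builtin_enzyme_motifs(),
                              mask_signal = NULL) {
  if (is.character(record)) record <- precursor_records("query", record)
  id <- record$id[1]
  seq <- record$sequence[1]
  rows <- lapply(motifs, function(mo) {
    starts <- scan_one(seq, mo$pattern)
    if (length(starts) == 0L) return(NULL)
    k <- mo$pattern$length
    data.frame(record_id = id, enzyme = mo$enzyme,
               pattern = render_pattern(mo$pattern),
               start = starts, end = starts + k - 1L,
               matched = substring(seq, starts, starts + k - 1L),
               cut_after = if (is.na(mo$cut_offset)) NA_integer_
                           else starts + mo$cut_offset - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(record_id = character(), enzyme = character(),
                      pattern = character(), start = integer(),
                      end = integer(), matched = character(),
                      cut_after = integer(), stringsAsFactors = FALSE)
  }
  if (!is.null(mask_signal) && nrow(out) > 0L) {
    stopifnot(length(mask_signal) == 2L)
    keep <- out$end < mask_signal[1] | out$start > mask_signal[2]
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$start, out$enzyme, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-enzyme motif-presence report over a collection
#'
#' The cross-homolog summary: for each enzyme, which records carry at least
#' one recognition-motif hit.
#'
#' @param records a `precursor_set`.
#' @param motifs enzyme motif list (default built-ins).
#' @param mask_signal optional named list of `c(from, to)` spans per
#'   record id, passed through to [annotate_cleavage()].
#' @return list with `membership` (named list: enzyme -> character vector
#'   of record ids) and `summary` (data frame `enzyme`, `n_with_motif`,
#'   `ids`).
#' @export
table3_report <- function(records, motifs = builtin_enzyme_motifs(),
                          mask_signal = NULL) {
  enzymes <- unique(vapply(motifs, `[[`, character(1), "enzyme"))
  hits <- lapply(seq_len(nrow(records)), function(i) {
    annotate_cleavage(records[i, , drop = FALSE], motifs,
                      mask_signal = mask_signal[[records$id[i]]])
  })
  hits <- do.call(rbind, c(hits, list(annotate_cleavage("G")[0, ])))
  membership <- lapply(enzymes, function(e) {
    ids <- unique(hits$record_id[hits$enzyme == e])
    records$id[records$id %in% ids]    # manifest order, deterministic
  })
  names(membership) <- enzymes
  summary <- data.frame(enzyme = enzymes,
                        n_with_motif = vapply(membership, length, integer(1)),
                        ids = vapply(membership, paste, character(1),
                                     collapse = ","),
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(membership = membership, summary = summary)
}
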
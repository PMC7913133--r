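#' Global alignment parameters
#'
#' Defaults match the EMBOSS needle settings used for the PSY similarity
#' table: BLOSUM62, gap opening 10, gap extension 0.5, end gaps free.
#'
#' @param matrix_name substitution matrix name; see [score_matrix()].
#' @param gap_open gap opening penalty (positive).
#' @param gap_extend gap extension penalty per gap column (positive); a gap
#'   of length L costs `gap_open + L * gap_extend`.
#' @param penalize_end_gaps charge leading/trailing gaps (EMBOSS
#'   `endweight`); `FALSE` by default as in the needle web service.
#' @return an `align_params` list (with the resolved scoring matrix).
#' @export
align_params <- function(matrix_name = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5, penalize_end_gaps = FALSE) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 0)
  structure(list(matrix_name = matrix_name,
                 matrix = score_matrix(matrix_name),
                 gap_open = gap_open, gap_extend = gap_extend,
                 penalize_end_gaps = isTRUE(penalize_end_gaps)),
            class = "align_params")
}

#' Load a protein substitution matrix
#'
#' Matrices are shipped as NCBI-format text files under
#' `inst/extdata/` (currently BLOSUM62, the standard NCBI half-bit
#' matrix including the B/Z/X/* extra letters).
#'
#' @param name matrix name, e.g. `"BLOSUM62"`.
#' @return numeric matrix with residue dimnames.
#' @export
score_matrix <- function(name = "BLOSUM62") {
  dir <- system.file("extdata", package = "psykit")
  avail <- sub("\\.txt$", "", basename(Sys.glob(file.path(dir, "*.txt"))))
  avail <- setdiff(avail, character(0))
  path <- file.path(dir, paste0(name, ".txt"))
  if (!file.exists(path)) {
    stop("unknown scoring matrix '", name, "'; available: ",
         paste(avail, collapse = ", "))
  }
  read_score_matrix(path)
}

#' Read an NCBI-format scoring matrix file
#'
#' @param path text file: `#` comment lines, a header row of residue
#'   letters, then one labelled row per residue.
#' @return numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(cols))))
  dimnames(m) <- list(vapply(rows, `[`, character(1), 1L), cols)
  if (!identical(rownames(m), colnames(m)) || any(is.na(m))) {
    stop("malformed scoring matrix file: ", path)
  }
  m
}

# Round half away from zero (reporting convention for the similarity
# table); base round() rounds half to even.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Needleman-Wunsch global alignment with affine gaps
#'
#' Optimal global alignment under the three-state (Gotoh) affine-gap model
#' with deterministic traceback, plus EMBOSS-needle-compatible summary
#' percentages: identity and similarity both use the full alignment length
#' (gap columns included) as denominator, and a column counts as similar
#' when its substitution score is positive.
#'
#' @param a,b amino-acid sequence strings (non-empty).
#' @param params an [align_params()].
#' @return an `alignment_result` list: `aligned_a`, `aligned_b` (equal
#'   length, `-` gaps), `score`, `length`, `n_identity`, `n_similarity`,
#'   `n_gaps`, `identity_pct`, `similarity_pct`, `gaps_pct`.
#' @export
nw_align <- function(a, b, params = align_params()) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  smat <- params$matrix
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ai <- match(ca, rownames(smat)) - 1L
  bi <- match(cb, rownames(smat)) - 1L
  if (anyNA(ai) || anyNA(bi)) {
    bad <- unique(c(ca[is.na(ai)], cb[is.na(bi)]))
    stop("residue(s) not in scoring matrix ", params$matrix_name, ": ",
         paste(bad, collapse = ", "))
  }
  res <- nw_align_cpp(ai, bi, smat, params$gap_open, params$gap_extend,
                      params$penalize_end_gaps)
  ga <- rep("-", length(res$ia))
  ga[res$ia >= 0] <- ca[res$ia[res$ia >= 0] + 1L]
  gb <- rep("-", length(res$ib))
  gb[res$ib >= 0] <- cb[res$ib[res$ib >= 0] + 1L]
  len <- length(ga)
  gap_col <- ga == "-" | gb == "-"
  ident <- !gap_col & ga == gb
  scores <- rep(-Inf, len)
  scores[!gap_col] <- smat[cbind(ga[!gap_col], gb[!gap_col])]
  similar <- !gap_col & scores > 0
  structure(list(aligned_a = paste(ga, collapse = ""),
                 aligned_b = paste(gb, collapse = ""),
                 score = res$score, length = len,
                 n_identity = sum(ident), n_similarity = sum(similar),
                 n_gaps = sum(gap_col),
                 identity_pct = 100 * sum(ident) / len,
                 similarity_pct = 100 * sum(similar) / len,
                 gaps_pct = 100 * sum(gap_col) / len,
                 params = params[c("matrix_name", "gap_open", "gap_extend",
                                   "penalize_end_gaps")]),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("Global alignment (%s, open %g, extend %g)\n",
              x$params$matrix_name, x$params$gap_open, x$params$gap_extend))
  cat(sprintf("Length %d  Score %g\n", x$length, x$score))
  cat(sprintf("Identity   %d/%d (%.1f%%)\n", x$n_identity, x$length,
              x$identity_pct))
  cat(sprintf("Similarity %d/%d (%.1f%%)\n", x$n_similarity, x$length,
              x$similarity_pct))
  cat(sprintf("Gaps       %d/%d (%.1f%%)\n", x$n_gaps, x$length, x$gaps_pct))
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Extract the 13-residue PSY domain from a precursor
#'
#' Prefers the leftmost strict-motif match in the second half of the
#' sequence, then the leftmost strict match anywhere, then the same two
#' steps with the relaxed five-residue pattern. Returns `NULL` when neither
#' pattern matches.
#'
#' @param record one-row `precursor_set`, or a sequence string.
#' @param strict,relaxed the strict and relaxed PSY motif patterns.
#' @return list with `sequence` (13-mer), `start`, `end`, `pattern`, or
#'   `NULL`.
#' @export
extract_domain <- function(record, strict = psy_motif_pattern(),
                           relaxed = relaxed_psy_pattern()) {
  if (is.character(record)) {
    record <- precursor_records("query", record)
  }
  seq <- record$sequence[1]
  L <- nchar(seq)
  for (pat in list(strict, relaxed)) {
    starts <- scan_one(seq, pat)
    if (length(starts) == 0L) next
    second <- starts[in_second_half(starts, L)]
    s <- if (length(second) > 0L) second[1] else starts[1]
    return(list(sequence = substr(seq, s, s + pat$length - 1L),
                start = s, end = s + pat$length - 1L, pattern = pat$name))
  }
  NULL
}

#' Similarity table of homologs against a reference precursor
#'
#' For each non-reference record: the full-precursor percent similarity and
#' the PSY-domain-vs-domain percent similarity from global alignments under
#' `params`. Percentages are rounded half-up to one decimal, the reporting
#' precision of the table. The domain column is `NA` for records without an
#' extractable domain.
#'
#' @param reference one-row `precursor_set`; must have an extractable
#'   domain.
#' @param others a `precursor_set` of homologs.
#' @param params an [align_params()].
#' @return data frame `id`, `precursor_similarity`, `domain_similarity`
#'   with attribute `reference_id`.
#' @export
similarity_table <- function(reference, others, params = align_params()) {
  ref_dom <- extract_domain(reference)
  if (is.null(ref_dom)) {
    stop("reference record '", reference$id[1],
         "' has no extractable PSY domain")
  }
  rows <- lapply(seq_len(nrow(others)), function(i) {
    full <- nw_align(reference$sequence[1], others$sequence[i], params)
    dom <- extract_domain(others[i, , drop = FALSE])
    dom_pct <- if (is.null(dom)) NA_real_ else {
      round_half_up(nw_align(ref_dom$sequence, dom$sequence,
                             params)$similarity_pct, 1L)
    }
    data.frame(id = others$id[i],
               precursor_similarity = round_half_up(full$similarity_pct, 1L),
               domain_similarity = dom_pct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference_id") <- reference$id[1]
  out
}
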
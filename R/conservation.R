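#' Read a multiple sequence alignment
#'
#' Ingests an externally built MSA (e.g. MUSCLE output) from aligned FASTA
#' or Clustal format. `.` gap characters are normalized to `-`; all rows
#' must have equal length.
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"` (Clustal ingest uses the seqinr
#'   package).
#' @return an `msa` object: list with `id` (character), `gapped`
#'   (character, aligned rows) and `n_cols`.
#' @export
read_msa <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    aa <- Biostrings::readAAStringSet(path)
    ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
    gapped <- as.character(aa)
  } else {
    if (!requireNamespace("seqinr", quietly = TRUE)) {
      stop("Clustal ingest requires the 'seqinr' package")
    }
    aln <- seqinr::read.alignment(path, format = "clustal")
    ids <- aln$nam
    gapped <- toupper(unlist(aln$seq))
  }
  gapped <- gsub(".", "-", gapped, fixed = TRUE)
  lens <- nchar(gapped)
  if (length(unique(lens)) > 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(unique(lens), collapse = ", "))
  }
  structure(list(id = unname(ids), gapped = unname(gapped),
                 n_cols = if (length(lens)) unname(lens[1]) else 0L),
            class = "msa")
}

#' Five-residue conservation census across homologs
#'
#' Per (ungapped) record, the census passes iff the relaxed 13-position PSY
#' pattern (D, Y at positions 1-2, N at 8, H at 11, P at 13, all other
#' positions free) matches anywhere in the sequence. For failing records
#' the missing residues are attributed from the best partial match: the
#' 13-residue window satisfying the most of the five constraints, leftmost
#' on ties.
#'
#' @param records a `precursor_set`.
#' @return a `conservation_census`: list with `per_record` (data frame
#'   `id`, `has_all_five`, `missing`), `n_pass`, `n_total`, `failures`
#'   (failing subset of `per_record`).
#' @export
five_residue_census <- function(records) {
  if (anyDuplicated(records$id)) stop("duplicate record ids in census input")
  constraints <- list(c(1L, "D"), c(2L, "Y"), c(8L, "N"),
                      c(11L, "H"), c(13L, "P"))
  labels <- vapply(constraints, `[`, character(1), 2L)
  per <- lapply(seq_len(nrow(records)), function(i) {
    seq <- records$sequence[i]
    chars <- strsplit(seq, "")[[1]]
    L <- length(chars)
    if (L < 13L) {
      return(data.frame(id = records$id[i], has_all_five = FALSE,
                        missing = paste(labels, collapse = ","),
                        stringsAsFactors = FALSE))
    }
    n_win <- L - 12L
    sat <- matrix(FALSE, nrow = n_win, ncol = 5L)
    for (k in seq_along(constraints)) {
      off <- as.integer(constraints[[k]][1])
      sat[, k] <- chars[seq(off, length.out = n_win)] == constraints[[k]][2]
    }
    n_sat <- rowSums(sat)
    best <- which.max(n_sat)    # leftmost maximum
    ok <- n_sat[best] == 5L
    data.frame(id = records$id[i], has_all_five = ok,
               missing = if (ok) "" else
                 paste(labels[!sat[best, ]], collapse = ","),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(per_record = per, n_pass = sum(per$has_all_five),
                 n_total = nrow(per),
                 failures = per[!per$has_all_five, , drop = FALSE]),
            class = "conservation_census")
}

#' @export
print.conservation_census <- function(x, ...) {
  cat(sprintf("Five-residue conservation census: %d of %d pass\n",
              x$n_pass, x$n_total))
  if (nrow(x$failures) > 0L) {
    for (i in seq_len(nrow(x$failures))) {
      cat(sprintf("  %s missing: %s\n", x$failures$id[i],
                  x$failures$missing[i]))
    }
  }
  invisible(x)
}

#' Per-column conservation statistics of an MSA
#'
#' For every alignment column: the most frequent non-gap residue (ties
#' broken alphabetically), the fraction of rows carrying exactly that
#' residue, and the gap fraction. Fractions use the number of rows as
#' denominator, so identical + non-identical + gap counts add to the row
#' count in each column.
#'
#' @param msa an `msa` from [read_msa()].
#' @return data frame `column`, `majority_residue`, `frac_identical`,
#'   `gap_fraction`.
#' @export
column_stats <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  n <- length(msa$gapped)
  if (n == 0L || msa$n_cols == 0L) {
    return(data.frame(column = integer(), majority_residue = character(),
                      frac_identical = numeric(), gap_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  mat <- do.call(rbind, strsplit(msa$gapped, ""))
  rows <- lapply(seq_len(msa$n_cols), function(j) {
    col <- mat[, j]
    gaps <- sum(col == "-")
    resid <- col[col != "-"]
    if (length(resid) == 0L) {
      maj <- NA_character_; n_id <- 0L
    } else {
      tab <- table(resid)
      maj <- sort(names(tab)[tab == max(tab)])[1]
      n_id <- max(tab)
    }
    data.frame(column = j, majority_residue = maj,
               frac_identical = n_id / n, gap_fraction = gaps / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
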
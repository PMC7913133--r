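#' Parse a PROSITE-style protein motif pattern
#'
#' Supports the pattern subset needed for PSY-domain work: literal residues,
#' `X` (any residue; lowercase `x` accepted), and bracketed residue classes
#' such as `[AP]`. `-` separators are ignored. Anything else from the full
#' ScanProsite grammar (repeat ranges `x(2,4)`, exclusions `{..}`, anchors
#' `<`/`>`) is rejected loudly rather than half-supported.
#'
#' @param text pattern string, e.g. `"DYXXXX[AP]NXXHXP"`.
#' @param name optional pattern name carried into match tables.
#' @return a `motif_pattern`: list with `name`, `elements` (one entry per
#'   position; `NULL` means "any residue", otherwise the allowed residues)
#'   and `length`.
#' @export
parse_pattern <- function(text, name = text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  src <- gsub("[-[:space:]]", "", toupper(text))
  if (!nzchar(src)) stop("pattern parse error: no positions in '", text, "'")
  chars <- strsplit(src, "")[[1]]
  elements <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (length(close) == 0L) {
        stop(sprintf("pattern parse error at position %d: unbalanced '['", i))
      }
      close <- close[1]
      members <- chars[seq(i + 1L, length.out = close - i - 1L)]
      if (length(members) == 0L) {
        stop(sprintf("pattern parse error at position %d: empty class", i))
      }
      bad <- setdiff(members, AA20)
      if (length(bad) > 0L) {
        stop(sprintf("pattern parse error at position %d: illegal class member(s) %s",
                     i, paste(bad, collapse = ", ")))
      }
      elements[[length(elements) + 1L]] <- unique(members)
      i <- close + 1L
    } else if (ch == "X") {
      elements[length(elements) + 1L] <- list(NULL)
      i <- i + 1L
    } else if (ch %in% AA20) {
      elements[[length(elements) + 1L]] <- ch
      i <- i + 1L
    } else if (ch %in% c("(", ")", "{", "}", "<", ">", ".", ",") ||
               grepl("[0-9]", ch)) {
      stop(sprintf("pattern parse error at position %d: unsupported construct '%s'",
                   i, ch))
    } else {
      stop(sprintf("pattern parse error at position %d: illegal character '%s'",
                   i, ch))
    }
  }
  structure(list(name = name, elements = elements,
                 length = length(elements)),
            class = "motif_pattern")
}

#' Render a motif pattern back to text
#'
#' Inverse of [parse_pattern()] up to separator stripping:
#' `parse_pattern(render_pattern(p))` has the same elements as `p`.
#'
#' @param pattern a `motif_pattern`.
#' @return pattern string.
#' @export
render_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  paste(vapply(pattern$elements, function(e) {
    if (is.null(e)) "X"
    else if (length(e) == 1L) e
    else paste0("[", paste(e, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern '%s'> %s (%d positions)\n",
              x$name, render_pattern(x), x$length))
  invisible(x)
}

#' The strict 13-residue PSY-domain motif
#'
#' `DYXXXX[AP]NXXHXP`: the conserved domain of the PSY family of
#' tyrosine-sulfated plant signaling peptides, anchored on the Asp-Tyr
#' sulfation site.
#'
#' @return a `motif_pattern`.
#' @export
psy_motif_pattern <- function() {
  parse_pattern("DYXXXX[AP]NXXHXP", name = "PSY_strict")
}

#' The relaxed five-residue PSY-domain motif
#'
#' The same 13-position frame constraining only the five residues conserved
#' across species (D and Y at positions 1-2, N at 8, H at 11, P at 13); all
#' other positions accept any residue. Used for the cross-species
#' conservation census, where e.g. a GmPSY2-like sequence fails only the
#' terminal P.
#'
#' @return a `motif_pattern`.
#' @export
relaxed_psy_pattern <- function() {
  parse_pattern("DYXXXXXNXXHXP", name = "PSY_relaxed")
}

# Match start positions (1-based) of `pattern` in one sequence string.
# "Any" positions match every valid residue including X; literal and class
# positions never match an X in the sequence, so unknown residues cannot
# fabricate motif hits.
scan_one <- function(seq, pattern) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  k <- pattern$length
  if (k > L) return(integer(0))
  n_win <- L - k + 1L
  ok <- rep(TRUE, n_win)
  for (p in seq_len(k)) {
    e <- pattern$elements[[p]]
    m <- if (is.null(e)) rep(TRUE, L) else chars %in% e
    ok <- ok & m[seq(p, length.out = n_win)]
  }
  which(ok)
}

#' Scan sequences for a motif pattern
#'
#' All (possibly overlapping) occurrences are reported, in ascending start
#' order per record, mirroring overlap-inclusive ScanProsite behavior.
#' Coordinates are 1-based inclusive.
#'
#' @param records a `precursor_set` ([precursor_records()]), or a named
#'   character vector of sequences.
#' @param pattern a `motif_pattern` (default: strict PSY motif).
#' @return data frame with columns `record_id`, `start`, `end`, `matched`,
#'   `pattern` (zero rows when nothing matches).
#' @export
scan_motif <- function(records, pattern = psy_motif_pattern()) {
  stopifnot(inherits(pattern, "motif_pattern"))
  if (is.character(records)) {
    ids <- if (is.null(names(records))) as.character(seq_along(records))
           else names(records)
    records <- precursor_records(ids, records)
  }
  res <- lapply(seq_len(nrow(records)), function(i) {
    starts <- scan_one(records$sequence[i], pattern)
    if (length(starts) == 0L) return(NULL)
    data.frame(record_id = records$id[i], start = starts,
               end = starts + pattern$length - 1L,
               matched = substring(records$sequence[i], starts,
                                   starts + pattern$length - 1L),
               pattern = pattern$name, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(record_id = character(), start = integer(),
                      end = integer(), matched = character(),
                      pattern = character(), stringsAsFactors = FALSE)
  }
  res
}

#' Tyrosine-sulfation context check
#'
#' Tyrosylprotein sulfotransferase prefers an acidic residue flanking the
#' acceptor tyrosine: the check is `TRUE` iff the residue at -1 or +1 of the
#' given tyrosine is D or E. Positions beyond either end of the sequence are
#' treated as absent.
#'
#' @param sequence amino-acid sequence string.
#' @param tyr_pos 1-based position of a tyrosine in `sequence`.
#' @return logical scalar.
#' @export
sulfation_context <- function(sequence, tyr_pos) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  if (tyr_pos < 1L || tyr_pos > L) {
    stop("tyr_pos out of range: ", tyr_pos)
  }
  if (substr(sequence, tyr_pos, tyr_pos) != "Y") {
    stop(sprintf("contract violation: residue at position %d is '%s', not Y",
                 tyr_pos, substr(sequence, tyr_pos, tyr_pos)))
  }
  flank <- c(if (tyr_pos > 1L) substr(sequence, tyr_pos - 1L, tyr_pos - 1L),
             if (tyr_pos < L) substr(sequence, tyr_pos + 1L, tyr_pos + 1L))
  any(flank %in% c("D", "E"))
}
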
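# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the motif oracle goes through PCRE regexes, the
# alignment oracle enumerates every global alignment as a move string.

# Internal package helpers exercised directly by the tests.
scan_one <- getFromNamespace("scan_one", "psykit")
in_second_half <- getFromNamespace("in_second_half", "psykit")
round_half_up <- getFromNamespace("round_half_up", "psykit")
normalize_sequence <- getFromNamespace("normalize_sequence", "psykit")

AA20_T <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Regex lookahead scan: overlap-inclusive match starts of a parsed pattern.
oracle_regex_scan <- function(seq, pattern) {
  re <- paste(vapply(pattern$elements, function(e) {
    if (is.null(e)) "."
    else if (length(e) == 1L) e
    else paste0("[", paste(e, collapse = ""), "]")
  }, character(1)), collapse = "")
  m <- gregexpr(paste0("(?=", re, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# All monotone move strings ("D" diagonal, "U" consume a, "L" consume b)
# from (0,0) to (n,m), memoized on (n,m).
.path_memo <- new.env(parent = emptyenv())
enumerate_paths <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.path_memo[[key]])) return(.path_memo[[key]])
  res <- if (n == 0L && m == 0L) {
    ""
  } else {
    out <- character(0)
    if (n > 0L && m > 0L) out <- c(out, paste0("D", enumerate_paths(n - 1L, m - 1L)))
    if (n > 0L) out <- c(out, paste0("U", enumerate_paths(n - 1L, m)))
    if (m > 0L) out <- c(out, paste0("L", enumerate_paths(n, m - 1L)))
    out
  }
  .path_memo[[key]] <- res
  res
}

# Score one alignment given as a move string: substitution scores on D
# columns; each maximal gap run costs open + len * extend, except the first
# and last run of the alignment when end gaps are free.
score_path <- function(moves, ca, cb, smat, gap_open, gap_extend, end_gaps) {
  mv <- strsplit(moves, "")[[1]]
  ia <- cumsum(mv != "L")
  ib <- cumsum(mv != "U")
  d <- mv == "D"
  sub <- if (any(d)) sum(smat[cbind(ca[ia[d]], cb[ib[d]])]) else 0
  r <- rle(mv)
  gap_runs <- which(r$values %in% c("U", "L"))
  cost <- 0
  for (g in gap_runs) {
    if (!end_gaps && (g == 1L || g == length(r$values))) next
    cost <- cost + gap_open + r$lengths[g] * gap_extend
  }
  sub - cost
}

# Brute-force optimal score over every global alignment of a and b.
oracle_align_score <- function(a, b, gap_open = 10, gap_extend = 0.5,
                               end_gaps = FALSE, smat = score_matrix()) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  paths <- enumerate_paths(length(ca), length(cb))
  max(vapply(paths, score_path, numeric(1), ca = ca, cb = cb, smat = smat,
             gap_open = gap_open, gap_extend = gap_extend,
             end_gaps = end_gaps))
}

# Random amino-acid sequence; include_x mixes in the unknown-residue letter.
random_seq <- function(len, include_x = FALSE) {
  alpha <- if (include_x) c(AA20_T, "X") else AA20_T
  paste(sample(alpha, len, replace = TRUE), collapse = "")
}

# Where the paper-scale regressions look for the (optional) UniProt cache.
sequence_cache_dir <- function() {
  opt <- getOption("psykit.cache_dir")
  if (!is.null(opt)) return(opt)
  pkg <- system.file("extdata", "uniprot_cache", package = "psykit")
  if (nzchar(pkg)) return(pkg)
  "uniprot_cache"
}
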
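#' Normalize a raw amino-acid sequence
#'
#' Uppercases, strips `*` stop characters (with a warning), maps `U`
#' (selenocysteine) to `X` (with a warning), and rejects any letter outside
#' the 20 standard residues plus `X`.
#'
#' @param seq character scalar, raw sequence.
#' @param id record identifier used in messages.
#' @return normalized sequence string.
#' @keywords internal
normalize_sequence <- function(seq, id = "<unnamed>") {
  seq <- toupper(gsub("[ \t\r\n]", "", seq))
  if (grepl("*", seq, fixed = TRUE)) {
    warning(sprintf("record '%s': '*' stop character(s) stripped", id),
            call. = FALSE)
    seq <- gsub("*", "", seq, fixed = TRUE)
  }
  if (grepl("U", seq, fixed = TRUE)) {
    warning(sprintf("record '%s': nonstandard residue U mapped to X", id),
            call. = FALSE)
    seq <- gsub("U", "X", seq, fixed = TRUE)
  }
  if (!nzchar(seq)) {
    stop(sprintf("record '%s': empty sequence", id), call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), AA_VALID)
  if (length(bad) > 0L) {
    stop(sprintf("record '%s': invalid residue letter(s): %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  seq
}

#' Construct a set of precursor records
#'
#' A precursor set is a plain `data.frame` (class `precursor_set`) with one
#' row per prepropeptide and columns `id`, `accession`, `species`,
#' `sequence`. Sequences are normalized on construction (see
#' [normalize_sequence()]).
#'
#' @param id character vector of unique identifiers (e.g. `"AtPSY2"`).
#' @param sequence character vector of amino-acid sequences.
#' @param accession optional UniProt accessions.
#' @param species optional species names.
#' @return a `precursor_set` data frame.
#' @export
precursor_records <- function(id, sequence, accession = NA_character_,
                              species = NA_character_) {
  stopifnot(length(id) == length(sequence))
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate record ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sequence <- vapply(seq_along(sequence),
                     function(i) normalize_sequence(sequence[i], id[i]),
                     character(1))
  out <- data.frame(id = id,
                    accession = rep_len(as.character(accession), length(id)),
                    species = rep_len(as.character(species), length(id)),
                    sequence = sequence,
                    stringsAsFactors = FALSE)
  class(out) <- c("precursor_set", "data.frame")
  out
}

#' Read a protein FASTA file into a precursor set
#'
#' Wrap-agnostic, order-preserving. The file is structurally validated first
#' so malformed input is reported with a line number, then parsed with
#' [Biostrings::readAAStringSet()].
#'
#' @param path path to a FASTA file.
#' @return a `precursor_set` (see [precursor_records()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("FASTA parse error: file is empty: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("FASTA parse error at line %d: expected '>' header",
                 nonblank[1]))
  }
  hdr <- which(startsWith(trimws(lines), ">"))
  for (k in seq_along(hdr)) {
    h <- hdr[k]
    if (!nzchar(trimws(sub("^>", "", trimws(lines[h]))))) {
      stop(sprintf("FASTA parse error at line %d: empty header", h))
    }
    to <- if (k < length(hdr)) hdr[k + 1] - 1L else length(lines)
    body <- lines[setdiff(seq(h, to), h)]
    if (!any(nzchar(trimws(body)))) {
      stop(sprintf("FASTA parse error at line %d: record '%s' has no sequence",
                   h, trimws(sub("^>\\s*", "", lines[h]))))
    }
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  precursor_records(id = ids, sequence = as.character(aa))
}

#' Write a precursor set to FASTA
#'
#' @param records a `precursor_set`.
#' @param path output path.
#' @param width line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aa, filepath = path, width = width)
  invisible(path)
}

#' Read a BLAST tabular hit file
#'
#' Two dialects are accepted and auto-detected from the column count:
#' \describe{
#'   \item{12+ columns}{NCBI `outfmt 6` default order (`qseqid sseqid pident
#'     length mismatch gapopen qstart qend sstart send evalue bitscore`).
#'     `subject_length` is not part of that dialect and is returned as `NA`.}
#'   \item{3 columns}{a minimal dialect `subject_id`, `subject_length`,
#'     `evalue`.}
#' }
#'
#' @param path path to a tab-separated file; may be empty.
#' @return data frame with columns `query_id`, `subject_id`, `evalue`,
#'   `subject_length`, `percent_identity`, `bitscore` (missing fields `NA`).
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), subject_length = integer(),
                      percent_identity = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty)
  tab <- read.delim(text = lines, header = FALSE, sep = "\t",
                    colClasses = "character", stringsAsFactors = FALSE)
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      stop(sprintf("BLAST table parse error: non-numeric %s in row %d",
                   what, which(is.na(v))[1]))
    }
    v
  }
  if (ncol(tab) >= 12L) {
    out <- data.frame(query_id = tab[[1]], subject_id = tab[[2]],
                      evalue = num(tab[[11]], "evalue"),
                      subject_length = NA_integer_,
                      percent_identity = num(tab[[3]], "percent identity"),
                      bitscore = num(tab[[12]], "bitscore"),
                      stringsAsFactors = FALSE)
  } else if (ncol(tab) == 3L) {
    out <- data.frame(query_id = NA_character_, subject_id = tab[[1]],
                      evalue = num(tab[[3]], "evalue"),
                      subject_length = as.integer(num(tab[[2]],
                                                      "subject length")),
                      percent_identity = NA_real_, bitscore = NA_real_,
                      stringsAsFactors = FALSE)
    if (any(out$subject_length < 1L)) {
      stop("BLAST table parse error: subject_length must be >= 1")
    }
  } else {
    stop("BLAST table parse error: expected 3 or >= 12 tab-separated columns, got ",
         ncol(tab))
  }
  if (any(out$evalue < 0)) stop("BLAST table parse error: negative evalue")
  out
}

uniprot_accession_ok <- function(x) {
  re <- paste0("^([OPQ][0-9][A-Z0-9]{3}[0-9]|",
               "[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$")
  grepl(re, x)
}

#' The PSY homolog accession manifest
#'
#' Names and UniProt accessions of the 32 PSY homologs used in the
#' cross-species analysis: eight Arabidopsis PSYs plus homologs from
#' Amborella, rice, maize, soybean, chickpea, Lotus, poplar, Medicago and
#' the moss Physcomitrella. Only identifiers are shipped; sequences are
#' retrieved with [fetch_accessions()] and cached locally.
#'
#' @return data frame with columns `name`, `accession`, `species`.
#' @export
psy_manifest <- function() {
  path <- system.file("extdata", "psy_manifest.tsv", package = "psykit",
                      mustWork = TRUE)
  man <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(man), c("name", "accession", "species")))
  bad <- man$accession[!uniprot_accession_ok(man$accession)]
  if (length(bad) > 0L) {
    stop("manifest contains syntactically invalid UniProt accession(s): ",
         paste(bad, collapse = ", "))
  }
  man
}

#' Fetch manifest sequences from UniProt into a local FASTA cache
#'
#' Downloads `<accession>.fasta` for every manifest entry that is not
#' already cached, records fetch date and MD5 checksums in
#' `cache_metadata.tsv`, and returns the cached records. Failures are
#' reported per entry, never silently dropped. All other operations in the
#' package are strictly offline; this is the only function that touches the
#' network.
#'
#' @param manifest data frame with columns `name`, `accession`
#'   (default [psy_manifest()]).
#' @param cache_dir directory for the FASTA cache.
#' @param base_url UniProt REST endpoint.
#' @return list with `records` (a `precursor_set` of the successfully
#'   cached entries, in manifest order) and `failures` (data frame
#'   `name`, `accession`, `error`).
#' @export
fetch_accessions <- function(manifest = psy_manifest(),
                             cache_dir = "uniprot_cache",
                             base_url = "https://rest.uniprot.org/uniprotkb") {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  failures <- data.frame(name = character(), accession = character(),
                         error = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    acc <- manifest$accession[i]
    dest <- file.path(cache_dir, paste0(acc, ".fasta"))
    if (file.exists(dest)) next
    url <- sprintf("%s/%s.fasta", base_url, acc)
    ok <- tryCatch({
      utils::download.file(url, dest, quiet = TRUE, mode = "wb")
      TRUE
    }, error = function(e) conditionMessage(e),
       warning = function(w) conditionMessage(w))
    if (!isTRUE(ok)) {
      unlink(dest)
      failures <- rbind(failures,
                        data.frame(name = manifest$name[i], accession = acc,
                                   error = as.character(ok),
                                   stringsAsFactors = FALSE))
    }
  }
  cached <- manifest[!(manifest$accession %in% failures$accession), ,
                     drop = FALSE]
  records <- if (nrow(cached) > 0L) {
    load_cached_accessions(cached, cache_dir)
  } else {
    precursor_records(character(), character())
  }
  files <- file.path(cache_dir, paste0(cached$accession, ".fasta"))
  meta <- data.frame(accession = cached$accession,
                     fetched = as.character(Sys.Date()),
                     md5 = unname(tools::md5sum(files)),
                     stringsAsFactors = FALSE)
  write.table(meta, file.path(cache_dir, "cache_metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  list(records = records, failures = failures)
}

#' Load previously cached manifest sequences (offline)
#'
#' @inheritParams fetch_accessions
#' @return a `precursor_set` in manifest order, with `id` set to the
#'   manifest name and `accession`/`species` filled in.
#' @export
load_cached_accessions <- function(manifest = psy_manifest(),
                                   cache_dir = "uniprot_cache") {
  files <- file.path(cache_dir, paste0(manifest$accession, ".fasta"))
  missing <- !file.exists(files)
  if (any(missing)) {
    stop("sequence cache at '", cache_dir, "' is missing ",
         sum(missing), " entr", if (sum(missing) == 1) "y" else "ies", ": ",
         paste(manifest$accession[missing], collapse = ", "),
         "; run fetch_accessions() with network access first")
  }
  seqs <- vapply(files, function(f) {
    r <- read_fasta(f)
    if (nrow(r) != 1L) stop("cache file ", f, " must hold exactly one record")
    r$sequence
  }, character(1))
  precursor_records(id = manifest$name, sequence = unname(seqs),
                    accession = manifest$accession,
                    species = if ("species" %in% names(manifest))
                      manifest$species else NA_character_)
}
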
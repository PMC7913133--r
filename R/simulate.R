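#' Configuration for the synthetic prepropeptide generator
#'
#' The generator emulates the architecture of secreted-peptide precursors:
#' a hydrophobicity-biased N-terminal leader standing in for the secretion
#' signal, a uniform-background propeptide body of 60-200 residues, and
#' one instantiated PSY-like motif placed in a controlled half of the
#' sequence. Ground truth (motif position, intended screening verdict,
#' planted cleavage motifs) is recorded so downstream stages can be scored
#' without re-deriving it.
#'
#' @param n number of precursors.
#' @param seed integer seed; generation is byte-deterministic given it.
#' @param length_range inclusive precursor length range (within 30-500).
#' @param leader_length leader length in residues (< min length).
#' @param motif a `motif_pattern` instantiated into each sequence.
#' @param motif_half `"second"` (screening should pass), `"first"`
#'   (should fail with `MOTIF_FIRST_HALF`) or `"none"` (should fail with
#'   `NO_MOTIF`).
#' @param motif_mutations substitutions applied to the embedded motif
#'   instance (see [mutate_motif()]).
#' @param cleavage_motifs character vector of enzyme names from
#'   [builtin_enzyme_motifs()] to plant one instance of, each; the
#'   generator then guarantees by rejection that the cleavage annotation of
#'   the sequence is exactly the planted set. Best combined with
#'   `motif_half = "none"` (the PSY motif itself contains a DY site).
#' @return a `precursor_sim_config` list.
#' @export
sim_precursor_config <- function(n, seed = 1L, length_range = c(60L, 200L),
                                 leader_length = 25L,
                                 motif = psy_motif_pattern(),
                                 motif_half = c("second", "first", "none"),
                                 motif_mutations = 0L,
                                 cleavage_motifs = character(0)) {
  motif_half <- match.arg(motif_half)
  stopifnot(n >= 0, length_range[1] >= 30, length_range[2] <= 500,
            length_range[1] <= length_range[2],
            leader_length < length_range[1],
            motif_mutations >= 0, motif_mutations <= motif$length)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 length_range = as.integer(length_range),
                 leader_length = as.integer(leader_length),
                 motif = motif, motif_half = motif_half,
                 motif_mutations = as.integer(motif_mutations),
                 cleavage_motifs = cleavage_motifs),
            class = "precursor_sim_config")
}

HYDROPHOBIC <- c("A", "L", "V", "I", "F", "M", "W")

sample_leader <- function(k) {
  paste(sample(c(HYDROPHOBIC, AA20),
               k, replace = TRUE,
               prob = c(rep(0.8 / 7, 7), rep(0.2 / 20, 20))),
        collapse = "")
}

# Draw one concrete instance of a pattern (X positions get a uniform
# residue, classes a uniform member).
instantiate_pattern <- function(pattern) {
  paste(vapply(pattern$elements, function(e) {
    if (is.null(e)) sample(AA20, 1L) else sample(c(e, e), 1L)
  }, character(1)), collapse = "")
}

#' Generate synthetic prepropeptides with recorded ground truth
#'
#' @param config a [sim_precursor_config()].
#' @return list with `records` (a `precursor_set`), `truth` (data frame
#'   `id`, `length`, `motif_start`, `motif_end`, `expected_pass`,
#'   `expected_reasons`) and `cleavage_truth` (data frame of planted
#'   enzyme-motif instances: `record_id`, `enzyme`, `start`, `end`,
#'   `matched`).
#' @export
gen_precursors <- function(config) {
  stopifnot(inherits(config, "precursor_sim_config"))
  set.seed(config$seed)
  motif <- config$motif
  k <- motif$length
  enz <- builtin_enzyme_motifs()
  truth <- list()
  cleav <- list()
  seqs <- character(config$n)
  ids <- sprintf("sim%04d", seq_len(config$n))
  for (r in seq_len(config$n)) {
    for (try in seq_len(200L)) {
      L <- sample(seq(config$length_range[1], config$length_range[2]), 1L)
      chars <- c(strsplit(sample_leader(config$leader_length), "")[[1]],
                 sample(AA20, L - config$leader_length, replace = TRUE))
      motif_start <- NA_integer_
      if (config$motif_half != "none") {
        lo <- if (config$motif_half == "second") ceiling(L / 2) + 1L
              else config$leader_length + 1L
        hi <- if (config$motif_half == "second") L - k + 1L
              else min(ceiling(L / 2), L - k + 1L)
        if (lo > hi) next
        motif_start <- sample(seq(lo, hi), 1L)
        inst <- strsplit(instantiate_pattern(motif), "")[[1]]
        chars[seq(motif_start, length.out = k)] <- inst
      }
      seq <- paste(chars, collapse = "")
      if (config$motif_mutations > 0L && !is.na(motif_start)) {
        seq <- mutate_motif(seq, motif_start, config$motif_mutations,
                            motif = motif)$sequence
      }
      planted <- NULL
      if (length(config$cleavage_motifs) > 0L) {
        body <- c(config$leader_length + 1L, L)
        occupied <- if (is.na(motif_start)) integer(0)
                    else seq(motif_start, length.out = k)
        pl <- list()
        ok_place <- TRUE
        for (e in config$cleavage_motifs) {
          cand <- Filter(function(m) m$enzyme == e, enz)
          if (length(cand) == 0L) stop("unknown enzyme motif: ", e)
          mo <- cand[[sample.int(length(cand), 1L)]]
          kk <- mo$pattern$length
          free <- setdiff(seq(body[1], L - kk + 1L), occupied)
          free <- free[vapply(free, function(s)
            !any(seq(s, length.out = kk) %in% occupied), logical(1))]
          if (length(free) == 0L) { ok_place <- FALSE; break }
          s <- free[sample.int(length(free), 1L)]
          inst <- instantiate_pattern(mo$pattern)
          chars2 <- strsplit(seq, "")[[1]]
          chars2[seq(s, length.out = kk)] <- strsplit(inst, "")[[1]]
          seq <- paste(chars2, collapse = "")
          occupied <- c(occupied, seq(s, length.out = kk))
          pl[[length(pl) + 1L]] <- data.frame(record_id = ids[r],
                                              enzyme = e, start = s,
                                              end = s + kk - 1L,
                                              matched = inst,
                                              stringsAsFactors = FALSE)
        }
        if (!ok_place) next
        planted <- do.call(rbind, pl)
      }
      # Rejection step: the assembled sequence must realize exactly the
      # intended ground truth.
      hits <- scan_one(seq, motif)
      if (config$motif_half == "none" && length(hits) > 0L) next
      if (config$motif_half == "second" && config$motif_mutations == 0L &&
          !(motif_start %in% hits)) next
      if (config$motif_half == "first" &&
          any(in_second_half(hits, L))) next
      if (!is.null(planted)) {
        # Ground truth guarantee: every planted site is recovered at its
        # coordinates, and planted-enzyme hits occur only where a planted
        # instance lies (overlapping patterns within a planted span, e.g.
        # the RXLX inside RRSLVLHTDY, are inherent and allowed).
        ann <- annotate_cleavage(precursor_records(ids[r], seq))
        ann <- ann[ann$enzyme %in% config$cleavage_motifs, , drop = FALSE]
        key <- function(d) paste(d$enzyme, d$start, d$end)
        if (!all(key(planted) %in% key(ann))) next
        in_planted <- vapply(seq_len(nrow(ann)), function(h) {
          any(ann$start[h] <= planted$end & ann$end[h] >= planted$start)
        }, logical(1))
        if (!all(in_planted)) next
      }
      seqs[r] <- seq
      expected_reasons <-
        if (length(hits) == 0L) "NO_MOTIF"
        else if (!any(in_second_half(hits, L))) "MOTIF_FIRST_HALF"
        else ""
      truth[[r]] <- data.frame(id = ids[r], length = L,
                               motif_start = motif_start,
                               motif_end = if (is.na(motif_start))
                                 NA_integer_ else motif_start + k - 1L,
                               expected_pass = !nzchar(expected_reasons),
                               expected_reasons = expected_reasons,
                               stringsAsFactors = FALSE)
      if (!is.null(planted)) cleav[[length(cleav) + 1L]] <- planted
      break
    }
    if (!nzchar(seqs[r])) {
      stop("could not realize ground truth for record ", ids[r],
           " in 200 attempts; check the configuration")
    }
  }
  records <- precursor_records(ids, seqs)
  cleavage_truth <- if (length(cleav) > 0L) do.call(rbind, cleav) else
    data.frame(record_id = character(), enzyme = character(),
               start = integer(), end = integer(), matched = character(),
               stringsAsFactors = FALSE)
  list(records = records, truth = do.call(rbind, truth),
       cleavage_truth = cleavage_truth)
}

#' Mutate residues inside a motif instance
#'
#' Applies `k` substitutions at positions of the 13-residue motif span,
#' preferring replacement residues with non-positive BLOSUM62 score
#' against the original (and, at constrained pattern positions, residues
#' outside the allowed set). The mutation order and replacements for all
#' positions are drawn up front, so for a fixed seed the `k`-mutation
#' result is a prefix of the `k+1`-mutation result — useful for
#' monotonicity properties of alignment similarity.
#'
#' @param sequence sequence string containing the motif instance.
#' @param start 1-based start of the motif span.
#' @param k number of substitutions (0 to motif length).
#' @param motif the `motif_pattern` whose constraints are being broken.
#' @param seed optional seed (`NULL` = use current RNG stream).
#' @return list with `sequence`, `positions` (absolute, the first `k` of
#'   the drawn order) and `replacements`.
#' @export
mutate_motif <- function(sequence, start, k, motif = psy_motif_pattern(),
                         seed = NULL) {
  stopifnot(k >= 0, k <= motif$length,
            start >= 1, start + motif$length - 1L <= nchar(sequence))
  if (!is.null(seed)) set.seed(seed)
  b62 <- score_matrix("BLOSUM62")
  chars <- strsplit(sequence, "")[[1]]
  order_ <- sample.int(motif$length)
  repl <- character(motif$length)
  for (j in seq_len(motif$length)) {
    p <- order_[j]
    orig <- chars[start + p - 1L]
    allowed <- motif$elements[[p]]
    cand <- setdiff(AA20, c(orig, allowed))
    nonpos <- cand[b62[orig, cand] <= 0]
    pool <- if (length(nonpos) > 0L) nonpos else cand
    repl[j] <- pool[sample.int(length(pool), 1L)]
  }
  use <- seq_len(k)
  chars[start + order_[use] - 1L] <- repl[use]
  list(sequence = paste(chars, collapse = ""),
       positions = start + order_[use] - 1L, replacements = repl[use])
}

#' Configuration for the synthetic Ct-table generator
#'
#' Mirrors the 3 biological x 2 technical replicate qPCR design. Each well
#' gets `Ct = ct_base[gene] - log_efficiency(true relative expression) +
#' Normal(0, noise_sd)`; the true ratio applies to every biological
#' replicate of the treatment group, with independent technical noise.
#'
#' @param genes named numeric vector of true expression ratios
#'   (treatment vs control) per target gene.
#' @param seed integer seed.
#' @param n_bio biological replicates per group (>= 2).
#' @param n_tech technical replicates per biological replicate.
#' @param ct_base named baseline Ct per gene (unnamed scalar recycles);
#'   the reference gene defaults to 20 cycles if not listed.
#' @param noise_sd technical noise, cycles.
#' @param efficiency amplification efficiency (fold per cycle).
#' @param reference_gene normalizer transcript; its true ratio is fixed at
#'   1.
#' @param control_group,treatment_group group labels.
#' @return a `ct_sim_config` list.
#' @export
sim_ct_config <- function(genes, seed = 1L, n_bio = 3L, n_tech = 2L,
                          ct_base = 24, noise_sd = 0.2, efficiency = 2,
                          reference_gene = "actin-2",
                          control_group = "control",
                          treatment_group = "treated") {
  stopifnot(n_bio >= 2, n_tech >= 1, noise_sd >= 0, efficiency > 1,
            !is.null(names(genes)), all(genes > 0))
  all_genes <- c(names(genes), reference_gene)
  if (is.null(names(ct_base))) {
    ct_base <- setNames(rep_len(ct_base, length(all_genes)), all_genes)
    ct_base[reference_gene] <- 20
  } else {
    missing <- setdiff(all_genes, names(ct_base))
    ct_base <- c(ct_base, setNames(rep(20, length(missing)), missing))
  }
  structure(list(genes = genes, seed = as.integer(seed),
                 n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
                 ct_base = ct_base, noise_sd = noise_sd,
                 efficiency = efficiency, reference_gene = reference_gene,
                 control_group = control_group,
                 treatment_group = treatment_group),
            class = "ct_sim_config")
}

#' Generate a synthetic Ct table with known true fold changes
#'
#' @param config a [sim_ct_config()].
#' @return list with `table` (a validated [ct_table()]) and `truth`
#'   (data frame `gene`, `true_ratio`).
#' @export
gen_ct_table <- function(config) {
  stopifnot(inherits(config, "ct_sim_config"))
  set.seed(config$seed)
  ratios <- c(config$genes, setNames(1, config$reference_gene))
  grid <- expand.grid(gene = names(ratios),
                      group = c(config$control_group,
                                config$treatment_group),
                      bio_rep = seq_len(config$n_bio),
                      tech_rep = seq_len(config$n_tech),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$gene, grid$group, grid$bio_rep, grid$tech_rep), ,
               drop = FALSE]
  expr <- ifelse(grid$group == config$treatment_group,
                 ratios[grid$gene], 1)
  grid$ct <- config$ct_base[grid$gene] -
    log(expr) / log(config$efficiency) +
    rnorm(nrow(grid), 0, config$noise_sd)
  rownames(grid) <- NULL
  list(table = ct_table(grid, reference_gene = config$reference_gene),
       truth = data.frame(gene = names(config$genes),
                          true_ratio = unname(config$genes),
                          stringsAsFactors = FALSE))
}
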
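test_that("self-alignment scores the diagonal and reports 100/100/0", {
  set.seed(3)
  b62 <- score_matrix("BLOSUM62")
  for (i in 1:10) {
    s <- random_seq(sample(5:60, 1))
    r <- nw_align(s, s)
    expect_identical(r$identity_pct, 100)
    expect_identical(r$similarity_pct, 100)
    expect_identical(r$gaps_pct, 0)
    chars <- strsplit(s, "")[[1]]
    expect_equal(r$score, sum(b62[cbind(chars, chars)]))
  }
})

test_that("DP score equals brute-force enumeration over all global alignments", {
  set.seed(17)
  n_pairs <- 520
  for (i in seq_len(n_pairs)) {
    a <- random_seq(sample(1:6, 1))
    b <- random_seq(sample(1:6, 1))
    endg <- i %% 4 == 0    # exercise both end-gap conventions
    p <- align_params(penalize_end_gaps = endg)
    got <- nw_align(a, b, p)$score
    want <- oracle_align_score(a, b, 10, 0.5, end_gaps = endg)
    expect_equal(got, want, info = sprintf("a=%s b=%s endgaps=%d", a, b, endg))
  }
})

test_that("alignment is symmetric and ungapping recovers the inputs", {
  set.seed(29)
  for (i in 1:60) {
    a <- random_seq(sample(5:50, 1))
    b <- random_seq(sample(5:50, 1))
    r1 <- nw_align(a, b)
    r2 <- nw_align(b, a)
    # the optimal score is symmetric; percentages of co-optimal
    # alignments can differ between argument orders, so only the score
    # and determinism are asserted
    expect_equal(r1$score, r2$score)
    expect_identical(gsub("-", "", r1$aligned_a), a)
    expect_identical(gsub("-", "", r1$aligned_b), b)
    # BLOSUM62 diagonal is positive, so identity implies similarity
    expect_lte(r1$identity_pct, r1$similarity_pct)
  }
})

test_that("scores agree with an independent affine-gap implementation", {
  suppressMessages(requireNamespace("Biostrings"))
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  set.seed(41)
  for (i in 1:25) {
    a <- random_seq(sample(10:80, 1))
    b <- random_seq(sample(10:80, 1))
    endg <- i %% 2 == 0
    got <- nw_align(a, b, align_params(penalize_end_gaps = endg))$score
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = e$BLOSUM62, gapOpening = 10, gapExtension = 0.5,
      type = if (endg) "global" else "overlap", scoreOnly = TRUE)
    expect_equal(got, ref)
  }
})

test_that("alignment is deterministic across repeated runs", {
  set.seed(53)
  a <- random_seq(40); b <- random_seq(35)
  r1 <- nw_align(a, b); r2 <- nw_align(a, b)
  expect_identical(r1[c("aligned_a", "aligned_b", "score")],
                   r2[c("aligned_a", "aligned_b", "score")])
})

test_that("unknown scoring matrix errors and lists what is available", {
  expect_error(align_params(matrix_name = "PAM250"), "BLOSUM62")
})

test_that("the vendored BLOSUM62 equals the NCBI matrix distributed elsewhere", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  own <- score_matrix("BLOSUM62")
  common <- intersect(rownames(own), rownames(e$BLOSUM62))
  expect_true(all(c(AA20_T, "X", "*") %in% common))
  expect_identical(own[common, common],
                   e$BLOSUM62[common, common] + 0)
})

test_that("domain extraction prefers strict second-half matches, then falls back", {
  seq <- paste0(strrep("G", 50), "DYGGGGANGGHGP", strrep("G", 10))
  d <- extract_domain(seq)
  expect_identical(d$sequence, "DYGGGGANGGHGP")
  expect_identical(d$start, 51L)
  expect_identical(d$pattern, "PSY_strict")

  relaxed_only <- paste0(strrep("G", 50), "DYGGGGGNGGHGP", strrep("G", 10))
  d2 <- extract_domain(relaxed_only)
  expect_identical(d2$pattern, "PSY_relaxed")

  expect_null(extract_domain(strrep("G", 80)))

  # strict match present => relaxed fallback irrelevant
  both <- paste0(strrep("G", 30), "DYGGGGGNGGHGP", strrep("G", 20),
                 "DYGGGGANGGHGP", strrep("G", 5))
  expect_identical(extract_domain(both)$pattern, "PSY_strict")
})

test_that("similarity table: identical homolog rows are 100/100", {
  ref <- precursor_records("ref", paste0(strrep("A", 40),
                                         "DYGGGGANGGHGP", strrep("S", 10)))
  twin <- precursor_records("twin", ref$sequence)
  tab <- similarity_table(ref, twin)
  expect_identical(tab$precursor_similarity, 100)
  expect_identical(tab$domain_similarity, 100)
  expect_identical(attr(tab, "reference_id"), "ref")
})

test_that("domain similarity degrades monotonically under accumulating mutations", {
  b62 <- score_matrix("BLOSUM62")
  ref <- "DYGGGGANGGHGP"
  rc <- strsplit(ref, "")[[1]]
  base <- paste0(strrep("L", 40), ref, strrep("S", 12))
  for (sd in c(1, 2, 99)) {
    res <- lapply(0:13, function(k) {
      mut <- mutate_motif(base, 41L, k, seed = sd)$sequence
      dom <- substr(mut, 41L, 53L)
      al <- nw_align(ref, dom, align_params(penalize_end_gaps = TRUE))
      list(nw = al, col = mean(b62[cbind(rc, strsplit(dom, "")[[1]])] > 0))
    })
    # column-wise positive fraction is non-increasing for every k
    colsim <- vapply(res, `[[`, numeric(1), "col")
    expect_true(all(diff(colsim) <= 1e-9))
    expect_identical(colsim[1], 1)
    # alignment similarity follows while the optimum stays gap-free;
    # once heavy mutation forces gaps the percentage is over a longer
    # alignment and is no longer comparable column-for-column
    gapfree <- cumprod(vapply(res, function(r) r$nw$n_gaps == 0,
                              logical(1))) > 0
    nwsim <- vapply(res, function(r) r$nw$similarity_pct, numeric(1))
    expect_true(all(diff(nwsim[gapfree]) <= 1e-9))
    expect_gte(sum(gapfree), 10)
    expect_identical(nwsim[1], 100)
  }
})

test_that("reported percentages round half away from zero at one decimal", {
  expect_identical(round_half_up(0.25, 1), 0.3)
  expect_identical(round_half_up(84.61538, 1), 84.6)
  expect_identical(round_half_up(92.30769, 1), 92.3)
  expect_identical(round_half_up(57.25, 1), 57.3)
})
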
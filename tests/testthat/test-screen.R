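make_candidate <- function(id, L, motif_at = NULL, fill = "G") {
  chars <- rep(fill, L)
  if (!is.null(motif_at)) {
    chars[seq(motif_at, length.out = 13L)] <-
      strsplit("DYGGGGANGGHGP", "")[[1]]
  }
  precursor_records(id, paste(chars, collapse = ""))
}

verdict_for <- function(rec, hit = NULL, criteria = screen_criteria()) {
  matches <- scan_motif(rec, psy_motif_pattern())
  apply_criteria(rec, matches, hit, criteria)
}

test_that("verdicts implement the four criteria and their failure codes", {
  # all criteria met: L = 100, motif 0-based start 55 (1-based 56)
  ok <- verdict_for(make_candidate("ok", 100, motif_at = 56),
                    hit = list(evalue = 1))
  expect_true(ok$passed)
  expect_length(ok$reasons, 0)
  expect_identical(ok$motif_start, 56L)

  ev <- verdict_for(make_candidate("ev", 100, motif_at = 56),
                    hit = list(evalue = 25))
  expect_identical(ev$reasons, "EVALUE")

  short <- verdict_for(make_candidate("short", 59, motif_at = 45))
  expect_identical(short$reasons, "LENGTH")

  firsthalf <- verdict_for(make_candidate("fh", 100, motif_at = 31))
  expect_identical(firsthalf$reasons, "MOTIF_FIRST_HALF")

  nomotif <- verdict_for(make_candidate("nm", 100))
  expect_identical(nomotif$reasons, "NO_MOTIF")

  # reasons exhaustive and consistent: passed <=> no reasons
  for (v in list(ok, ev, short, firsthalf, nomotif)) {
    expect_identical(v$passed, length(v$reasons) == 0L)
    expect_false(all(c("NO_MOTIF", "MOTIF_FIRST_HALF") %in% v$reasons))
  }
})

test_that("the second-half boundary uses ceiling(L/2) on the 0-based start", {
  # L = 101: 0-based start 51 (1-based 52) is the first passing position
  expect_true(verdict_for(make_candidate("a", 101, motif_at = 52))$passed)
  expect_identical(verdict_for(make_candidate("b", 101, motif_at = 51))$reasons,
                   "MOTIF_FIRST_HALF")
  # L = 100: 0-based 50 passes, 49 does not
  expect_true(verdict_for(make_candidate("c", 100, motif_at = 51))$passed)
  expect_identical(verdict_for(make_candidate("d", 100, motif_at = 50))$reasons,
                   "MOTIF_FIRST_HALF")
})

test_that("length bounds are inclusive at 60 and 200", {
  expect_true(verdict_for(make_candidate("lo", 60, motif_at = 40))$passed)
  expect_true(verdict_for(make_candidate("hi", 200, motif_at = 150))$passed)
})

test_that("absent BLAST hit satisfies the E-value criterion vacuously", {
  v <- verdict_for(make_candidate("x", 100, motif_at = 56), hit = NULL)
  expect_true(v$passed)
})

test_that("screening a synthetic batch reproduces generator ground truth exactly", {
  gsec <- gen_precursors(sim_precursor_config(40, seed = 21,
                                              motif_half = "second"))
  gfir <- gen_precursors(sim_precursor_config(30, seed = 22,
                                              motif_half = "first"))
  gnon <- gen_precursors(sim_precursor_config(30, seed = 23,
                                              motif_half = "none"))
  recs <- precursor_records(
    id = c(paste0("s", gsec$records$id), paste0("f", gfir$records$id),
           paste0("n", gnon$records$id)),
    sequence = c(gsec$records$sequence, gfir$records$sequence,
                 gnon$records$sequence))
  truth <- rbind(gsec$truth, gfir$truth, gnon$truth)
  res <- screen_collection(recs)
  expect_identical(nrow(res$verdicts), 100L)
  # confusion matrix against ground truth is exact
  expect_identical(res$verdicts$passed, truth$expected_pass)
  expect_identical(res$verdicts$reasons, truth$expected_reasons)
  expect_identical(sum(res$verdicts$passed), 40L)

  # idempotence: re-screening the passing set passes everything
  again <- screen_collection(res$passing)
  expect_true(all(again$verdicts$passed))
})

test_that("screening is monotone in the E-value threshold", {
  set.seed(33)
  g <- gen_precursors(sim_precursor_config(30, seed = 5,
                                           motif_half = "second"))
  hits <- data.frame(subject_id = g$records$id,
                     evalue = 10^runif(30, -5, 3))
  thresholds <- c(0.01, 1, 20, 100, 1e4)
  passed_sets <- lapply(thresholds, function(t) {
    v <- screen_collection(g$records, hits = hits,
                           criteria = screen_criteria(evalue_max = t))
    v$verdicts$record_id[v$verdicts$passed]
  })
  for (k in seq_len(length(thresholds) - 1)) {
    expect_true(all(passed_sets[[k]] %in% passed_sets[[k + 1]]))
  }
})

test_that("empty input yields empty output", {
  empty <- precursor_records(character(0), character(0))
  res <- screen_collection(empty)
  expect_identical(nrow(res$passing), 0L)
  expect_identical(nrow(res$verdicts), 0L)
})
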
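---
title: "Methods: motif screening, alignment similarity and ΔΔCt analysis for the PSY family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif screening, alignment similarity and ΔΔCt analysis for the PSY family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psykit)
```

This vignette is the package's account of its methods: the models and
rules each module implements, the tunable parameters and why their
defaults are what they are, the numerical and design choices made where
conventions genuinely diverge, and what the synthetic-data generators do
and do not emulate.

## The biological objects

PSY peptides (plant peptides containing sulfated tyrosine) are small
secreted signaling peptides. Their precursors — prepropeptides of roughly
60–200 residues — carry an N-terminal hydrophobic secretion signal and,
in the second half of the sequence, a conserved 13-residue domain

```
D-Y-x-x-x-x-[AP]-N-x-x-H-x-P
```

whose Asp-Tyr opens the mature peptide and is the site of tyrosine
sulfation. Tyrosylprotein sulfotransferase prefers an acidic residue
adjacent to the acceptor tyrosine, which `sulfation_context()` encodes as:
true iff position −1 or +1 of the Y holds D or E (positions beyond the
sequence ends count as absent). Across species, five residues of the
domain are conserved — D, Y, N, H and the terminal P — which
`relaxed_psy_pattern()` captures as the same 13-position frame with only
those five constrained.

## Motif engine

`parse_pattern()` supports exactly the PROSITE subset these analyses
need: literal residues, `X`/`x` for any residue, and `[..]` classes.
Dashes are ignored as separators. Everything else in the ScanProsite
grammar (repeat counts, `{..}` exclusions, `<`/`>` anchors) is rejected
with a positioned error: silently approximating a richer pattern would
change candidate counts without warning.

Scanning is overlap-inclusive (every start position is tested
independently), matching the permissive ScanProsite behavior; screening
needs every candidate position, and downstream rules pick among them.
Two semantic decisions matter:

* matching is case-insensitive after ingest normalization;
* an `X` *in the sequence* (unknown residue) satisfies only "any"
  pattern positions, never a literal or a class — unknown residues must
  not fabricate motif hits.

All user-facing coordinates in the package are 1-based inclusive, the
native R convention; tables meant for human reading never mix
conventions.

## Homolog screening

`screen_criteria()` defaults encode the published acceptance rules for
putative PSY homologs: BLAST expect value ≤ 20 (the deliberately
permissive threshold that suits ~100-residue, weakly conserved queries),
precursor length 60–200 residues inclusive ("between 60 and 200" is read
as inclusive at both ends), a DY-anchored motif match, and the motif in
the second half of the precursor. Two operationalizations were open:

* **Second half.** A motif starting at 0-based offset `s` in a sequence
  of length `L` is in the second half iff `s >= ceiling(L/2)`; for odd
  lengths the motif must start strictly within the latter `floor(L/2)`
  residues. Some boundary had to be fixed; `ceiling` is the conservative
  choice (a motif straddling the midpoint of a 101-residue precursor does
  not count).
* **No BLAST hit supplied.** The E-value criterion is vacuously
  satisfied, so the screen runs on arbitrary FASTA without BLAST output.

Verdicts are data, not exceptions: each record gets `passed` plus an
exhaustive list of failure codes (`EVALUE`, `LENGTH`, `NO_MOTIF`,
`MOTIF_FIRST_HALF`), with `passed` true iff the list is empty.

## Pairwise alignment and the similarity table

`nw_align()` is a three-state (Gotoh) affine-gap global aligner written
in C++, with parameters fixed by the EMBOSS-needle conventions under
which the family's published similarity percentages were produced:

* BLOSUM62 (the standard NCBI half-bit matrix, shipped as a text file
  under `inst/extdata/` and cross-checked against an independently
  distributed copy in the test suite — matrix dialects differ subtly
  across toolkits);
* gap open 10, gap extend 0.5, with a gap of length *L* costing
  `open + L * extend` (the first gap column pays one extension);
* end gaps free by default (`penalize_end_gaps = FALSE`), the needle
  default;
* percent identity and percent similarity both use the full alignment
  length, gap columns included, as denominator; a column is "similar"
  when its substitution score is positive.

Determinism of the reported percentages matters because co-optimal
alignments can carry different percentages. Every argmax in the DP and
traceback uses a fixed preference — match state first, then extending the
current gap, then switching gaps; the ends-free endpoint scan prefers the
bottom-right cell, then the last column bottom-up, then the last row
right-to-left, replacing only on strict improvement. Re-running an
alignment therefore always reproduces the same strings. Note that this
makes *scores* symmetric in the argument order but not necessarily the
percentages: the mirrored problem prefers the mirrored gap state among
co-optimal alignments. The tests assert score symmetry only.

`similarity_table()` is the family-table twin: for each homolog, percent
similarity of the full precursor against the reference and of the
13-residue domain against the reference's domain, rounded half-up to one
decimal (reporting precision). Domain extraction prefers the leftmost
strict-pattern match in the second half, then the leftmost strict match,
then the same order with the relaxed pattern. On the real Arabidopsis
family the domain column is a count of positive columns out of 13
(11/13 = 84.6%, 12/13 = 92.3%), which corroborates computing it on the
13-column motif span.

## Cleavage annotation

Three subtilases with published recognition motifs are built in:

| enzyme | pattern | cut |
|---|---|---|
| SBT1.1 | `RRSLVLHTDY` (literal) | after match position 6 (`RRSLVL / HTDY`) |
| SBT6.1 | `RXLX` and `RXXL` | unknown |
| SBT3.8 | `DY` | immediately before the D (provisional) |

`X` is "any residue" with no positional context — the maximal-recall
reading of the published 4-mers. DY hits are labelled candidate
phytaspase sites, not asserted cleavages: the enzyme cleaves after
aspartate yet mature peptides begin with DY, so the exact scissile bond
is left provisional. Hits overlapping an annotated signal-peptide span
can be masked (`mask_signal`), since sites inside the leader are
biologically implausible. No positional restriction (e.g. upstream of
the PSY domain) is applied when compiling membership reports.

## Conservation census

The cross-species five-residue census is computed per sequence with the
relaxed pattern rather than from MSA columns: this makes the headline
count reproducible without replicating the exact multiple alignment an
external tool produced. For failing sequences, the missing residues are
attributed from the best partial match — the 13-residue window satisfying
the most of the five constraints, leftmost on ties — giving deterministic,
auditable failure reports (e.g. a soybean-type near-miss that carries
D, Y, N, H but lacks the terminal P). Sequences with repeated mature
peptides count once, as sequences. The MSA path (`read_msa()`,
`column_stats()`) serves figure-style per-column reporting; `.` gaps are
normalized to `-`.

## Comparative-Ct analysis

The qPCR module mirrors the published design: three biological × two
technical replicates, actin-2 as the single reference gene. Technical
replicates are averaged first; biological replicates are the units of
every inference, avoiding pseudo-replication. For gene *g* and group
*G*, `ΔCt_G = mean Ct(g, G) − mean Ct(ref, G)`, `ΔΔCt = ΔCt_treatment −
ΔCt_control`, and the fold change is `efficiency^(−ΔΔCt)`.
Amplification efficiency defaults to 2 (perfect doubling) and is a
per-call hook, as efficiencies were not reported.

Inference is a fixed-reallocation randomization test: biological
replicates, each carrying its target-minus-reference ΔCt, are reshuffled
between groups; the two-sided p-value uses the add-one correction
`p = (1 + #{|ΔΔCt*| ≥ |ΔΔCt|}) / (1 + B)`, the standard conservative
Monte-Carlo estimate, and is reproducible given a seed. A consequence of
the 3 + 3 design worth knowing: only 20 reallocations exist, so the
smallest attainable two-sided p-value is about 0.1. The null-calibration
simulation in the tests therefore uses 6 + 6 replicates, where the
permutation distribution has enough resolution for a 5% level to be
attainable at all. The uncertainty interval is a percentile bootstrap
over biological replicates resampled within groups; with three
replicates per group such an interval is crude, and its coverage is
checked in the tests at ten replicates per group where the asymptotics
have a chance.

## Synthetic data: what it emulates and what it does not

`gen_precursors()` builds sequences with the architecture the screening
rules care about: a 25-residue leader sampled with 80% probability from
the hydrophobic set {A, L, V, I, F, M, W} (a stand-in for a secretion
signal — no external signal-peptide predictor is involved anywhere), a
uniform-background body of 60–200 residues, and one instantiated motif
placed in the configured half. Rejection sampling guarantees the
recorded ground truth is exact: a "none" sequence has no motif match
anywhere, a "first-half" sequence has no accidental second-half match,
and planted cleavage sites are recovered at their coordinates with no
same-enzyme hit outside a planted span. Overlapping-pattern hits inside
a planted span are inherent — the SBT1.1 10-mer necessarily contains
SBT6.1 4-mers — and are part of the contract, not noise.

`gen_ct_table()` writes `Ct = ct_base − log_efficiency(expression) +
N(0, noise_sd)` per technical replicate, with the true ratio applied to
every treatment biological replicate. Defaults are the wet-lab design
(3 × 2, noise 0.2 cycles, efficiency 2).

What the generators do *not* emulate: evolutionary divergence (synthetic
"homologs" share a motif but not a phylogeny), compositional bias of
real propeptides, BLAST E-values derived from actual similarity, primer
efficiency differences, or inter-run qPCR batch effects. Passing tests
on synthetic data therefore demonstrate the correctness of the rules and
estimators, not the biological completeness of the screen.

`mutate_motif()` supports degradation experiments: substitutions inside
the motif span prefer residues scoring non-positively against the
original (and breaking the pattern constraint at constrained positions),
and the mutation order plus all replacements are drawn up front, so the
*k*-mutation sequence is a prefix of the *k+1* one. Column-wise, the
fraction of positive-scoring positions is non-increasing in *k* by
construction. Alignment-level percent similarity follows while the
optimal alignment stays gap-free; once heavy mutation makes gapped
alignments optimal, the percentage is computed over a longer alignment
and is no longer column-comparable — the tests assert monotonicity over
the gap-free regime.

## Problem sizes and reproducibility

The test suite and the acceptance script fix every seed. Sizes were
chosen as the smallest that make the checks meaningful rather than
ornamental: brute-force alignment enumeration on 300–520 random pairs of
length ≤ 6 (every global alignment of such pairs is enumerable
exactly), 500 random 200-residue sequences for the scanner-vs-regex
comparison, 100-candidate screening batches, 200 simulation seeds for
fold-change recovery, and 500 null tables for the type-I error of the
randomization test.

The published-value regressions (similarity percentages, per-subtilase
membership, the 31-of-32 census) run on the real UniProt sequences of
the 32 manifest homologs. Identifiers ship with the package; sequences
do not (redistribution hygiene) and are fetched once with
`fetch_accessions()`, which records fetch dates and checksums because
UniProt entries are versioned. Until that cache exists the regression
tests fail with a message saying exactly that.

## Known limitations

* The pattern language is the used subset of PROSITE, by design.
* Percent-similarity values of co-optimal alignments are tie-break
  dependent; a different (equally valid) tie-break can change a printed
  percentage while the score is unchanged.
* The SBT3.8 scissile position is provisional, and SBT6.1 motifs carry
  no positional context, so cleavage reports are candidate inventories,
  not proteolysis predictions.
* Single-reference-gene normalization only; multi-reference geometric
  means are out of scope.
* With three biological replicates the randomization test cannot reach
  p < 0.1; that is a property of the design, not the implementation.
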
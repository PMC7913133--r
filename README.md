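# psykit

Offline analysis toolkit for the **PSY peptide family** — the small
secreted plant signaling peptides carrying a sulfated tyrosine (PSY1–8 in
*Arabidopsis thaliana*, with homologs across higher plants and mosses).

Mature PSY peptides derive from 60–200-residue prepropeptides: an
N-terminal secretion signal, a variable propeptide, and a conserved
13-residue domain matching the PROSITE-style pattern

```
D-Y-x-x-x-x-[AP]-N-x-x-H-x-P
```

anchored on the Asp-Tyr tyrosine-sulfation site. The package implements
the computational analyses that characterize this family, each as plain R
functions:

* **Motif engine** — a PROSITE-subset pattern parser and overlap-inclusive
  scanner (literals, `X`, `[..]` classes), the strict PSY pattern, its
  relaxed five-residue variant (D, Y, N, H, P only), and the
  tyrosine-sulfation context rule (acidic residue at −1/+1 of the
  acceptor Y).
* **Homolog screening** — the acceptance criteria for putative homologs
  from BLAST output: expect value ≤ 20, precursor length 60–200 aa, a
  DY-anchored motif located in the second half of the precursor; verdicts
  carry explicit failure codes.
* **Pairwise alignment** — affine-gap Needleman–Wunsch (three-state
  Gotoh DP, in C++) with EMBOSS-needle conventions: BLOSUM62, gap open
  10, gap extend 0.5, free end gaps, percent identity/similarity over the
  full alignment length, similarity = columns with positive substitution
  score. Builds the homolog-vs-reference similarity table (full precursor
  and domain-only columns).
* **Cleavage annotation** — subtilase recognition motifs: SBT1.1
  (`RRSLVL/HTDY`), SBT6.1 (`RXLX`, `RXXL`), and the candidate phytaspase
  site SBT3.8 (`DY`), with per-enzyme membership reports.
* **Conservation** — the five-residue census across homolog collections
  (with missing-residue attribution) and per-column statistics of an
  externally built MSA (aligned FASTA or Clustal).
* **qPCR ΔΔCt** — comparative-Ct relative expression normalized to
  actin-2 (`ratio = efficiency^(−ΔΔCt)`), with a REST-style
  fixed-reallocation randomization test and a percentile bootstrap
  interval over biological replicates.
* **Synthetic data** — generators for prepropeptide-like sequences
  (hydrophobic leader, placed motif, planted cleavage sites) and
  replicate-structured Ct tables, all with recorded ground truth, so the
  whole pipeline runs and is testable without downloads.

## Worked example

Screen a synthetic candidate pool with known ground truth and quantify a
simulated qPCR experiment (`analysis/01_simulate_screen.R`,
`analysis/05_qpcr_ddct.R`):

```r
library(psykit)
pool <- gen_precursors(sim_precursor_config(40, seed = 101, motif_half = "second"))
scr  <- screen_collection(pool$records)
sum(scr$verdicts$passed)
#> [1] 40

sim <- gen_ct_table(sim_ct_config(genes = c(PSY3 = 6, PSY4 = 4, PSY2 = 0.5, PSY7 = 1),
                                  seed = 2024))
ddct_analysis(sim$table, "PSY4", "treated", "control", seed = 7)
```

The full driver prints, per gene, the estimated fold change against the
simulated truth:

```
 gene true_ratio ratio   ddct p_value ci_low ci_high
 PSY3        6.0 4.954 -2.309  0.0995  3.867   6.346
 PSY4        4.0 3.153 -1.657  0.0995  2.803   3.552
 PSY2        0.5 0.414  1.272  0.0995  0.325   0.562
 PSY7        1.0 0.858  0.222  0.4098  0.669   1.100
```

`ratio` is the treated-vs-control fold change after actin-2
normalization; `p_value` comes from reallocating biological replicates
between groups (with 3 vs 3 replicates its smallest attainable two-sided
value is ≈ 0.1, so the design bounds the evidence a single experiment can
give); `ci_low`/`ci_high` is the 95% percentile bootstrap interval.

The numbered scripts under `analysis/` run the remaining stages
(similarity table, cleavage report, conservation census) and write their
tables under `results/`. They use the real UniProt sequences of the 32
manifest homologs when a local cache exists — populate it once, with
network access, via `analysis/00_fetch_uniprot.R` — and otherwise fall
back to clearly labelled synthetic families so every step runs offline.

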
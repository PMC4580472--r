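---
title: "Methods: small RNA discovery and differential expression in dinomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA discovery and differential expression in dinomir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dinomir implements a genome-free miRNA analysis for two small RNA libraries
(conditions A and B, e.g. lag vs logarithmic growth phase of an algal batch
culture) over a transcriptome assembly. This vignette describes each stage's
model, its parameters and their rationale, and the numerical and design
decisions that shape the results.

```{r setup}
library(dinomir)
```

## 1. Read cleaning (`classify_and_filter`)

Platform reads are insert + 3′ adapter, truncated to the read length. Per
read, `trim_adapter()` removes the leftmost full adapter occurrence; when the
read ends inside the adapter, the longest read suffix equal to an adapter
prefix (at least `min_overlap = 6` nt, short enough to catch run-ins, long
enough to make chance matches rare at ~4^-6) is removed instead.

Reads are then assigned to exactly one category, in fixed precedence:

1. **3ADT&length filter** — trimmed length outside the 18–25 nt analysis
   window (the mature-miRNA size range), or no adapter found and the raw
   length outside the 15–40 nt insert-selection window;
2. **Junk** — any remaining read containing `N`, or whose longest poly(A)
   run covers ≥ 80 % of its length;
3. **Clean** — everything else, collapsed to unique sequences with
   per-library counts.

Because the categories form a strict partition, the accounting rows always
sum to the raw totals — an invariant the tests rely on. (The data source
this package emulates reported overlapping categories; the partition is a
deliberate divergence that makes the accounting checkable.)

## 2. Annotation (`annotate_reads`)

**Contaminants.** A unique read belongs to the first class, in the fixed
order rRNA → tRNA → snoRNA → snRNA → other Rfam → repeats, in which it
occurs as an exact substring of a reference sequence on either strand.
Exact substring matching is the appropriate model for short fragments of
long, well-conserved structural RNAs.

**Known miRNAs.** Each remaining read is aligned against every catalog
mature under end shifts of up to 2 nt per side; an alignment is accepted
when the Hamming distance over the overlap is ≤ 1. The best hit is chosen
by (fewest substitutions, smallest total absolute shift, species priority,
name). Variants are recorded with a compact suffix grammar on the detected
read: `_L±n` / `_R±n` for end shifts and `_1ss<pos><refBase><readBase>` for
the single substitution, e.g. `tae-miR159a_L-1_1ss11GC`. Families collapse
names to `miR` + the leading integer (`zma-miR169f-5p` → `miR169`).

## 3. Folding and the hairpin criteria (`fold_rna`, `evaluate_hairpin`)

Candidate precursor windows are folded with a Nussinov-style maximum
weighted base-pairing dynamic program: pair scores AT = 2, GC = 3, GT = 1
(wobble), a +1 bonus for stacking on an adjacent pair, minimum hairpin loop
3 nt, deterministic traceback. The reported "energy" is a pseudo-energy,
−score/2 kcal/mol — a monotone stand-in calibrated so that designed stable
stems land in the realistic −20…−100 kcal/mol range. This is a deliberate
choice: a thermodynamic nearest-neighbor model would add a large parameter
table without changing any downstream decision, because every acceptance
rule is a threshold on structure topology or on a monotone stability score.
Externally computed structures (e.g. RNAfold output) can be supplied in
Vienna format via `read_vienna()` and bypass the internal folder entirely,
including its 50–400 nt length bounds.

A candidate's structure is decomposed into the stem chain enclosing the
hairpin loop that maximizes overlap with the mature read. Unpaired runs at
each stem interface are split into a symmetric part (`min` of the two arms'
gaps — "errors", i.e. mismatched opposite bases) and the asymmetric excess
("biased" bulge nucleotides on one arm). Eleven criteria are then applied:

| criterion | threshold |
|---|---|
| largest stem bulge | ≤ 12 nt |
| stem size | ≥ 16 bp |
| folding energy | ≤ −15 kcal/mol |
| hairpin length | ≥ 50 nt |
| loop length | ≤ 200 nt |
| largest mature-region bulge | ≤ 4 nt |
| biased (one-arm) nt in mature | ≤ 4 |
| biased bulges touching mature | ≤ 2 |
| mismatched (error) nt in mature | ≤ 2 |
| paired mature positions | ≥ 12 bp |
| mature inside stem arms | ≥ 80 % |

All eleven must pass. Windows are the three spans
`[start−60, end]`, `[start, end+60]`, `[start−60, end+60]` around the
mapped read, truncated at contig bounds; among accepted windows the lowest
energy (then shortest) candidate is kept.

## 4. Differential expression (`de_table`)

Counts are normalized per million clean reads. The fold change is
`log2(norm_A / norm_B)`, with ±∞ when one side is zero (present in only one
library) and records zero in both libraries dropped. Significance of the
2×2 table `[[a, La−a], [b, Lb−b]]` is assessed with both the two-sided
Fisher exact test and the 1-df chi-square test without continuity
correction; the gating p value is the chi-square p when all four expected
cells are ≥ 5 (the classical validity rule), otherwise the Fisher p.
Bonferroni-adjusted p values are reported alongside, but the default DE
call uses the raw gate p — matching the convention of the printed tables
this package mirrors. A record is differentially expressed iff
|log2FC| > 1 **and** p < 0.05, direction = sign; p < 0.01 marks a stricter
tier.

## 5. Enrichment (`enrich`) and qPCR (`ddct`)

Term enrichment of a predicted target-gene list uses the upper-tail
hypergeometric probability evaluated from its explicit finite sum via
log-binomials (`lchoose`), which is exact to double precision at
desk-scale `N` — note "exact" here is absolute, not relative: tails below
~1e-12 cancel against 1. The equivalent one-sided Fisher exact test is
computed alongside as a cross-check; the tests verify their agreement
exhaustively at small `N`.

qPCR relative expression is the comparative-threshold method:
`ΔCt = Ct(target) − Ct(reference)` per sample,
`ΔΔCt = ΔCt(sample) − ΔCt(calibrator)`, relative expression `2^−ΔΔCt`, the
standard error propagated from replicate variances by the delta method, and
a two-sided paired t test on per-replicate ΔCt values for the `*`/`**`
tiers.

## 6. The synthetic generator (`sim_config`, `generate_reference`)

The generator emulates the *shape* of a two-condition small RNA experiment,
not its scale: a toy transcriptome (default 8 contigs × 600 nt), 12 planted
miRNAs whose between-library ratios mirror the magnitudes seen in the
motivating dataset (log2 ratios from −2.06 to 1.79, plus one
present-in-A-only and one present-in-B-only sentinel), contaminant
references, poly(A)/N junk, and out-of-window reads, at 20 000 reads per
library.

Each planted precursor is a designed perfect stem-loop

```
[flank][mature]  [12 nt loop]  [revcomp(mature)][revcomp(flank)]
```

with 48 nt arms (so the precursor is always 108 nt). Two properties make
recovery deterministic rather than statistical:

- the right-hand extraction window `[mature_start, mature_end+60]` equals
  mature + loop + 3′ arm *exactly*, and
- the loop is drawn from {A,C} (which cannot pair with itself) while the 3′
  tail alphabet is chosen so it can pair neither with itself nor with the
  first mature base — under maximum base pairing the designed stem is
  provably the optimal structure of that window.

Hence in deterministic mode the pipeline's recall of planted novel miRNAs
is exactly 1, an acceptance property of the package.

One consequence worth knowing: the two libraries' totals are *not*
rebalanced, so per-million normalization against unequal compositions
shifts every recovered log2 fold change by a constant
(`log2` of the library-share ratio) relative to the planted ratio. Planted
*signs* are preserved at the default settings, and that is what the tests
assert; magnitude recovery would require composition-matched libraries,
which real experiments do not have either.

## 7. Reproducibility

Every stochastic step is governed by a single integer seed
(`sim_config(seed = …)`); a rerun with the same seed and configuration is
byte-identical, including all files written by `write_simulation()` and
`run_pipeline(outdir = …)`. The run manifest (JSON) records the package
version, seed and every stage parameter.
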
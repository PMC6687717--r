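---
title: "Discovering public TCR clonotypes with pubtcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering public TCR clonotypes with pubtcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pubtcr)
```

## The problem

In T-cell-mediated drug hypersensitivity — most dramatically Stevens–Johnson
syndrome and toxic epidermal necrolysis (SJS/TEN) — the lymphocytes that
infiltrate the skin lesion are dominated by a small number of expanded T-cell
clones. When unrelated patients reacting to the *same* drug carry the *same*
T-cell receptor rearrangement, that clonotype is called **public**, and it is
strong evidence that the receptor itself participates in drug recognition.
`pubtcr` implements the desk side of that discovery: turning sequencing reads
into clonotype tables, quantifying V/J gene usage, and scanning case and
control repertoires for clonotypes that recur across every affected patient
while staying absent from tolerant and healthy controls.

A clonotype here is the triple (V gene, J gene, CDR3 amino-acid sequence).
The CDR3 — the hypervariable loop spanning the V(D)J junction — is the
principal determinant of antigen specificity, so identity of all three fields
across individuals is a stringent notion of "the same receptor".

## CDR3 extraction

Reads are modelled as a V-segment 3' end, junction nucleotides, and a
J-segment 5' start. Extraction proceeds in two steps:

1. **Segment assignment** (`assign_segments()`): every germline V is scored
   by the identity fraction of its terminal-suffix alignment against the
   read, anchored at each candidate V-end position; J segments symmetrically
   by anchored prefix alignment. Both calls must reach `min_identity`
   (default 0.9, over at least 15 aligned bases); otherwise the read is
   reported `unassigned` — an outcome, not an error. Ties between segments
   break to the lexicographically smallest gene name, and within a segment
   to the longest extension, both purely for determinism.
2. **Junction extraction** (`extract_cdr3()`): the read is translated in the
   frame propagated from the assigned V segment's reading-frame offset. The
   CDR3 comprises all residues strictly between the conserved cysteine of
   the *rightmost* `Y[YFLI]C` within the translated V region (plus two
   residues of slack) and the F/W of the *leftmost* `[FW]GXGT` after it.
   Both anchors are excluded, so the reported string carries neither the
   canonical leading C nor the J-motif F/W. Rightmost-V/leftmost-J is the
   innermost-anchor rule: it minimises spurious long junctions when motif
   look-alikes occur elsewhere in the segments.

A junction is **productive** when the translated span through the J motif is
stop-free and the CDR3 consists of standard residues. Frequencies use the
productive-assigned-read denominator: they are fractions of reported TCR
reads. The alternative (all input reads) is auditable from the per-read
outcome table attached to every `build_clonotype_table()` result, which
conserves `productive + nonproductive + unassigned + motif failures = reads in`.

## Repertoire statistics

* `usage_vector()` — per-gene count fractions; always sums to 1.
* `normalize_to_cohort()` — per-gene fold change over the mean usage of a
  control cohort, the usual way case repertoires are displayed against
  healthy-donor PBMC. The pseudocount default, half a read at the deepest
  involved library, keeps fold changes finite below one-read resolution.
  A log10 scale is available; usage heatmaps typically clip at ±2 because
  drug-associated V genes show 10- to 100-fold elevations.
* `vj_pairing_matrix()` / `cohort_mean_pairing()` — joint V–J frequencies
  whose margins reproduce the usage vectors by construction; the cohort mean
  aligns gene axes by union with zero fill and still sums to 1.
* `usage_pca()` — column-centred SVD of the samples × genes usage matrix.
  We deliberately decompose raw frequencies without unit-variance scaling:
  usage vectors are already compositional fractions on a common scale, and
  scaling would inflate rare genes. This is a genuine design choice — fold
  changes or log frequencies are defensible alternatives — so the scores
  should be read as "dominant usage contrasts", not as a canonical embedding.
* `qpcr_ratio()` — the 2^−ΔCt expression ratio of a clonotype-specific assay
  against a CD3 reference, floored at the assay detection limit 1e-4, with
  no efficiency correction (none is identifiable from Ct pairs alone).

Reported percentages round half-up to two decimals (`round_half_up()`), the
printed precision of clinical clonotype tables; R's default half-to-even
rounding would turn 3.995 % into 3.99 % rather than 4.00 %.

## Public-clonotype detection

`detect_public()` flags a clonotype as public when it is present at
`min_case_freq` or more in at least `min_case_fraction` of case samples and
its maximum control frequency is strictly below `max_control_freq`. The
defaults — all case samples, ≥ 1 % per case, < 0.001 % in every control —
encode the stringent situation of an expanded, strictly case-restricted
clone: the lowest per-case frequency worth calling "expanded" in a blister
repertoire is around a percent, and 0.001 % is the practical floor at which
deep control libraries would still register a single read. "Present in a
control" means one read or more; absence contributes frequency 0, not
missing. All three thresholds are explicit arguments, and the flag is
provably monotone in them (tested). A CDR3-only key mode exists because
cross-donor frequency look-ups are often CDR3-level.

`cdr3_cluster()` builds the one-residue neighbourhood of a seed CDR3:
equal length, Hamming distance ≤ 1, substitutions only. Requiring equal
length keeps "one amino-acid difference" unambiguous; indel variants are a
different biological statement. The seed is counted in the cluster
frequency when present.

`clonotype_group_contrast()` compares a clonotype's per-sample frequencies
across groups with Welch's unpaired two-sided t-test. Welch rather than the
pooled-variance Student test because case and control frequency variances
differ by construction; degenerate inputs (zero variance, singleton groups)
return the limiting values or missing entries instead of erroring.

## The simulator

`simulate_cohort()` generates the study conditions every test runs under:

* **Design**: 7 blister-cell cases, 11 case PBMC, 12 tolerant controls and
  44 healthy donors (`paper_like_design()`).
* **Spike-ins**: the public clonotype ASSLAGELF (TRBV12-4/TRBJ2-2) planted
  at per-case blister frequencies 3.73, 19.39, 6.64, 42.85, 17.41, 1.08 and
  4.00 %, 1.31 % in case PBMC, and absent from controls. Spike counts are
  fixed by half-up rounding of frequency × depth, not sampled, so
  printed-table-style checks are exact.
* **Background**: 20 000 clonotypes per sample with lognormal(0, 1)
  abundance weights and multinomial read sampling at depth 1e5. The
  richness matches what a deep bulk TCRβ library actually contains, and at
  this clone count the generator's clone-sampling noise sits at the
  read-sampling (binomial) level, which is the scale on which recovered
  usage is validated. Clonal dominance in cases is carried by the
  spike-ins, not by the background tail.
* **Usage skew**: per-group V/J sampling multipliers derived from target
  cohort means (blister TRBV12-4 31.62 %, TRBJ2-2 22.15 %; case PBMC
  TRBV12-4 4.95 %; tolerant 0.69 %) after subtracting the spike
  contribution, via `skew_multiplier()`.
* **Reads**: at `level = "reads"` each clonotype becomes V-suffix +
  junction codons (fixed first-codon encoding, for determinism) + J-prefix,
  with independent per-base substitution errors. Simulated V segments end
  in-frame with a `Y[YFLI]C` codon suffix and J segments open with
  `[FW]GXGT`, so extraction can never fail on a planted read for motif
  reasons. Background CDR3s are rejection-sampled away from anchor
  look-alikes and from the Hamming-1 neighbourhood of any spike, keeping
  cluster tests unambiguous.

At `error_rate = 0` the read level and the counts level (`level =
"counts"`, clonotype tables drawn directly) are interchangeable through the
pipeline — the round-trip tests verify exact equality of tabulated counts
with the generator truth. Analyses that only need tables therefore run at
counts level: the full 63-sample cohort at depth 1e5 is generated that way,
while read-level extraction is exercised on 10 000-read samples, sizes at
which the whole suite completes in a few minutes on one core.

What the simulator does **not** emulate: VDJ recombination realism
(trimming/insertion profiles, D segments), sequencing-quality models,
shared low-frequency background clonotypes between individuals, or
biological covariation between V usage and CDR3 sequence. Passing tests
therefore demonstrate the correctness of the arithmetic and the detection
logic under controlled truth — not that real repertoires satisfy the
detection thresholds.

## Numerical and degenerate-input conventions

* Half-up rounding everywhere a percentage is printed.
* Segment/alignment ties: smallest gene name, then longest extension.
* PCA of identical samples reports zero explained variance (no 0/0).
* `t` statistics on zero-variance data: 0 with p = 1 when means agree,
  ±Inf with p = 0 otherwise; singleton groups yield missing entries.
* Empty repertoires (no productive reads, all-zero counts) raise classed
  validation errors; unassignable reads never do.
* Usage-vector sums, pairing-matrix sums and treemap mass are conserved to
  1e-9; marginal consistency of the pairing matrix holds to double
  precision.

## Known limitations

The aligner is a fixed-anchor identity scorer, adequate for amplicon-style
reads flanked by known segments; it does not handle indels, D segments or
chimeric reads. The productive-only denominator is a convention; published
frequency tables rarely state theirs, and comparisons across conventions
can differ by the nonproductive fraction. One printed cohort mean cannot be
reproduced beyond rounding: the mean of the seven per-case public-clonotype
frequencies computes to 13.59 %, while 13.57 % is sometimes quoted; the
package reports the computed value.

## A minimal end-to-end run

```{r, eval = FALSE}
pl <- paper_like_config(seed = 1)
cohort <- simulate_cohort(pl$config, pl$design, level = "counts")
report <- detect_public(
  cohort$tables[cohort$design$group == "case_blister"],
  cohort$tables[cohort$design$cohort != "case"])
report[report$is_public, ]
```
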
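---
title: "Screening proteomes for classical AGPs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening proteomes for classical AGPs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agpscreen)
```

## The screen

Classical arabinogalactan proteins share no conserved domain; they are
recognised from precursor sequence by the conjunction of three
criteria, all of which `agpscreen` evaluates jointly for every protein:

* **Composition.** The PAST percentage — residues that are Pro, Ala,
  Ser or Thr, as a percentage of the region length — must be at least
  50 (inclusive: "at least" is a `>=`).  Unknown residues (`X`) count
  in the denominator only, a deliberately conservative choice: missing
  sequence can lower a score but never raise one.
* **Signal peptide.** Classical AGPs are secreted; a protein without a
  signal-peptide call is rejected with reason `no_signal_peptide`.
* **Dipeptide repeats.** At least `min_repeats` occurrences of AP, PA,
  SP or TP must start within the mature region.  Overlapping matches
  are all counted ("APA" contains both AP and PA): AGP glycomodules are
  overlap-dense and non-overlapping counting would systematically
  undercount exactly the true positives.

Because the three criteria are scored jointly rather than as a
short-circuiting funnel, the `reasons` column of a report is complete:
a protein failing two criteria lists both, which makes the screen's
behaviour auditable from the report alone.

### Mature versus precursor composition

When a signal peptide is called at position $p$, the mature region is
$[p+1, n]$ and both composition and repeats are evaluated there by
default.  The rationale: the signal peptide is removed in vivo, and its
hydrophobic core would dilute the PAST percentage of short proteins by
several points.  The alternative reading — a composition screen on the
full precursor *before* any signal-peptide logic — is equally defensible
as a two-stage pipeline, so it is preserved behind
`scan_params(use_precursor = TRUE)` (CLI flag
`--precursor-composition`).  On the synthetic benchmark the two modes
agree, because planted mature regions sit far above the threshold.

### The signal-peptide heuristic

External neural-network predictors are the field standard, but they are
web services.  To keep the pipeline self-contained and deterministic,
`predict_signal_peptide()` implements the textbook tripartite
architecture as four explicit rules on the precursor:

1. residue 1 is the initiator Met;
2. at least one Lys/Arg at positions 2–6 (the positively charged
   n-region);
3. some 8-residue window within positions 4–26 has mean Kyte–Doolittle
   hydropathy ≥ 1.6 (the h-region core);
4. a cleavage position $p$ with $15 \le p \le 34$, at least two
   residues downstream of the leftmost qualifying h-window, whose −3
   and −1 positions (sequence positions $p-2$ and $p$, with $p$ the
   last signal-peptide residue) are both small
   (A, G, S, C, T, V) — the von Heijne (−3, −1) rule.  The smallest
   qualifying $p$ is reported.

Sequences shorter than 15 residues are called absent, not an error.
The window width (8), hydropathy threshold (1.6), position bounds and
residue sets are package defaults exposed in `sigpep_params()`; they
were fixed once from the signal-peptide literature, not tuned.  `X`
residues take hydropathy 0 (neutral).  This rule set is a deliberately
transparent stand-in, not a re-implementation of any published
predictor; for real analyses, predictor output imported with
`load_external_calls()` overrides the heuristic per protein id.

### Defaults and units

| Parameter | Default | Units | Why |
|---|---|---|---|
| `past_threshold` | 50 | % of region residues | the classical composition criterion; inclusive |
| `min_repeats` | 4 | motif hits | the classical criterion fixes no count; 4 separates planted AGPs from every decoy class while staying permissive; configurable |
| `motifs` | AP, PA, SP, TP | — | the classical AGP glycomodule dipeptides |
| `max_gap_fraction` | 0.20 | fraction of rows | columns with ≥ 20 % gaps are removed; inclusive at the threshold |
| `gap_open`, `gap_extend` | 10, 1 | score units | conventional protein-alignment penalties with BLOSUM62 |

## Alignment utilities

`needleman_wunsch()` is a three-state Gotoh dynamic program over a
substitution matrix (BLOSUM62 by default, via Biostrings).  A gap run
of length $L$ costs `gap_open + L * gap_extend`; switching gap
orientation re-pays the opening cost.  This is the same convention as
`Biostrings::pairwiseAlignment`, and the test suite cross-checks scores
against both that implementation and an exhaustive enumeration of all
global alignments on short pairs.  Traceback is deterministic: on score
ties, diagonal is preferred over a vertical gap, which is preferred
over a horizontal gap; among states feeding a cell the same order
applies.  Ungapped single-cell problems and empty inputs are the
degenerate cases: the former reduces to one matrix lookup, the latter
is a configuration error.

One consequence of deterministic tie-breaking is worth stating: when a
pair has several optimal alignments, aligning (a, b) and (b, a) can
select mirror-image alignments whose *identities* differ even though
their *scores* are equal.  The score is symmetric; the identity of the
reported alignment is symmetric only when the optimum is unique.  The
tests therefore assert score symmetry, and assert that percent identity
is invariant under swapping the rows of a fixed alignment.

`percent_identity()` exposes both common denominators — identical
columns over non-gap aligned columns (default), or over the shorter
ungapped sequence — because published family-identity figures rarely
state which was used and the two can differ by several points on gappy
pairs.

`trim_gappy_columns()` removes a column iff its gap fraction is **at or
above** the threshold (`>= 20 %` removes a 1-gap column in a 5-row
alignment).  The operation is idempotent and preserves column order and
row ids.  Only `-` is accepted as a gap; `.` marks a different
alignment dialect and is rejected on import with a message.

`nearest_reference_grouping()` assigns each query to the reference of
maximal percent identity, ties broken by reference input order, making
the grouping invariant under query-order permutation.

## Coordinates

All positions are 1-based and intervals closed, the convention of base
R and Bioconductor (IRanges, Biostrings).  A motif hit at `start = 1`
covers residues 1 and 2; a cleavage position is the 1-based index of
the last signal-peptide residue.

## The synthetic benchmark

`generate_proteome()` draws, under a single integer seed restored on
exit (the caller's RNG stream is untouched):

* **background** proteins, 100–400 residues, i.i.d. from an embedded
  average-proteome frequency table whose PAST mass is ≈ 25 % — far
  enough below threshold that a background protein essentially never
  satisfies all three criteria jointly;
* **planted AGPs**: a signal peptide built to the heuristic's template
  (M + two basic residues + an 8–12 residue L/I/F run + a `xAyA`
  c-region, which the heuristic cleaves exactly at its final A, because
  L, I and F never satisfy the small-residue rule earlier), followed by
  a 120-residue mature region with PAST fraction drawn in [0.6, 0.85]
  and 6 planted motifs — two more than the classifier requires;
* **decoys**, each violating exactly one criterion: `decoy_no_sp`
  (mature-like body, first residue forced non-M), `decoy_low_past`
  (signal peptide and repeats, background-level PAST) and
  `decoy_no_repeats` (signal peptide and a pure-PAST mature region of
  homopolymer runs P…S…T…A whose junctions PS, ST, TA form none of the
  four motifs).

Composition fillers use exact residue counts (a fixed number of PAST
residues at shuffled positions) rather than per-residue coin flips, so
each planted class meets or violates its criterion deterministically,
not merely in expectation — the planted-truth recovery checks
(precision = recall = 1) are exact correctness tests of the
generator/classifier pair, not statistical ones.

What the generator does **not** emulate: real amino-acid autocorrelation,
gene families and paralogy, chimeric or borderline AGPs (AG peptides,
fasciclin-like AGPs, extensins), GPI anchors, and realistic
signal-peptide diversity beyond the heuristic's template.  Perfect
recovery on synthetic data therefore demonstrates that the classifier
implements its stated rules exactly — it says nothing about sensitivity
or specificity on a real proteome, where the signal-peptide call in
particular should come from a dedicated predictor via
`load_external_calls()`.

## Problem sizes in the tests

The suite exercises the scanner against a brute-force oracle on 1,000
random sequences (lengths 2–500), the aligner against exhaustive
alignment enumeration on 200 random pairs of length ≤ 6, trimming
against per-column recounts on 100 random 5–20 × 50 alignments, and
grouping against all-pairs maximisation on 5 × 5 instances; the
end-to-end benchmark is 200 background + 20 AGP + 30 decoy sequences.
These sizes make the whole suite run in well under a minute while
keeping every oracle exhaustive on its instance.

## Known limitations

* The built-in signal-peptide rule is intentionally simple; its
  false-negative rate on real secreted proteins is unknown and it
  should not be used as a predictor of record.
* No AGP subclassification (AG peptides, lysine-rich AGPs,
  fasciclin-like AGPs) and no GPI-anchor screening.
* Multiple-alignment *construction* is out of scope; `read_alignment()`
  imports alignments produced elsewhere.
* Pure-R dynamic programming aligns typical protein pairs in
  milliseconds to seconds; it is not intended for all-vs-all scans of
  whole proteomes.
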
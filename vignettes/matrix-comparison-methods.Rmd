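---
title: "Methods: alignment scoring, metrics and design choices in matcompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment scoring, metrics and design choices in matcompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matcompare)
```

## What the package computes

`matcompare` takes one *pattern*/*subject* pair of protein sequences and a
set of scoring configurations — each a substitution matrix bound to affine
gap penalties — and produces, per configuration, an optimal pairwise
alignment plus everything needed to compare configurations: score, four
percent-identity variants, per-column annotation, and search results. This
vignette records the model, the numerical conventions, and the design
decisions that were genuinely open.

## Substitution model

A substitution matrix stores log-odds scores
$s_{ij} = \ln\!\big(q_{ij} / (p_i p_j)\big) / \lambda$
with observed pair frequencies $q_{ij}$, background frequencies $p_i$, and a
positive scaling constant $\lambda$ that only changes the logarithm base.
`log_odds_matrix()` implements exactly this map from a `frequency_model`;
its tests verify the closed form ($q_{ij} = p_i p_j \Rightarrow s \equiv 0$),
linearity in $1/\lambda$, and invertibility
($q_{ij} = e^{\lambda s_{ij}} p_i p_j$) to $10^{-12}$.

A substitution is called **conservative** when $s_{ij} > 0$ and
**non-conservative** when $s_{ij} < 0$. A score of exactly zero does not fit
either published definition; rather than silently binning it we report a
third class, `neutral`. Residue–gap columns have no log-odds value and are
reported as `undefined` (`NA` in data frames).

The ten bundled matrices (PAM30/40/70/120/250, BLOSUM45/50/62/80/100) carry
NCBI-standard integer values as plain-text files in the NCBI flat dialect:
`#` comments, a header row of residue codes, then one labelled row per code.
Custom matrices use the same dialect, so published matrix files drop in
unchanged. Symmetry is enforced on load (tolerance $10^{-9}$); an optional
flag symmetrizes by averaging instead, because silently accepting an
asymmetric file usually hides a transcription bug. Real-valued cells are
allowed; nothing in the scoring pipeline assumes integers.

## Gap model and the five modes

A gap run of length $L$ costs `gap_open + L * gap_extend`; both penalties
are non-positive numbers *added* to the score, and the first gap column pays
both. Positive inputs are negated with a warning — this convention has to be
pinned because it changes every score. Penalties enter through
`matrix_config()` or the master file, whose one-line-per-matrix format
(`filename gap_open gap_extend`, repeated filenames allowed) labels
configurations `CM0`, `CM1`, ... in file order.

Alignment uses three-state (substitution / gap-in-subject / gap-in-pattern)
dynamic programming with affine gap recurrences, full matrices kept: inputs
are protein-scale and the contract is optimality, not speed. The rows are
filled vectorised; the gap-in-pattern state, which depends on its own row,
is resolved with a running-maximum (cummax) formulation, so the fill is
$O(nm)$ with $O(n)$ interpreted steps. Mode differences are confined to
border initialisation and the set of admissible traceback origins:

| mode | pattern | subject | end gaps |
|---|---|---|---|
| `global` | whole | whole | charged |
| `local` | substring | substring | (no terminal gaps; score floored at 0) |
| `overlap` | whole | whole | leading and trailing run free |
| `global_local` | whole | substring | charged inside the aligned region |
| `local_global` | substring | whole | charged inside the aligned region |

Two conventions here were open and are worth stating:

* **Mixed-mode orientation.** `global_local` aligns the *entire pattern*
  against a contiguous substring of the subject; `local_global` the entire
  subject against a substring of the pattern. The two are easily swapped;
  this orientation follows the de facto semantics of the widely used
  Bioconductor aligner, and the identity
  `global_local(p, s) == local_global(s, p)` is property-tested.
* **Overlap free ends.** Exactly one leading and one trailing gap run are
  free (the standard ends-free initialisation: zero first row/column, best
  over last row/column). A hypothetical "mixed" free prefix with gaps in
  both strings is not admissible. The enumeration oracle charges paths under
  the identical convention, so both routes test the same stated world.

**Tie-breaking.** Traceback prefers diagonal over gap-in-subject over
gap-in-pattern, and among equal-scoring origin cells takes the earliest in a
fixed scan order (for local mode: smallest subject position, then smallest
pattern position). Exactly one optimal alignment is reported; counting
co-optima is out of scope. In local mode a chain value of zero always
terminates the alignment, so zero-scoring prefixes are never glued on.

**Degenerate inputs.** Empty sequences are rejected. A local alignment with
no positive-scoring residue pair is reported as an *empty* alignment with
score 0 and `NA` coordinate ranges — the Smith–Waterman floor — and is the
one case where aligned strings may have length zero. Floating-point
comparisons in traceback use a relative tolerance of $10^{-9}$; scores are
sums of matrix entries and penalties, so ties at this tolerance are exact
ties in practice.

## The enumeration oracle

`enumerate_best_score()` is part of the public API because it is the
package's primary verification surface. It enumerates every admissible
alignment as a monotone move path (substitution / consume-pattern /
consume-subject; gap/gap columns are impossible by construction), scores
each path by direct column accounting, and returns the maximum. Substring
modes enumerate substring choices explicitly. It shares nothing with the
Gotoh recurrences — no cell ever stores a partial optimum — and refuses
instances above $49$ cells, since path counts grow like the Delannoy
numbers. The acceptance suite checks DP-vs-oracle equality on 200 random
instances across all five modes; an independent third route
(`Biostrings::pairwiseAlignment`) is cross-checked in the unit tests.

## Percent identity

All four variants share the numerator (columns with equal residues; identity
is exact equality after uppercasing, and in lenient mode an `X`–`X` column
does count) and differ in the denominator:

* **PID1** — aligned columns plus *internal* gap columns. "Internal"
  excludes gap runs touching either end of the alignment; this follows the
  PID literature that distinguishes internal from terminal gaps, and it is
  isolated in one helper because it is the one place where conventions
  differ between tools.
* **PID2** — aligned columns only. Hence `pid2 >= pid1` always.
* **PID3** — ungapped length of the shorter *input* sequence.
* **PID4** — mean ungapped input length. Hence `pid3 >= pid4` always.

PID3/PID4 use the original input lengths carried on the alignment object,
not the clipped aligned ranges — for local-type modes the two differ.
Empty alignments score 0 on all four. Values are kept at full precision;
only the TSV/HTML renderers round (2 decimals).

## Classification

Seven classification schemes (hydropathy, volume, chemical, charge,
hydrogen donor/acceptor, polarity, and a combined physicochemical scheme
with singleton groups G, F, P, W, Y) ship as an editable TSV transcribed
from the IMGT-style published grouping. Each scheme must partition the 20
standard residues; the partition is enforced on load, and non-standard
residues (and gaps) classify as `unclassified`. A user table can be swapped
in via `load_classification()` or the CLI's `--classification-table`.

## Comparison, normalisation, reports

`run_comparison()` aligns once per configuration and precomputes everything
an interactive viewer would reveal on demand — per-column annotation under
all schemes, indels, match regions — because the batch report is the
product. Rankings are descending with lexicographic label tie-break.
Normalisation is min–max onto $[0,1]$; the all-equal (and single-value)
case maps to 0.5 rather than dividing by zero. The HTML overview colours
cells linearly from blue (0) to red (1). JSON carries full precision and is
byte-deterministic apart from the timestamp. Identical pattern and subject
are rejected by default (they almost always mean the same file was loaded
twice) behind an `allow_identical` override.

## Synthetic fixtures: what they do and do not establish

The generator (`fixture_spec()`, `random_sequence()`, `mutate_sequence()`,
`random_matrix()`) drives all tests; nothing binary is checked in. Defaults
were chosen once as a generic protein-scale world: lengths 30–80 residues,
uniform residue usage over the 20 standard codes, 10% substitution and 2%
indel rate for mutated partners, matrix values in the BLOSUM62 integer range
$[-4, 11]$ with strictly positive diagonals. The oracle-equivalence suite
instead uses the prescribed tiny-instance world: lengths 1–6, a 5-letter
alphabet, random symmetric matrices, penalties in $[-10, 0]$. A single
integer seed fully determines every fixture, and generation restores the
caller's RNG state.

These fixtures emulate none of the structure of real proteins — no
composition bias, no conserved domains, no realistic indel length
distribution, no evolutionary model. A green suite therefore establishes
*algorithmic* correctness (optimality, metric definitions, coordinate
bookkeeping, format round-trips) — not that any particular matrix is
biologically appropriate for a given protein family. Conversely the
published-style workflow on real disordered proteins (DDX4 against the
DISORDER matrix) needs externally downloaded sequences and matrix files;
the CLI reproduces it but no test depends on network data.

## Known limitations

* Pure-R DP: a 1,000×1,000 alignment takes seconds, not milliseconds; no
  banding or linear-memory variant.
* One pattern/subject pair per run; no multiple sequence alignment.
* Exact subsequence search only (no mismatches or regular expressions),
  operating on the degapped sequence with hits mapped back to alignment
  columns.
* No statistical significance (P-values) for alignment scores.
* Protein sequences only; extended codes (X, B, Z, U, O, J) are accepted
  solely in lenient mode and score 0 when a matrix lacks them.
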
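# matcompare

Pairwise protein alignment across multiple substitution matrices, as a batch
R library and command-line tool.

## The problem

The quality of a pairwise protein alignment depends heavily on the
substitution matrix used to score residue replacements. Matrices store
log-odds scores

```
s_ij = ln( q_ij / (p_i * p_j) ) / lambda
```

where `q_ij` is the observed frequency of the *i*→*j* substitution, `p_i`
the background frequency of residue *i*, and `lambda` a positive scaling
constant; a positive `s_ij` marks a conservative substitution, a negative
one a non-conservative substitution. Standard families (PAM, BLOSUM) make
different evolutionary assumptions, and custom matrices exist for special
regimes (disordered regions, transmembrane segments, ...). Researchers
comparing candidate matrices usually re-run their aligner once per matrix
and collate results by hand.

`matcompare` does this in one call: it aligns a single *pattern*/*subject*
pair of protein sequences under any number of matrix + affine-gap-penalty
configurations and emits directly comparable results — the alignment score,
four percent-identity (PID) variants, per-column log-odds and conservation
annotation, amino-acid classification under seven physicochemical schemes,
and indel/match/subsequence search — with cross-configuration rankings and
min-max normalised values, written as JSON, TSV, and a static HTML overview
(blue = lowest, red = highest, mirroring the usual overview colouring).

Five alignment modes are supported, all with affine gap cost
`gap_open + L * gap_extend` for a run of L gap columns: `global`
(Needleman–Wunsch), `local` (Smith–Waterman), `overlap` (ends-free), and the
mixed modes `global-local` (whole pattern vs a substring of the subject) and
`local-global` (whole subject vs a substring of the pattern).

The four PID variants differ only in the denominator: aligned columns plus
internal gap columns (PID1), aligned columns (PID2), length of the shorter
input sequence (PID3), mean input length (PID4).

## Worked example

The package ships a small synthetic pair and a master file listing BLOSUM62
and PAM250 under two penalty sets each (the master-file format: one matrix
file per line followed by its gap and extension penalties; repeated
filenames explore penalty effects; configs are labelled `CM0`, `CM1`, ... in
file order):

```r
library(matcompare)
seqs    <- read_fasta(system.file("extdata", "examples", "pair.fa",   package = "matcompare"))
configs <- parse_master_file(system.file("extdata", "examples", "master.txt", package = "matcompare"))
report  <- run_comparison(seqs[[1]], seqs[[2]], configs, mode = "local")
report
#> comparison_report: demo_pattern_synthetic vs demo_subject_synthetic, local mode, 4 config(s)
#>   by score: CM0 > CM1 > CM2 > CM3
#>   CM0        BLOSUM62   score    277.70  PID  75.71 /  76.81 /  76.81 /  76.26
#>   CM1        BLOSUM62   score    270.40  PID  75.71 /  76.81 /  76.81 /  76.26
#>   CM2        PAM250     score    270.10  PID  75.36 /  78.79 /  75.36 /  74.82
#>   CM3        PAM250     score    262.40  PID  76.47 /  77.61 /  75.36 /  74.82
```

Both BLOSUM62 configurations out-score PAM250 here, while PID2 is highest
for `CM2` — the metrics genuinely disagree, which is exactly what the
side-by-side report is for. Drill into one column across all
configurations, or into one alignment:

```r
column_histogram(report, 31)        # residue frequencies at column 31, all configs
#> E N T
#> 2 4 2
annotate_columns(report$results$CM0$alignment, configs[[1]]$matrix,
                 schemes = "physicochemical")[31, ]
#>    position pattern_char subject_char log_odds     conservation  pattern_... subject_...
#> 31       31            T            E       -1 non_conservative     hydroxyl      acidic
find_indels(report$results$CM0$alignment)
#>             role start length
#> 1 gap_in_subject    38      1

write_report(report, "json", "report.json")   # full per-column detail
write_report(report, "tsv",  "report.tsv")    # one row per config
write_report(report, "html", "report.html")   # static overview page
```

### Command line

```sh
Rscript inst/cli/compare.R \
  --pattern inst/extdata/examples/pair.fa \
  --custom  inst/extdata/examples/master.txt \
  --mode local --out report.json --tsv report.tsv --html report.html
```

Predefined matrices take `NAME:open:extend` triples, e.g.
`--predefined BLOSUM62:-10:-0.5,PAM70:-7:-1`. Exit codes: 0 success,
2 input/validation error, 3 alignment failure. To reproduce a published-style
comparison of the DISORDER matrix against BLOSUM62 on the human and
*Xenopus laevis* DDX4 proteins, download the two sequences and the DISORDER
matrix file, list `DISORDER` and `BLOSUM62` in a master file under penalty
sets `(-3.2, -0.1)`, `(-10, -0.6)`, `(-7.5, -0.9)`, and run the line above
with `--mode local` (no external data is bundled or required by the tests).

## Verification

The aligner is verified three ways: against `enumerate_best_score()`, an
exhaustive enumeration oracle that scores every admissible alignment of tiny
instances independently of the dynamic program; by column-wise re-scoring of
every traceback; and against `Biostrings::pairwiseAlignment` in the test
suite. Run the acceptance checks with

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

which re-runs the oracle-equivalence, bundled-matrix and end-to-end checks
from scratch and writes the (empty — no scalar targets are defined for this
artifact) machine-readable target report to `--out`.
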
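---
title: "Design of primers for microRNA-specific RT-qPCR: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design of primers for microRNA-specific RT-qPCR: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdesign)
```

## The assay and its design constraints

MicroRNA-specific RT-qPCR quantifies a mature microRNA with **two**
microRNA-specific DNA primers on a cDNA made by poly(A) tailing followed by
reverse transcription with a tagged poly(T) primer. The cDNA therefore
always carries 15 T's (and the RT tag) immediately 3' of the microRNA
sequence. This fixes the design space almost completely:

* the **forward primer** must be identical to the microRNA 5' end — the
  only freedom is its length and a possible non-template 5' tail;
* the **reverse primer** must end in 3–8 bases complementary to the
  microRNA 3' end and continue into the poly(T)/tag region it shares with
  the RT primer;
* 3'-terminal A residues of the microRNA are removed before design: on the
  tailed cDNA they merge with the poly(T) tract and carry no specificity.

Because both primers are locked onto essentially one position, the design
question is not *where* to put a primer but *which length/tail variant has
the best 3' end*. `mirdesign` enumerates every variant, scores each one
with a small set of multiplicative rules, and ranks all admissible pairs.

## Melting-temperature model

Primer variants are sized toward a 59 °C melting temperature, the
empirical optimum of the assay. `melting_temperature()` implements the
two-state nearest-neighbor model

$$T_m = \frac{1000\,\Delta H}{\Delta S + 0.368\,(N-1)\ln[\mathrm{Na}^+] + R \ln C} - 273.15$$

with the unified nearest-neighbor $\Delta H/\Delta S$ stack parameters and
terminal initiation corrections (plus the symmetry entropy term for
self-complementary oligos), the standard monovalent-salt entropy
correction, and an effective single-strand concentration $C$.

Three constants of this model are not dictated by the assay chemistry: the
parameter table, the salt-correction formula, and $C$. They were fixed by
**calibration against the reference design** for ssc-let-7a: the published
candidate set determines, for every specific length, exactly how many tail
bases (forward) or tag bases (reverse) are added before 59 °C is first
crossed — 15 sizing constraints in all. A grid scan over the published
parameter tables (Breslauer 1986, Sugimoto 1996, unified 1998,
SantaLucia–Hicks 2004), the common salt corrections and a wide
concentration range satisfies all constraints only for the unified table
with the entropy-based salt correction, over an effective concentration
window of roughly 1.4–1.9 µM; the default `oligo_nM = 1600` is the middle
of that window. The calibrated model also reproduces, without further
tuning, the independent reference reverse primer for hsa-miR-23a (4 tag
bases: `ccag` + 15 T's + `ggaaatcc`). All three constants remain exposed in
`thermo_config()`; an end-to-end calibration test pins the behavior.

The unit tests additionally cross-check `melting_temperature()` against an
independently maintained nearest-neighbor implementation (Biopython's
`MeltingTemp`) on 1,000 random 12–30-mers, and verify duplex symmetry
(`Tm(s) = Tm(revcomp(s))`) and monotone response to salt.

## Candidate enumeration

**Forward** (`build_forward_candidates()`): one candidate per specific
length 12–19 nt (the reference output shows eight candidates, lengths 12
through 19, which this package takes as normative; the range is
configurable). A candidate below target Tm gains 5' bases one at a time in
the order G, A, C, G, C, cycled once more if needed (maximum 10); the
order packs in G/C without creating homopolymeric G/C runs. A candidate
above target is trimmed one base at a time from its 5' end — losing
template bases, which is recorded as `five_prime_score` 5 instead of 10
(informational only; never part of the score). Stopping is at the *first
crossing*: extension stops at the first Tm ≥ target, trimming at the first
Tm ≤ target, which makes the discrete rule deterministic.

**Reverse** (`build_reverse_candidates()`): one candidate per specific
length 3–8; the base sequence is 15 T's plus the reverse complement of the
template 3' end, extended by prepending RT-tag bases (default tag
`CAGGTCCAG`, consumed from its 3' end) until the target Tm. If the tag is
exhausted first, the maximal primer is kept with a warning — unlike the
forward tail there is nothing further to add.

Degenerate cases are handled conservatively: a forward candidate that is
still too hot at 12 total nt is kept at 12 nt with a warning rather than
discarded; candidates that collapse to the same final sequence after
trimming are deduplicated (keeping the shortest specific length); targets
shorter than 12 designable nt after A-trimming are rejected per target
with a diagnostic while the rest of the batch proceeds.

## The score matrix

Every rule maps a discrete sequence feature to a factor in (0, 1]; a
primer's score is the product of its factors. The factors were chosen to
be of similar magnitude so that no single rule dominates:

| feature | value | factor |
|---|---|---|
| 3'-terminal 2-mer | 0 or 2 weak (A/T) bases | 0.7 |
| | 1 weak base | 1.0 |
| 3'-terminal 3-mer | 0 or 3 weak | 0.3 |
| | 1 or 2 weak | 1.0 |
| 3'-terminal 5-mer | 0 or 5 weak | 0.1 |
| | 1 or 4 weak | 0.5 |
| | 2 or 3 weak | 1.0 |
| 3'-anchored annealing | 5 nt (or more) | 0.1 |
| | 4 nt | 0.2 |
| | less | 1.0 |
| internal annealing | 8 nt (or more) | 0.1 |
| | 7 nt | 0.3 |
| | 6 nt | 0.8 |
| | less | 1.0 |

Matches longer than the tabulated lengths keep the strongest penalty
(monotone extension). Forward primers are additionally multiplied by the
length score $L^2/400$ ($L$ = specific length), favoring longer
microRNA-specific parts; reverse primers carry no length factor because
no length–performance correlation has been established for them — but
equal-scoring pairs are ranked with the longer reverse primer first.

Annealing uses a two-molecule hybridization model: the 3'-anchored
detector finds the longest 3'-terminal k-mer of one primer whose reverse
complement occurs anywhere in the other (or in a second copy of itself for
self-annealing — the matching k-mer may be the primer's own 3' end, which
is what detects 3'-palindromic ends such as `...TATA`); the internal
detector finds the longest k-mer/k-mer reverse-complement match anywhere.
No unimolecular hairpin model and no thermodynamic (ΔG) secondary-structure
scoring is attempted; the rule-based factors keep the ranking transparent.
Both detectors are verified against an independent brute-force oracle — a
position-wise complementarity matrix in which duplexes are anti-diagonal
runs — on 10,000 random sequence pairs.

Pairs are formed from all forward × reverse combinations except those
whose specific footprints on the template overlap by more than 2 nt
(the reference best pair itself has a 2-nt overlap, so the threshold is
"more than 2", configurable), and scored as

$$\text{pair score} = f_\text{score} \times r_\text{score} \times F_\text{anneal} \times R_\text{anneal} \times \text{dimer},$$

where the three cross factors reuse the annealing tables above. Ranking is
by unrounded score; ties prefer the longer reverse specific part, then the
longer forward part, then the lexicographically smaller forward sequence —
a deterministic total order, so repeated runs are byte-identical.

## Pair similarity for redesign

When an assay fails, the recommended next attempt is the retained pair
*most different* from the failed one, not necessarily the second-ranked
pair. `compare_pairs()` scores similarity per primer as
`end3_factor × length_factor`, where `end3_factor` maps position-wise
matches of the 3'-terminal trinucleotides (3 → 1.0, 2 → 0.7, 1 → 0.4,
0 → 0.2) and `length_factor = max(0.1, 1 − 0.2·|ΔL|)`; the pair similarity
is `forward² × reverse`, squaring implementing the double weighting of
forward-primer differences. The *inputs* of this comparison (length
difference, 3' trinucleotide, forward double-weighting, identity → 1.0)
are fixed by the method; the concrete factor values are this package's
documented interpretation and are arguments of `compare_pairs()`. No
bit-compatibility with any other implementation's comparison file is
claimed.

## Reports and numeric formatting

`write_outputs()` writes five fixed-name tab-separated files. Scores are
printed with half-up rounding to two decimals in minimal form ("0.5",
"1.0", "0.64"); ranking always uses the unrounded values. Half-up (rather
than banker's) rounding matches the reference tables on boundary products
such as 0.08505 → 0.09. Line endings are LF by default with a CRLF option
for Windows spreadsheet workflows. Reader functions
(`read_primer_report()`, `read_pair_report()`,
`read_comparison_report()`) parse the files back for programmatic use and
round-trip testing.

## The synthetic target generator

`generate_random_targets()` produces seeded random records with uniform
base composition and lengths 19–25 nt, the size range of mature
microRNAs. It emulates only the *shape* of an input list (lengths,
alphabet, RNA/DNA spelling, batch structure) — not the base-composition
bias, seed-region conservation or family structure of real microRNAs.
Property tests on these fixtures therefore demonstrate the pipeline's
invariants (determinism, score identities, round-trips, case/U-T
invariance), not wet-lab performance on real targets; assay success rates
can only be established experimentally.

## Problem sizes and limitations

The test suite runs the full pipeline on the 10-target example list and a
15-target random fixture set, checks the annealing detectors against brute
force on 10,000 random pairs, and cross-checks 1,000 random Tm values —
sizes at which every check is exhaustive rather than sampled for the
sequence lengths involved.

Known limitations: no LNA thermodynamics (the method deliberately uses
plain DNA primers); no miRBase lookup (the input is an explicit sequence
list); no ΔG-based secondary-structure model; scores are relative rankings
within one target, not calibrated probabilities of assay success; and the
melting-temperature constants, while calibrated and cross-checked, inherit
the usual uncertainty of two-state nearest-neighbor predictions for
tailed, partly homopolymeric oligos.
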
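# mirdesign

Automatic design and score-based ranking of DNA primer pairs for
microRNA-specific RT-qPCR.

## The problem

A mature microRNA is ~22 nt long — the size of a single PCR primer — so two
specific primers cannot be placed on it directly. In microRNA-specific
RT-qPCR the RNA is first poly(A)-tailed and reverse-transcribed with a
tagged poly(T) primer, which extends the template at both ends. A forward
primer identical to 12–19 nt of the microRNA 5' end and a reverse primer
with only 3–8 microRNA-specific 3' bases (behind 15 T's and part of the RT
tag) then give a specific, efficient assay. Designing such primers by hand
is tedious and error-prone at scale; `mirdesign` automates it for whole
target lists and ranks every candidate pair by a transparent rule-based
score.

## The method

For each target the tool:

1. converts the sequence to DNA sense and removes 3'-terminal A residues
   (indistinguishable from the poly(T) tract on the cDNA);
2. enumerates forward candidates of every specific length (default 12–19 nt
   from the 5' end) and sizes each to the 59 °C nearest-neighbor melting
   temperature — too-cold candidates gain 5' tail bases one at a time in
   the order G, A, C, G, C; too-hot candidates are trimmed from the 5' end;
3. enumerates reverse candidates (3–8 specific 3' bases + 15 T's), extended
   one base at a time with the 3' end of the RT-primer tag until 59 °C;
4. scores every primer as a product of penalty factors: weak-base (A/T)
   content of the 3'-terminal 2-, 3- and 5-mers, 3'-anchored and internal
   self-annealing, and (forward only) the length score `L²/400`;
5. combines all forward × reverse pairs whose template footprints overlap
   by at most 2 nt at the 3' end, and ranks them by

   `pair_score = forward_score × reverse_score × Fprimer_anneal × Rprimer_anneal × primer_dimer`

   with ties broken toward the longer reverse primer;
6. writes five tab-separated report files
   (`result_best_primer_pairs.txt`, `result_all_primer_pairs.txt`,
   `result_f_primers.txt`, `result_r_primers.txt`,
   `result_comparison_of_pairs.txt`) that open directly in spreadsheet
   programs. The comparison file scores the pairwise similarity of the
   designed pairs to guide redesign after an assay failure.

Melting temperatures use the unified nearest-neighbor thermodynamic
parameters with an entropy salt correction at 115 mM monovalent salt; see
`vignette` sources in `vignettes/` for the model and its calibration.

## Worked example

```r
library(mirdesign)

targets <- parse_targets(">ssc-let-7a\nTGAGGTAGTAGGTTGTATAGTT")
res <- design_primers(targets)
res
#> <mirdesign_result> 1 target(s) designed, 0 failed
#>   ssc-let-7a: best pair F_1 + R_1 (score 0.32)

head(res$targets[["ssc-let-7a"]]$forwards[, c("name", "sequence", "specific_length", "score")], 3)
#>   name             sequence specific_length  score
#> 1  F_1 GCAGTGAGGTAGTAGGTTGT              16 0.6400
#> 2  F_2  GCAGTGAGGTAGTAGGTTG              15 0.5625
#> 3  F_3   CGCAGTGAGGTAGTAGGT              13 0.4225
```

The top forward primer keeps all penalty factors at 1.0 (a balanced 3' end,
no self-annealing) so its score is the pure length term `16²/400 = 0.64`.
The best pair combines it with the 8-nt-specific reverse primer
`ggtccagtttttttttttttttaactatac` (score 0.5, penalized only for its
weak-base-rich 3' 5-mer): `0.64 × 0.5 × 1.0 × 1.0 × 1.0 = 0.32`. Scores are
relative rankings within one target, not absolute success probabilities.

From a shell, the same run is:

```sh
inst/cli/mirdesign --input input_miRs.txt --out-dir results/
```

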
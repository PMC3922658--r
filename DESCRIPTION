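Package: mirdesign
Title: Score-Based Design of Primers for MicroRNA-Specific RT-qPCR
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automatic design and score-based ranking of DNA primer pairs
    for microRNA-specific quantitative RT-PCR on poly(A)-tailed,
    universally reverse-transcribed cDNA. Candidate forward primers match
    the microRNA 5' end and are tail-extended (or 5'-trimmed) to a 59
    degree Celsius nearest-neighbor melting temperature; reverse primers
    combine a short microRNA-specific 3' end with the poly(T) tract and
    tag of the reverse-transcription primer. Candidates and pairs are
    ranked by a transparent rule-based score covering 3'-end base
    composition, self-annealing, primer-dimer propensity and primer
    length, and results are written as spreadsheet-compatible
    tab-separated reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
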
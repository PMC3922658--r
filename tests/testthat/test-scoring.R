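cfg <- design_config()
let7a <- make_template(let7a_record(), cfg)

test_that("weak bases are A and T, in either case and spelling", {
  expect_equal(weak_count("GT"), 1)
  expect_equal(weak_count("TAT"), 3)
  expect_equal(weak_count("GCGCG"), 0)
  expect_equal(weak_count("gcau"), 2)
})

test_that("3'-end windows map weak-base counts to the published factors", {
  expect_equal(end_scores("GCAGTGAGGTAGTAGGTTGT"),
               c(two_last = 1.0, three_last = 1.0, five_last = 1.0))
  expect_equal(end_scores("GCAGTGAGGTAGTAGGTTGTAT"),
               c(two_last = 0.7, three_last = 0.3, five_last = 0.5))
  expect_equal(end_scores("GGTCCAGTTTTTTTTTTTTTTTAACTATAC"),
               c(two_last = 1.0, three_last = 1.0, five_last = 0.5))
  # extremes of each window
  expect_equal(unname(end_scores("GCGCG")), c(0.7, 0.3, 0.1))
  expect_equal(unname(end_scores("ATATA")), c(0.7, 0.3, 0.1))
  expect_equal(unname(end_scores("GGGTG")), c(1.0, 1.0, 0.5))
  # windows wider than the sequence default to 1.0
  expect_equal(unname(end_scores("GAT")), c(0.7, 1.0, 1.0))
})

test_that("annealing detectors match known constructions", {
  # the 3'-terminal TATA is its own reverse complement
  expect_equal(longest_three_prime_anneal("GCAGTGAGGTAGTAGGTTGTATA",
                                          "GCAGTGAGGTAGTAGGTTGTATA"), 4)
  expect_equal(longest_three_prime_anneal("ATATATAT", "ATATATAT"), 8)
  expect_lt(longest_internal_anneal("GCAGTGAGGTAGTAGGTTGT",
                                    "GCAGTGAGGTAGTAGGTTGT"), 6)
  expect_gte(longest_internal_anneal("AAAAAACCCCCC", "GGGGGGTTTTTT"), 6)
  # engineered 5-base 3' cross-complement
  expect_equal(longest_three_prime_anneal("GGGGGGATCCA", "AAATGGATAAA"), 5)
})

test_that("annealing detectors equal the brute-force oracles", {
  set.seed(123)
  for (i in 1:400) {
    a <- random_dna(sample(8:35, 1))
    b <- random_dna(sample(8:35, 1))
    expect_equal(longest_internal_anneal(a, b), brute_internal_anneal(a, b),
                 info = paste(a, b))
    expect_equal(longest_three_prime_anneal(a, b),
                 brute_three_prime_anneal(a, b), info = paste(a, b))
  }
  # self case
  for (i in 1:100) {
    a <- random_dna(sample(8:35, 1))
    expect_equal(longest_internal_anneal(a, a), brute_internal_anneal(a, a))
    expect_equal(longest_three_prime_anneal(a, a),
                 brute_three_prime_anneal(a, a))
  }
})

test_that("published forward primer scores are reproduced exactly", {
  expected <- list(
    gcagtgaggtagtaggttgt    = 0.64,
    gcagtgaggtagtaggttg     = 0.56,
    cgcagtgaggtagtaggt      = 0.42,
    cgcagtgaggtagtaggtt     = 0.34,
    gcagtgaggtagtaggttgta   = 0.25,
    cgcagtgaggtagtagg       = 0.25,
    gcagtgaggtagtaggttgtat  = 0.09,
    gcagtgaggtagtaggttgtata = 0.02)
  for (s in names(expected)) {
    cand <- as_primer_candidate(s, let7a, "forward", cfg)
    sc <- score_primer(cand, cfg)
    expect_equal(as.numeric(format_score(sc$total)), expected[[s]], info = s)
  }
  # full factor breakdown of the extreme rows
  sc1 <- score_primer(as_primer_candidate("gcagtgaggtagtaggttgt", let7a,
                                          "forward", cfg), cfg)
  expect_equal(sc1$length_score, 16^2 / 400)
  expect_equal(unlist(sc1[c("two_last_score", "three_last_score",
                            "five_last_score", "three_self_anneal",
                            "internal_self_anneal")]),
               c(two_last_score = 1, three_last_score = 1,
                 five_last_score = 1, three_self_anneal = 1,
                 internal_self_anneal = 1))
  sc8 <- score_primer(as_primer_candidate("gcagtgaggtagtaggttgtata", let7a,
                                          "forward", cfg), cfg)
  expect_equal(unname(unlist(sc8[1:6])), c(0.7, 0.3, 0.5, 0.2, 1.0, 19^2 / 400))
})

test_that("reverse primers carry no length factor and score as published", {
  cand <- as_primer_candidate("ggtccagtttttttttttttttaactatac", let7a,
                              "reverse", cfg)
  sc <- score_primer(cand, cfg)
  expect_equal(sc$length_score, 1.0)
  expect_equal(sc$total, 0.5)
})

test_that("the five_prime_score never enters the score", {
  cand <- as_primer_candidate("gcagtgaggtagtaggttgt", let7a, "forward", cfg)
  sc10 <- score_primer(cand, cfg)
  cand$five_prime_score <- 5L
  sc5 <- score_primer(cand, cfg)
  expect_identical(sc10, sc5)
})

test_that("scores are products of their factors and penalties only shrink them", {
  set.seed(31)
  recs <- generate_random_targets(12, seed = 31)
  for (i in seq_len(nrow(recs))) {
    tm <- tryCatch(make_template(recs[i, ], cfg), error = function(e) NULL)
    if (is.null(tm)) next
    cands <- rbind(build_forward_candidates(tm, cfg),
                   build_reverse_candidates(tm, cfg))
    scored <- score_candidates(cands, cfg)
    expect_equal(scored$score,
                 scored$two_last_score * scored$three_last_score *
                   scored$five_last_score * scored$three_self_anneal *
                   scored$internal_self_anneal * scored$length_score)
    expect_true(all(scored$score <= scored$length_score + 1e-12))
    expect_true(all(scored$score > 0))
  }
})

test_that("scoring is invariant under case and U/T spelling", {
  a <- as_primer_candidate("GCAGTGAGGTAGTAGGTTGT", let7a, "forward", cfg)
  b <- as_primer_candidate("gcagugagguaguagguugu", let7a, "forward", cfg)
  expect_identical(score_primer(a, cfg), score_primer(b, cfg))
})

test_that("pair enumeration excludes 3' overlaps beyond the threshold", {
  fwd <- rank_candidates(score_candidates(build_forward_candidates(let7a, cfg),
                                          cfg), "F")
  rev <- rank_candidates(score_candidates(build_reverse_candidates(let7a, cfg),
                                          cfg), "R")
  pairs <- enumerate_pairs(fwd, rev, let7a, cfg)
  # F footprint [0, L), R footprint [22-k, 22): overlap = L + k - 22
  expect_true(all(pairs$footprint_overlap <= 2))
  expect_false(any(pairs$f_specific_length + pairs$r_specific_length > 24))
  # the published best combination (overlap exactly 2) is retained
  expect_true(any(pairs$f_specific_length == 16 & pairs$r_specific_length == 8))
  # 8 x 6 combinations minus the six with overlap > 2
  expect_equal(nrow(pairs), 42)
})

test_that("the published best pair and its score are reproduced", {
  fwd <- rank_candidates(score_candidates(build_forward_candidates(let7a, cfg),
                                          cfg), "F")
  rev <- rank_candidates(score_candidates(build_reverse_candidates(let7a, cfg),
                                          cfg), "R")
  expect_equal(tolower(fwd$sequence[1]), "gcagtgaggtagtaggttgt")
  expect_equal(format_score(fwd$score), c("0.64", "0.56", "0.42", "0.34",
                                          "0.25", "0.25", "0.09", "0.02"))
  pairs <- rank_pairs(enumerate_pairs(fwd, rev, let7a, cfg))
  top <- pairs[1, ]
  expect_equal(tolower(top$f_sequence), "gcagtgaggtagtaggttgt")
  expect_equal(tolower(top$r_sequence), "ggtccagtttttttttttttttaactatac")
  expect_equal(top$pair_score, 0.32)
  expect_equal(c(top$fprimer_anneal, top$rprimer_anneal, top$primer_dimer),
               c(1, 1, 1))
  # pair score identity holds for every retained pair
  expect_equal(pairs$pair_score,
               pairs$f_score * pairs$r_score * pairs$fprimer_anneal *
                 pairs$rprimer_anneal * pairs$primer_dimer)
  expect_true(all(pairs$pair_score <= pmin(pairs$f_score, pairs$r_score) + 1e-12))
})

test_that("equal pair scores prefer the longer reverse primer", {
  pairs <- data.frame(
    f_name = c("F_1", "F_1"), r_name = c("R_a", "R_b"),
    f_sequence = c("ACGTACGTACGT", "ACGTACGTACGT"),
    r_sequence = c("AAAA", "BBBB"),
    f_specific_length = c(12L, 12L), r_specific_length = c(4L, 8L),
    f_score = c(0.5, 0.5), r_score = c(0.5, 0.5),
    fprimer_anneal = 1, rprimer_anneal = 1, primer_dimer = 1,
    pair_score = c(0.25, 0.25), footprint_overlap = 0L,
    stringsAsFactors = FALSE)
  ranked <- rank_pairs(pairs)
  expect_equal(ranked$r_specific_length, c(8L, 4L))
})
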
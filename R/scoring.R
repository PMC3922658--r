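# Rule-based score matrix. Every rule maps a discrete sequence feature to a
# multiplicative factor in (0, 1]; a primer's score is the product of its
# factors (forward primers additionally carry the length score).

.two_last_table <- c("0" = 0.7, "1" = 1.0, "2" = 0.7)
.three_last_table <- c("0" = 0.3, "1" = 1.0, "2" = 1.0, "3" = 0.3)
.five_last_table <- c("0" = 0.1, "1" = 0.5, "2" = 1.0, "3" = 1.0,
                      "4" = 0.5, "5" = 0.1)

#' Count weak (A/T) bases in a sequence
#'
#' @param seq DNA string (case-insensitive, U counted as T).
#' @return Integer count of A and T letters.
#' @export
weak_count <- function(seq) {
  s <- chartr("U", "T", toupper(seq))
  nchar(gsub("[^AT]", "", s))
}

#' 3'-end composition factors of a primer
#'
#' Looks up the penalty factors for the weak-base (A/T) content of the
#' 3'-terminal 2-, 3- and 5-mers. A balanced 3' end scores 1.0 in all three
#' windows; all-weak or all-strong ends are penalized. Windows longer than
#' the sequence are skipped (factor 1.0).
#'
#' @param seq DNA string.
#' @return Named numeric vector `c(two_last, three_last, five_last)`.
#' @examples
#' end_scores("GCAGTGAGGTAGTAGGTTGT")   # all 1.0
#' @export
end_scores <- function(seq) {
  s <- chartr("U", "T", toupper(seq))
  n <- nchar(s)
  win <- function(w, table) {
    if (n < w) return(1.0)
    unname(table[[as.character(weak_count(substr(s, n - w + 1, n)))]])
  }
  c(two_last = win(2, .two_last_table),
    three_last = win(3, .three_last_table),
    five_last = win(5, .five_last_table))
}

#' Longest 3'-anchored annealing between two primers
#'
#' Length of the longest 3'-terminal k-mer of `a` that is the reverse
#' complement of a k-mer occurring anywhere in `b` (two-molecule annealing
#' model; with `b = a` this is 3' self-annealing, and the matching k-mer may
#' be `a`'s own 3' end).
#'
#' @param a,b DNA strings (non-empty).
#' @return Integer match length (0 if even the terminal base finds no
#'   complement).
#' @export
longest_three_prime_anneal <- function(a, b) {
  a <- chartr("U", "T", toupper(a)); b <- chartr("U", "T", toupper(b))
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  na <- nchar(a)
  best <- 0L
  # a match at k implies one at k - 1, so ascend and stop at the first miss
  for (k in seq_len(min(na, nchar(b)))) {
    if (!grepl(reverse_complement(substr(a, na - k + 1, na)), b,
               fixed = TRUE)) {
      break
    }
    best <- k
  }
  best
}

#' Longest internal annealing between two primers
#'
#' Length of the longest k-mer of `a` whose reverse complement occurs in `b`
#' (anywhere in either molecule). With `b = a` this is internal
#' self-annealing.
#'
#' @param a,b DNA strings (non-empty).
#' @return Integer match length.
#' @export
longest_internal_anneal <- function(a, b) {
  a <- chartr("U", "T", toupper(a)); b <- chartr("U", "T", toupper(b))
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  # a k-mer of a reverse-complements a k-mer of b iff revcomp(a) and b share
  # a k-mer: longest common substring of revcomp(a) and b
  x <- reverse_complement(a)
  nx <- nchar(x); nb <- nchar(b)
  best <- 0L
  for (k in seq_len(min(nx, nb))) {
    kx <- substring(x, 1:(nx - k + 1), k:nx)
    kb <- substring(b, 1:(nb - k + 1), k:nb)
    if (!any(kx %in% kb)) break
    best <- k
  }
  best
}

# factor maps for annealing match lengths; matches beyond the tabulated
# lengths keep the strongest penalty
.three_prime_anneal_factor <- function(k) {
  if (k >= 5) 0.1 else if (k == 4) 0.2 else 1.0
}
.internal_anneal_factor <- function(k) {
  if (k >= 8) 0.1 else if (k == 7) 0.3 else if (k == 6) 0.8 else 1.0
}

#' Score a single primer candidate
#'
#' Multiplies the 3'-end composition factors, the 3'-anchored and internal
#' self-annealing factors and, for forward primers only, the length score
#' `specific_length^2 / 400`. The informational `five_prime_score` never
#' enters the score.
#'
#' @param candidate One-row candidate data frame (from
#'   [build_forward_candidates()], [build_reverse_candidates()] or
#'   [as_primer_candidate()]).
#' @param config A [design_config()].
#' @return Named list with the individual factors (`two_last_score`,
#'   `three_last_score`, `five_last_score`, `three_self_anneal`,
#'   `internal_self_anneal`, `length_score`) and their product `total`.
#' @export
score_primer <- function(candidate, config = design_config()) {
  s <- candidate$sequence[[1]]
  ends <- end_scores(s)
  k3 <- longest_three_prime_anneal(s, s)
  ki <- longest_internal_anneal(s, s)
  f3 <- .three_prime_anneal_factor(k3)
  fi <- .internal_anneal_factor(ki)
  len_score <- if (identical(candidate$orientation[[1]], "forward")) {
    candidate$specific_length[[1]]^2 / config$length_score_denominator
  } else {
    1.0
  }
  list(two_last_score = unname(ends[["two_last"]]),
       three_last_score = unname(ends[["three_last"]]),
       five_last_score = unname(ends[["five_last"]]),
       three_self_anneal = f3,
       internal_self_anneal = fi,
       length_score = len_score,
       total = unname(prod(ends)) * f3 * fi * len_score)
}

#' Score every candidate in a data frame
#'
#' @param candidates Candidate data frame.
#' @param config A [design_config()].
#' @return The data frame with score columns appended (`score` is the total).
#' @export
score_candidates <- function(candidates, config = design_config()) {
  if (is.null(candidates) || nrow(candidates) == 0) return(candidates)
  sc <- lapply(seq_len(nrow(candidates)),
               function(i) score_primer(candidates[i, , drop = FALSE], config))
  candidates$two_last_score <- vapply(sc, `[[`, numeric(1), "two_last_score")
  candidates$three_last_score <- vapply(sc, `[[`, numeric(1), "three_last_score")
  candidates$five_last_score <- vapply(sc, `[[`, numeric(1), "five_last_score")
  candidates$three_self_anneal <- vapply(sc, `[[`, numeric(1), "three_self_anneal")
  candidates$internal_self_anneal <- vapply(sc, `[[`, numeric(1), "internal_self_anneal")
  candidates$length_score <- vapply(sc, `[[`, numeric(1), "length_score")
  candidates$score <- vapply(sc, `[[`, numeric(1), "total")
  candidates
}

#' Rank scored candidates
#'
#' Descending by unrounded score; ties broken by longer specific part, then
#' lexicographic sequence (a deterministic total order).
#'
#' @param candidates Scored candidate data frame.
#' @param prefix Name prefix (`"F"` or `"R"`).
#' @return The data frame reordered, with a `name` column `F_1 ...` / `R_1 ...`.
#' @export
rank_candidates <- function(candidates, prefix = "F") {
  if (is.null(candidates) || nrow(candidates) == 0) return(candidates)
  ord <- order(-candidates$score, -candidates$specific_length,
               candidates$sequence)
  candidates <- candidates[ord, , drop = FALSE]
  candidates$name <- paste0(prefix, "_", seq_len(nrow(candidates)))
  rownames(candidates) <- NULL
  candidates
}

#' Combine forward and reverse candidates into scored pairs
#'
#' All cross combinations are formed except those whose specific-part
#' template footprints overlap by more than `max_pair_template_overlap`
#' positions (default 2). Each retained pair carries the forward-3'-end vs
#' reverse annealing factor (`fprimer_anneal`), the reverse-3'-end vs forward
#' factor (`rprimer_anneal`), the internal cross-annealing factor
#' (`primer_dimer`) and the pair score
#' `forward_score * reverse_score * fprimer_anneal * rprimer_anneal * primer_dimer`.
#'
#' @param forwards,reverses Scored, ranked candidate data frames.
#' @param template A `mir_template` (used only for context checks).
#' @param config A [design_config()].
#' @return Data frame of pairs (possibly empty), unranked.
#' @export
enumerate_pairs <- function(forwards, reverses, template,
                            config = design_config()) {
  if (is.null(forwards) || is.null(reverses) ||
      nrow(forwards) == 0 || nrow(reverses) == 0) {
    return(NULL)
  }
  rows <- list()
  for (i in seq_len(nrow(forwards))) {
    for (j in seq_len(nrow(reverses))) {
      f <- forwards[i, ]; r <- reverses[j, ]
      overlap <- max(0L, min(f$fp_end, r$fp_end) - max(f$fp_start, r$fp_start))
      if (overlap > config$max_pair_template_overlap) next
      fa <- .three_prime_anneal_factor(
        longest_three_prime_anneal(f$sequence, r$sequence))
      ra <- .three_prime_anneal_factor(
        longest_three_prime_anneal(r$sequence, f$sequence))
      pd <- .internal_anneal_factor(
        longest_internal_anneal(f$sequence, r$sequence))
      rows[[length(rows) + 1L]] <- data.frame(
        f_name = f$name, r_name = r$name,
        f_sequence = f$sequence, r_sequence = r$sequence,
        f_specific_length = f$specific_length,
        r_specific_length = r$specific_length,
        f_score = f$score, r_score = r$score,
        fprimer_anneal = fa, rprimer_anneal = ra, primer_dimer = pd,
        pair_score = f$score * r$score * fa * ra * pd,
        footprint_overlap = overlap, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank primer pairs
#'
#' Descending by unrounded pair score. Equal scores prefer the longer
#' reverse specific part, then the longer forward specific part, then the
#' lexicographically smaller forward sequence, giving a deterministic total
#' order.
#'
#' @param pairs Data frame from [enumerate_pairs()].
#' @return The data frame reordered, with a `name` column `Pair_1 ...`.
#' @export
rank_pairs <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) return(pairs)
  ord <- order(-pairs$pair_score, -pairs$r_specific_length,
               -pairs$f_specific_length, pairs$f_sequence)
  pairs <- pairs[ord, , drop = FALSE]
  pairs$name <- paste0("Pair_", seq_len(nrow(pairs)))
  rownames(pairs) <- NULL
  pairs
}
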
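#' Pairwise similarity between designed primer pairs
#'
#' After an assay fails, the recommended redesign strategy is to pick the
#' retained pair most *different* from the failed one. This comparison scores
#' how alike two primer pairs are, from the difference in length of the
#' microRNA-specific parts and the sequence of the 3'-terminal trinucleotide
#' of each primer, with differences in the forward primer weighted twice as
#' heavily as differences in the reverse primer. Identical pairs score 1.0;
#' lower means more different.
#'
#' For each primer versus its counterpart:
#' `primer_factor = end3_factor * length_factor`, where `end3_factor` maps
#' the number of position-wise matches in the 3'-terminal trinucleotide
#' (3 matches: 1.0, 2: 0.7, 1: 0.4, 0: 0.2) and
#' `length_factor = max(0.1, 1 - 0.2 * |delta specific_length|)`. The pair
#' similarity is `forward_factor^2 * reverse_factor` (squaring implements the
#' double weighting of the forward primer). The factor values are a
#' documented interpretation and can be swapped out via the arguments.
#'
#' @param pairs Ranked pair data frame from [rank_pairs()] (columns
#'   `f_sequence`, `r_sequence`, `f_specific_length`, `r_specific_length`,
#'   `name`).
#' @param end3_map Numeric vector of length 4: factors for 0, 1, 2 and 3
#'   position-wise trinucleotide matches.
#' @param length_slope Similarity lost per nucleotide of specific-length
#'   difference.
#' @param length_floor Lower bound of the length factor.
#' @return Symmetric numeric matrix of similarities with the pair names as
#'   dimnames; unit diagonal.
#' @export
compare_pairs <- function(pairs, end3_map = c(0.2, 0.4, 0.7, 1.0),
                          length_slope = 0.2, length_floor = 0.1) {
  stopifnot(!is.null(pairs), nrow(pairs) >= 1, length(end3_map) == 4)
  n <- nrow(pairs)
  primer_factor <- function(seq_a, len_a, seq_b, len_b) {
    ta <- strsplit(substr(seq_a, nchar(seq_a) - 2, nchar(seq_a)), "")[[1]]
    tb <- strsplit(substr(seq_b, nchar(seq_b) - 2, nchar(seq_b)), "")[[1]]
    matches <- sum(toupper(ta) == toupper(tb))
    end3 <- end3_map[[matches + 1L]]
    lenf <- max(length_floor, 1 - length_slope * abs(len_a - len_b))
    end3 * lenf
  }
  m <- matrix(1.0, n, n, dimnames = list(pairs$name, pairs$name))
  if (n == 1) return(m)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ff <- primer_factor(pairs$f_sequence[i], pairs$f_specific_length[i],
                          pairs$f_sequence[j], pairs$f_specific_length[j])
      rf <- primer_factor(pairs$r_sequence[i], pairs$r_specific_length[i],
                          pairs$r_sequence[j], pairs$r_specific_length[j])
      m[i, j] <- m[j, i] <- ff^2 * rf
    }
  }
  m
}
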
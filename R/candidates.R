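#' Design configuration
#'
#' Collects every tunable constant of the primer-design method. Defaults are
#' the published operating conditions of microRNA-specific RT-qPCR primer
#' design: forward primers match 12-19 nt of the microRNA 5' end, reverse
#' primers carry 3-8 microRNA-specific 3' bases behind 15 T's and the tag of
#' the reverse-transcription primer, and both are sized toward a 59 degree
#' Celsius nearest-neighbor melting temperature.
#'
#' @param thermo A [thermo_config()].
#' @param forward_specific_range Inclusive length interval of the forward
#'   microRNA-specific part.
#' @param reverse_specific_range Inclusive length interval of the reverse
#'   microRNA-specific 3' part.
#' @param forward_tail_order Nucleotides prepended one at a time (and cycled)
#'   to cold forward primers, 5'-most last.
#' @param rt_tag Tag of the reverse-transcription primer adjacent to its
#'   poly(T) run; consumed 3' to 5' when extending cold reverse primers.
#' @param poly_t_length Number of T's between tag and specific part of a
#'   reverse primer.
#' @param max_pair_template_overlap Maximum allowed overlap, in template
#'   positions, between the specific footprints of a retained pair.
#' @param length_score_denominator Denominator of the forward length score
#'   `specific_length^2 / denominator`.
#' @param min_template_length Shortest usable design sequence after 3'
#'   A-trimming.
#' @param max_forward_tail Hard cap on forward tail length (two passes
#'   through `forward_tail_order`).
#' @return A list of class `design_config`.
#' @export
design_config <- function(thermo = thermo_config(),
                          forward_specific_range = c(12L, 19L),
                          reverse_specific_range = c(3L, 8L),
                          forward_tail_order = "GACGC",
                          rt_tag = "CAGGTCCAG",
                          poly_t_length = 15L,
                          max_pair_template_overlap = 2L,
                          length_score_denominator = 400,
                          min_template_length = 12L,
                          max_forward_tail = 2L * nchar(forward_tail_order)) {
  stopifnot(inherits(thermo, "thermo_config"),
            length(forward_specific_range) == 2,
            length(reverse_specific_range) == 2,
            forward_specific_range[1] <= forward_specific_range[2],
            reverse_specific_range[1] <= reverse_specific_range[2],
            nchar(forward_tail_order) >= 1, nchar(rt_tag) >= 1,
            poly_t_length >= 0, max_pair_template_overlap >= 0,
            length_score_denominator > 0)
  structure(list(thermo = thermo,
                 forward_specific_range = as.integer(forward_specific_range),
                 reverse_specific_range = as.integer(reverse_specific_range),
                 forward_tail_order = toupper(forward_tail_order),
                 rt_tag = toupper(rt_tag),
                 poly_t_length = as.integer(poly_t_length),
                 max_pair_template_overlap = as.integer(max_pair_template_overlap),
                 length_score_denominator = length_score_denominator,
                 min_template_length = as.integer(min_template_length),
                 max_forward_tail = as.integer(max_forward_tail)),
            class = "design_config")
}

#' Forward tail after k single-nucleotide extensions
#'
#' Tail letters are prepended one at a time in the configured order (default
#' G, A, C, G, C, cycled), so read 5' to 3' the tail of length `k` is the
#' reverse of the first `k` letters of that cycled order.
#'
#' @param k Number of prepended nucleotides (>= 0).
#' @param config A [design_config()].
#' @return Tail as an uppercase DNA string (`""` for `k = 0`).
#' @examples
#' forward_tail(4) # "GCAG"
#' forward_tail(5) # "CGCAG"
#' @export
forward_tail <- function(k, config = design_config()) {
  stopifnot(k >= 0)
  if (k == 0) return("")
  order <- strsplit(config$forward_tail_order, "")[[1]]
  letters <- rep_len(order, k)
  paste(rev(letters), collapse = "")
}

.empty_candidates <- function() {
  data.frame(orientation = character(0), sequence = character(0),
             tail = character(0), specific_part = character(0),
             specific_length = integer(0), fp_start = integer(0),
             fp_end = integer(0), five_prime_score = integer(0),
             tm = numeric(0), tm_reached = logical(0),
             stringsAsFactors = FALSE)
}

#' Enumerate forward primer candidates for a template
#'
#' One candidate per specific length in `forward_specific_range` (clamped to
#' the template length). A candidate colder than the Tm target is extended by
#' prepending tail nucleotides one at a time until the target is first
#' reached; a candidate hotter than the target is trimmed from its 5' end
#' (losing template bases, hence `five_prime_score` 5) until the Tm first
#' drops to or below the target. Candidates that collapse to the same final
#' sequence are deduplicated, keeping the shortest specific length.
#'
#' @param template A `mir_template` from [make_template()].
#' @param config A [design_config()].
#' @return Data frame of candidates (possibly empty), one row each, with the
#'   final sequence, tail, specific part, template footprint (`fp_start`,
#'   `fp_end`; 0-based half-open), `five_prime_score` (10 if anchored at the
#'   microRNA 5' end, 5 if trimmed) and final Tm. `tm_reached` is `FALSE`
#'   when the tail cap was hit before the target temperature.
#' @export
build_forward_candidates <- function(template, config = design_config()) {
  stopifnot(inherits(template, "mir_template"))
  tmpl <- template$design_sequence
  n <- nchar(tmpl)
  target <- config$thermo$tm_target_C
  lo <- config$forward_specific_range[1]
  hi <- min(config$forward_specific_range[2], n)
  if (hi < lo) return(.empty_candidates())
  rows <- list()
  seen <- character(0)
  for (L in lo:hi) {
    spec <- substr(tmpl, 1, L)
    tm <- melting_temperature(spec, config$thermo)
    tail_k <- 0L
    trim <- 0L
    reached <- TRUE
    if (tm < target) {
      while (tm < target && tail_k < config$max_forward_tail) {
        tail_k <- tail_k + 1L
        tm <- melting_temperature(paste0(forward_tail(tail_k, config), spec),
                                  config$thermo)
      }
      if (tm < target) {
        reached <- FALSE
        warning(sprintf(
          "%s: forward candidate (specific %d nt) below %.1f C even with full tail",
          template$name, L, target), call. = FALSE)
      }
    } else if (tm > target) {
      # trimming removes template 5' bases; keep at least min_template_length
      while (tm > target && (L - trim) > config$min_template_length) {
        trim <- trim + 1L
        tm <- melting_temperature(substr(tmpl, 1 + trim, L), config$thermo)
      }
      if (tm > target && (L - trim) <= config$min_template_length) {
        warning(sprintf(
          "%s: forward candidate kept at %d nt despite Tm above target",
          template$name, L - trim), call. = FALSE)
      }
    }
    spec_final <- substr(tmpl, 1 + trim, L)
    tail <- forward_tail(tail_k, config)
    seqn <- paste0(tail, spec_final)
    if (seqn %in% seen) next
    seen <- c(seen, seqn)
    rows[[length(rows) + 1L]] <- data.frame(
      orientation = "forward", sequence = seqn, tail = tail,
      specific_part = spec_final, specific_length = nchar(spec_final),
      fp_start = trim, fp_end = L,
      five_prime_score = if (trim > 0L) 5L else 10L,
      tm = tm, tm_reached = reached, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Enumerate reverse primer candidates for a template
#'
#' One candidate per specific length `k` in `reverse_specific_range`: the
#' reverse complement of the template's 3'-terminal `k`-mer preceded by 15
#' T's (the poly(T) run shared with the RT primer). Cold candidates are
#' extended by prepending RT-tag nucleotides one at a time, consuming the tag
#' from its 3' end, until the Tm target is first reached or the tag is
#' exhausted (then a warning is issued and the maximal-length primer kept).
#'
#' @param template A `mir_template` from [make_template()].
#' @param config A [design_config()].
#' @return Data frame of candidates as in [build_forward_candidates()];
#'   `five_prime_score` is `NA` for reverse primers.
#' @export
build_reverse_candidates <- function(template, config = design_config()) {
  stopifnot(inherits(template, "mir_template"))
  tmpl <- template$design_sequence
  n <- nchar(tmpl)
  target <- config$thermo$tm_target_C
  polyT <- strrep("T", config$poly_t_length)
  tag <- config$rt_tag
  lo <- config$reverse_specific_range[1]
  hi <- min(config$reverse_specific_range[2], n)
  if (hi < lo) return(.empty_candidates())
  rows <- list()
  for (k in lo:hi) {
    spec_rc <- reverse_complement(substr(tmpl, n - k + 1, n))
    base <- paste0(polyT, spec_rc)
    j <- 0L
    tm <- melting_temperature(base, config$thermo)
    reached <- TRUE
    while (tm < target && j < nchar(tag)) {
      j <- j + 1L
      tm <- melting_temperature(
        paste0(substr(tag, nchar(tag) - j + 1, nchar(tag)), base),
        config$thermo)
    }
    if (tm < target) {
      reached <- FALSE
      warning(sprintf(
        "%s: reverse candidate (specific %d nt) below %.1f C with full RT tag",
        template$name, k, target), call. = FALSE)
    }
    tail <- if (j > 0L) substr(tag, nchar(tag) - j + 1, nchar(tag)) else ""
    rows[[length(rows) + 1L]] <- data.frame(
      orientation = "reverse", sequence = paste0(tail, base), tail = tail,
      specific_part = spec_rc, specific_length = k,
      fp_start = n - k, fp_end = n, five_prime_score = NA_integer_,
      tm = tm, tm_reached = reached, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Reconstruct a primer candidate from its final sequence
#'
#' Splits a given primer into tail and microRNA-specific part against a
#' template, so that externally supplied primers can be scored with the same
#' machinery as generated candidates. For a forward primer the specific part
#' is the longest primer suffix found in the template; for a reverse primer
#' it is the longest primer suffix that reverse-complements a template
#' suffix.
#'
#' @param sequence Primer sequence, 5' to 3' (case-insensitive, U as T).
#' @param template A `mir_template` or a DNA template string.
#' @param orientation `"forward"` or `"reverse"`.
#' @param config A [design_config()].
#' @return One-row candidate data frame as in [build_forward_candidates()].
#' @export
as_primer_candidate <- function(sequence, template,
                                orientation = c("forward", "reverse"),
                                config = design_config()) {
  orientation <- match.arg(orientation)
  tmpl <- if (inherits(template, "mir_template")) template$design_sequence
          else chartr("U", "T", toupper(template))
  s <- chartr("U", "T", toupper(sequence))
  n <- nchar(s)
  nt <- nchar(tmpl)
  spec_len <- 0L
  fp <- c(NA_integer_, NA_integer_)
  for (k in seq_len(min(n, nt))) {
    suff <- substr(s, n - k + 1, n)
    if (orientation == "forward") {
      pos <- regexpr(suff, tmpl, fixed = TRUE)
      if (pos > 0) {
        spec_len <- k
        fp <- c(pos - 1L, pos - 1L + k)
      }
    } else {
      if (suff == reverse_complement(substr(tmpl, nt - k + 1, nt))) {
        spec_len <- k
        fp <- c(nt - k, nt)
      }
    }
  }
  if (spec_len == 0L) {
    stop("primer has no microRNA-specific part matching the template",
         call. = FALSE)
  }
  spec <- substr(s, n - spec_len + 1, n)
  tail <- substr(s, 1, n - spec_len)
  data.frame(
    orientation = orientation, sequence = s, tail = tail,
    specific_part = spec, specific_length = spec_len,
    fp_start = fp[1], fp_end = fp[2],
    five_prime_score = if (orientation == "forward") {
      if (fp[1] == 0L) 10L else 5L
    } else NA_integer_,
    tm = melting_temperature(s, config$thermo), tm_reached = NA,
    stringsAsFactors = FALSE)
}
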
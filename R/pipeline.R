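#' Design and rank primer pairs for a set of microRNA targets
#'
#' Runs the full pipeline per target: template normalization (3' A-trimming),
#' forward and reverse candidate enumeration with Tm-adjusted tails, scoring,
#' pair enumeration with 3'-overlap exclusion, ranking, and pair-similarity
#' comparison. Targets that fail (e.g. too short after A-trimming) are
#' reported and skipped; the rest are processed.
#'
#' @param targets Data frame with columns `name` and `raw_sequence`, as
#'   returned by [parse_targets()] / [read_targets()].
#' @param config A [design_config()].
#' @return A list of class `mirdesign_result` with elements `targets` (a
#'   named list of per-target results: `template`, `forwards`, `reverses`,
#'   `pairs`, `best_pair`, `comparison`) and `failures` (named character
#'   vector of per-target error messages).
#' @export
design_primers <- function(targets, config = design_config()) {
  stopifnot(is.data.frame(targets), nrow(targets) >= 1)
  out <- list()
  failures <- character(0)
  for (i in seq_len(nrow(targets))) {
    rec <- targets[i, , drop = FALSE]
    res <- tryCatch({
      tmpl <- make_template(rec, config)
      fwd <- rank_candidates(
        score_candidates(build_forward_candidates(tmpl, config), config), "F")
      rev <- rank_candidates(
        score_candidates(build_reverse_candidates(tmpl, config), config), "R")
      pairs <- rank_pairs(enumerate_pairs(fwd, rev, tmpl, config))
      if (is.null(pairs)) {
        stop(sprintf("target '%s': no primer pair passes the 3'-overlap rule",
                     tmpl$name), call. = FALSE)
      }
      list(template = tmpl, forwards = fwd, reverses = rev, pairs = pairs,
           best_pair = pairs[1, , drop = FALSE],
           comparison = compare_pairs(pairs))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[rec$name]] <- conditionMessage(res)
    } else {
      out[[rec$name]] <- res
    }
  }
  structure(list(targets = out, failures = failures),
            class = "mirdesign_result")
}

#' @export
print.mirdesign_result <- function(x, ...) {
  cat(sprintf("<mirdesign_result> %d target(s) designed, %d failed\n",
              length(x$targets), length(x$failures)))
  for (nm in names(x$targets)) {
    bp <- x$targets[[nm]]$best_pair
    cat(sprintf("  %s: best pair %s + %s (score %s)\n", nm,
                bp$f_name, bp$r_name, format_score(bp$pair_score)))
  }
  for (nm in names(x$failures)) {
    cat(sprintf("  %s: FAILED (%s)\n", nm, x$failures[[nm]]))
  }
  invisible(x)
}

#' Run the complete design tool
#'
#' Thin wrapper used by the command-line interface: reads the input file,
#' designs primers for every target, writes the five report files, and
#' reports per-target failures without aborting the batch.
#'
#' @param input Path to the FASTA-like target list (default
#'   `input_miRs.txt` in the working directory).
#' @param out_dir Directory for the five report files (created if needed).
#' @param config A [design_config()].
#' @param crlf Write Windows line endings.
#' @param verbose Print progress messages.
#' @return The `mirdesign_result`, invisibly. Errors if the input is missing
#'   or empty, or if no target could be designed.
#' @export
run_mirdesign <- function(input = "input_miRs.txt", out_dir = ".",
                          config = design_config(), crlf = FALSE,
                          verbose = FALSE) {
  targets <- read_targets(input)
  if (verbose) {
    message(sprintf("read %d target(s) from %s", nrow(targets), input))
  }
  results <- design_primers(targets, config)
  for (nm in names(results$failures)) {
    warning(sprintf("target '%s' skipped: %s", nm, results$failures[[nm]]),
            call. = FALSE)
  }
  if (length(results$targets) == 0) {
    stop("no target could be designed", call. = FALSE)
  }
  write_outputs(results, out_dir, crlf = crlf)
  if (verbose) {
    message(sprintf("wrote 5 report files to %s", normalizePath(out_dir)))
  }
  invisible(results)
}

#' Generate random microRNA-like target records
#'
#' Seeded generator of synthetic records (uniform random bases, lengths
#' drawn uniformly from `length_range`, the typical size range of mature
#' microRNAs) for property tests and demonstrations. The sequences are
#' random and carry none of the base-composition biases of real microRNAs.
#'
#' @param n Number of records.
#' @param seed Integer seed (deterministic output).
#' @param length_range Inclusive length interval.
#' @param rna Emit RNA spelling (U) instead of DNA.
#' @return Data frame with columns `name` and `raw_sequence`.
#' @export
generate_random_targets <- function(n, seed = 1L,
                                    length_range = c(19L, 25L),
                                    rna = FALSE) {
  stopifnot(n >= 1, length(length_range) == 2,
            length_range[1] <= length_range[2])
  set.seed(seed)
  alphabet <- if (rna) c("A", "C", "G", "U") else c("A", "C", "G", "T")
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
  data.frame(name = sprintf("synth-miR-%03d", seq_len(n)),
             raw_sequence = seqs, stringsAsFactors = FALSE)
}
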
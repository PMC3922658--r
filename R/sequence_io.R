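#' Parse a list of microRNA targets from FASTA-like text
#'
#' Reads records of the form `>name` followed by one or more sequence lines.
#' Sequences may be RNA or DNA, upper- or lowercase; the original spelling is
#' preserved in `raw_sequence`. Wrapped sequence lines are concatenated and
#' blank lines are ignored.
#'
#' @param text Character scalar (whole file contents) or character vector of
#'   lines.
#' @return A data frame with columns `name` and `raw_sequence`, one row per
#'   record, in input order.
#' @details Record names must be unique within one input. Only the unambiguous
#'   bases `A`, `C`, `G`, `T`, `U` (either case) are accepted; IUPAC ambiguity
#'   codes are rejected with the offending line number. A header with no
#'   sequence line is an error.
#' @examples
#' parse_targets(">ssc-let-7a\nTGAGGTAGTAGGTTGTATAGTT")
#' @export
parse_targets <- function(text) {
  stopifnot(is.character(text), length(text) >= 1)
  lines <- if (length(text) == 1L) strsplit(text, "\r?\n")[[1]] else text
  lines <- sub("\r$", "", lines)
  if (all(!nzchar(trimws(lines)))) {
    stop("input contains no records", call. = FALSE)
  }
  names_out <- character(0)
  seqs_out <- character(0)
  cur_name <- NULL
  cur_seq <- character(0)
  flush <- function() {
    if (is.null(cur_name)) return()
    if (length(cur_seq) == 0) {
      stop(sprintf("record '%s' has a header but no sequence", cur_name),
           call. = FALSE)
    }
    names_out[length(names_out) + 1L] <<- cur_name
    seqs_out[length(seqs_out) + 1L] <<- paste(cur_seq, collapse = "")
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush()
      cur_name <- trimws(sub("^>", "", line))
      if (!nzchar(cur_name)) {
        stop(sprintf("line %d: empty record name", i), call. = FALSE)
      }
      cur_seq <- character(0)
    } else {
      if (is.null(cur_name)) {
        stop(sprintf("line %d: sequence before any '>' header", i),
             call. = FALSE)
      }
      if (grepl("[^ACGTUacgtu]", line)) {
        bad <- regmatches(line, regexpr("[^ACGTUacgtu]", line))
        stop(sprintf("line %d: invalid character '%s' in sequence of '%s'",
                     i, bad, cur_name), call. = FALSE)
      }
      cur_seq <- c(cur_seq, line)
    }
  }
  flush()
  if (length(names_out) == 0) {
    stop("input contains no records", call. = FALSE)
  }
  dup <- names_out[duplicated(names_out)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate record name: '%s'", dup[[1]]), call. = FALSE)
  }
  data.frame(name = names_out, raw_sequence = seqs_out,
             stringsAsFactors = FALSE)
}

#' Read targets from a file
#'
#' @param path Path to a FASTA-like text file (see [parse_targets()]).
#' @return A data frame of records, as [parse_targets()].
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  parse_targets(readLines(path, warn = FALSE))
}

#' Serialize target records back to FASTA-like text
#'
#' @param records Data frame with columns `name` and `raw_sequence`.
#' @return Character vector of lines (`>name` then sequence, per record).
#' @export
format_targets <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("name", "raw_sequence") %in% names(records)))
  as.vector(rbind(paste0(">", records$name), records$raw_sequence))
}

#' Write target records to a FASTA-like file
#'
#' @param records Data frame with columns `name` and `raw_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(records, path) {
  writeLines(format_targets(records), path)
  invisible(path)
}

#' Build the design template for one target
#'
#' Converts the record to an uppercase DNA string (U to T) and removes all
#' consecutive 3'-terminal A residues. On the poly(A)-tailed cDNA used for
#' microRNA-specific RT-qPCR those template positions are indistinguishable
#' from the poly(T) tract of the RT primer, so they carry no design
#' information.
#'
#' @param record One-row data frame (or list) with `name` and `raw_sequence`.
#' @param config A [design_config()] list; `min_template_length` is the
#'   shortest usable design sequence after A-trimming.
#' @return A list of class `mir_template` with fields `name`, `dna_sequence`,
#'   `trimmed_a_count` and `design_sequence`.
#' @examples
#' make_template(list(name = "x", raw_sequence = "UGAGGUAGUAGGUUGUAUAGUU"))
#' @export
make_template <- function(record, config = design_config()) {
  name <- as.character(record$name)
  raw <- as.character(record$raw_sequence)
  if (grepl("[^ACGTUacgtu]", raw)) {
    stop(sprintf("target '%s': sequence contains non-IUPAC characters", name),
         call. = FALSE)
  }
  dna <- chartr("U", "T", toupper(raw))
  design <- sub("A+$", "", dna)
  trimmed <- nchar(dna) - nchar(design)
  if (nchar(design) < config$min_template_length) {
    stop(sprintf(
      "target '%s': only %d designable nt remain after 3' A-trimming (minimum %d)",
      name, nchar(design), config$min_template_length), call. = FALSE)
  }
  structure(list(name = name,
                 dna_sequence = dna,
                 trimmed_a_count = trimmed,
                 design_sequence = design),
            class = "mir_template")
}

#' @export
print.mir_template <- function(x, ...) {
  cat(sprintf("<mir_template> %s\n  template: %s\n  design:   %s (%d 3' A removed)\n",
              x$name, x$dna_sequence, x$design_sequence, x$trimmed_a_count))
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string (case-insensitive; U treated as T).
#' @return Uppercase reverse complement.
#' @export
reverse_complement <- function(seq) {
  s <- chartr("U", "T", toupper(seq))
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}
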
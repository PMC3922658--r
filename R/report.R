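# Spreadsheet-compatible tab-separated report files. Five fixed filenames,
# one block per target, scores printed at 2-decimal precision with a single
# trailing zero dropped ("0.5", "1.0", "0.64").

.report_files <- c(best = "result_best_primer_pairs.txt",
                   all = "result_all_primer_pairs.txt",
                   fwd = "result_f_primers.txt",
                   rev = "result_r_primers.txt",
                   cmp = "result_comparison_of_pairs.txt")

#' Format a score the way the reports print it
#'
#' Half-up rounding to 2 decimals, then minimal decimal representation: a
#' trailing zero in the second decimal place is dropped (`0.5`, `1.0`) while
#' two significant decimals are kept (`0.64`).
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
format_score <- function(x) {
  r <- sign(x) * floor(abs(x) * 100 + 0.5) / 100
  s <- sprintf("%.2f", r)
  sub("(\\.\\d)0$", "\\1", s)
}

.fwd_header <- c("Name", "Seq", "Length", "score", "two_last_score",
                 "three_last_score", "five_last_score", "three_self_anneal",
                 "internal_self_anneal", "five_prime_score")
.rev_header <- .fwd_header[-length(.fwd_header)]
.pair_header <- c("Name", "Sequence", "Score", "Fprimer_anneal",
                  "Rprimer_anneal", "Primer_dimer")

.candidate_rows <- function(df, with_five_prime) {
  vapply(seq_len(nrow(df)), function(i) {
    row <- c(df$name[i], tolower(df$sequence[i]), df$specific_length[i],
             format_score(c(df$score[i], df$two_last_score[i],
                            df$three_last_score[i], df$five_last_score[i],
                            df$three_self_anneal[i],
                            df$internal_self_anneal[i])))
    if (with_five_prime) row <- c(row, df$five_prime_score[i])
    paste(row, collapse = "\t")
  }, character(1))
}

.pair_block <- function(p, first_col) {
  c(paste(c(first_col, "", format_score(c(p$pair_score, p$fprimer_anneal,
                                          p$rprimer_anneal, p$primer_dimer))),
          collapse = "\t"),
    paste(c(p$f_name, tolower(p$f_sequence), format_score(p$f_score)),
          collapse = "\t"),
    paste(c(p$r_name, tolower(p$r_sequence), format_score(p$r_score)),
          collapse = "\t"))
}

#' Write the five report files
#'
#' Produces `result_best_primer_pairs.txt`, `result_all_primer_pairs.txt`,
#' `result_f_primers.txt`, `result_r_primers.txt` and
#' `result_comparison_of_pairs.txt` in `out_dir`. All files are
#' tab-separated text that opens directly in spreadsheet programs.
#'
#' @param results A `mirdesign_result` from [design_primers()].
#' @param out_dir Output directory (created if missing).
#' @param crlf Use Windows (CRLF) line endings.
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_outputs <- function(results, out_dir = ".", crlf = FALSE) {
  stopifnot(inherits(results, "mirdesign_result"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory: %s", out_dir),
                  call. = FALSE)
  }
  if (file.access(out_dir, mode = 2) != 0) {
    stop(sprintf("output directory not writable: %s", out_dir), call. = FALSE)
  }
  eol <- if (crlf) "\r\n" else "\n"
  best <- character(0); allp <- character(0)
  fwd <- character(0); rev <- character(0); cmp <- character(0)
  for (nm in names(results$targets)) {
    tg <- results$targets[[nm]]
    tmpl_lc <- tolower(tg$template$design_sequence)
    fwd <- c(fwd, paste(nm, tmpl_lc, sep = "\t"), "Primers",
             paste(.fwd_header, collapse = "\t"),
             .candidate_rows(tg$forwards, with_five_prime = TRUE), "")
    rev <- c(rev, paste(nm, tmpl_lc, sep = "\t"), "Primers",
             paste(.rev_header, collapse = "\t"),
             .candidate_rows(tg$reverses, with_five_prime = FALSE), "")
    bp <- tg$best_pair
    best <- c(best, paste(.pair_header, collapse = "\t"),
              paste(c(nm, tmpl_lc,
                      format_score(c(bp$pair_score, bp$fprimer_anneal,
                                     bp$rprimer_anneal, bp$primer_dimer))),
                    collapse = "\t"),
              paste(c(bp$f_name, tolower(bp$f_sequence),
                      format_score(bp$f_score)), collapse = "\t"),
              paste(c(bp$r_name, tolower(bp$r_sequence),
                      format_score(bp$r_score)), collapse = "\t"), "")
    allp <- c(allp, paste(nm, tmpl_lc, sep = "\t"),
              paste(.pair_header, collapse = "\t"))
    for (i in seq_len(nrow(tg$pairs))) {
      allp <- c(allp, .pair_block(tg$pairs[i, ], tg$pairs$name[i]))
    }
    allp <- c(allp, "")
    cm <- tg$comparison
    cmp <- c(cmp, nm,
             paste(c("", colnames(cm)), collapse = "\t"),
             vapply(seq_len(nrow(cm)), function(i) {
               paste(c(rownames(cm)[i], format_score(cm[i, ])),
                     collapse = "\t")
             }, character(1)), "")
  }
  paths <- file.path(out_dir, .report_files)
  names(paths) <- names(.report_files)
  contents <- list(best = best, all = allp, fwd = fwd, rev = rev, cmp = cmp)
  for (key in names(paths)) {
    con <- file(paths[[key]], open = "wb")
    writeLines(contents[[key]], con, sep = eol)
    close(con)
  }
  invisible(paths)
}

.split_blocks <- function(lines) {
  lines <- sub("\r$", "", lines)
  out <- list(); cur <- character(0)
  for (ln in lines) {
    if (!nzchar(ln)) {
      if (length(cur)) out[[length(out) + 1L]] <- cur
      cur <- character(0)
    } else cur <- c(cur, ln)
  }
  if (length(cur)) out[[length(out) + 1L]] <- cur
  out
}

#' Read back a forward- or reverse-primer report
#'
#' @param path Path to `result_f_primers.txt` or `result_r_primers.txt`.
#' @return Named list (per target) of data frames at printed precision, with
#'   the target's template sequence as attribute `"template"`.
#' @export
read_primer_report <- function(path) {
  blocks <- .split_blocks(readLines(path, warn = FALSE))
  out <- list()
  for (b in blocks) {
    head <- strsplit(b[1], "\t", fixed = TRUE)[[1]]
    cols <- strsplit(b[3], "\t", fixed = TRUE)[[1]]
    rows <- strsplit(b[-(1:3)], "\t", fixed = TRUE)
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- cols
    for (nm in setdiff(cols, c("Name", "Seq"))) df[[nm]] <- as.numeric(df[[nm]])
    attr(df, "template") <- head[2]
    out[[head[1]]] <- df
  }
  out
}

#' Read back a primer-pair report
#'
#' Handles both `result_best_primer_pairs.txt` and
#' `result_all_primer_pairs.txt`.
#'
#' @param path Report path.
#' @return Named list (per target) of data frames, one row per pair, at
#'   printed precision.
#' @export
read_pair_report <- function(path) {
  blocks <- .split_blocks(readLines(path, warn = FALSE))
  out <- list()
  for (b in blocks) {
    first <- strsplit(b[1], "\t", fixed = TRUE)[[1]]
    if (identical(first[1], "Name")) {
      # best-pairs layout: header, target row, F row, R row
      tgt <- strsplit(b[2], "\t", fixed = TRUE)[[1]]
      f <- strsplit(b[3], "\t", fixed = TRUE)[[1]]
      r <- strsplit(b[4], "\t", fixed = TRUE)[[1]]
      out[[tgt[1]]] <- data.frame(
        pair = "Pair_1", f_name = f[1], r_name = r[1],
        f_sequence = f[2], r_sequence = r[2],
        f_score = as.numeric(f[3]), r_score = as.numeric(r[3]),
        pair_score = as.numeric(tgt[3]),
        fprimer_anneal = as.numeric(tgt[4]),
        rprimer_anneal = as.numeric(tgt[5]),
        primer_dimer = as.numeric(tgt[6]), stringsAsFactors = FALSE)
    } else {
      # all-pairs layout: target line, header, then 3-line pair blocks
      tgt <- first[1]
      body <- b[-(1:2)]
      rows <- list()
      for (i in seq(1, length(body), by = 3)) {
        p <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
        f <- strsplit(body[i + 1], "\t", fixed = TRUE)[[1]]
        r <- strsplit(body[i + 2], "\t", fixed = TRUE)[[1]]
        rows[[length(rows) + 1L]] <- data.frame(
          pair = p[1], f_name = f[1], r_name = r[1],
          f_sequence = f[2], r_sequence = r[2],
          f_score = as.numeric(f[3]), r_score = as.numeric(r[3]),
          pair_score = as.numeric(p[3]),
          fprimer_anneal = as.numeric(p[4]),
          rprimer_anneal = as.numeric(p[5]),
          primer_dimer = as.numeric(p[6]), stringsAsFactors = FALSE)
      }
      out[[tgt]] <- do.call(rbind, rows)
    }
  }
  out
}

#' Read back a pair-comparison report
#'
#' @param path Path to `result_comparison_of_pairs.txt`.
#' @return Named list (per target) of numeric similarity matrices at printed
#'   precision.
#' @export
read_comparison_report <- function(path) {
  blocks <- .split_blocks(readLines(path, warn = FALSE))
  out <- list()
  for (b in blocks) {
    tgt <- strsplit(b[1], "\t", fixed = TRUE)[[1]][1]
    cols <- strsplit(b[2], "\t", fixed = TRUE)[[1]][-1]
    rows <- strsplit(b[-(1:2)], "\t", fixed = TRUE)
    m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
    dimnames(m) <- list(vapply(rows, `[[`, character(1), 1), cols)
    out[[tgt]] <- m
  }
  out
}
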
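# The Syntax Checker: a non-throwing acceptor with halt-position
# reporting, description-form classification, and batch mode.

probe_description <- function(text, level, dialect,
                              forms = DESCRIPTION_FORMS) {
  if (level == "dna_rna") {
    dna_parse_all_forms(text, dialect, tree = FALSE, forms = forms)
  } else {
    protein_parse_all_forms(text, dialect, tree = FALSE, forms = forms)
  }
}

new_syntax_result <- function(input, level, dialect, valid, halt_position,
                              matched_form, message) {
  structure(list(input = input, level = level, dialect = dialect,
                 valid = valid,
                 halt_position = if (valid) NA_integer_
                                 else as.integer(halt_position),
                 matched_form = matched_form, message = message),
            class = "hgvs_syntax_result")
}

#' Check the syntax of one variant description
#'
#' Runs the parser as an acceptor. Entry points are tried in the order
#' `full` (with reference part), `coordinate_prefixed`, `bare`; the input
#' is valid if any entry point consumes every character. On rejection the
#' halt position is the furthest 0-based offset any attempt required — the
#' first character the parser could not consume under its most successful
#' reading. All outcomes, including the empty string, are encoded in the
#' result; this function never throws on ordinary input.
#'
#' @param text The description to check (any single string, possibly
#'   empty).
#' @param level `"dna_rna"` or `"protein"`; the two grammars are checked
#'   independently, with no auto-detection.
#' @param dialect `"strict"`, `"legacy"` or `"lenient"`.
#' @return An object of class `hgvs_syntax_result` with fields `valid`,
#'   `halt_position` (`NA` when valid), `matched_form` (`"full"`,
#'   `"coordinate_prefixed"`, `"bare"` or `"none"`) and `message`.
#' @examples
#' hgvs_check("NM_003002.2:c.274G>T")
#' hgvs_check("c.274G>")$halt_position
#' @export
hgvs_check <- function(text, level = "dna_rna", dialect = "strict") {
  level <- match_arg2(level, LEVELS, "level")
  dialect <- match_arg2(dialect, DIALECTS, "dialect")
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) {
    return(new_syntax_result(NA_character_, level, dialect, FALSE, 0L,
                             "none", "missing input"))
  }
  res <- probe_description(text, level, dialect)
  if (res$ok) {
    new_syntax_result(text, level, dialect, TRUE, NA_integer_,
                      res$matched_form, "")
  } else {
    new_syntax_result(text, level, dialect, FALSE, res$far, "none",
                      sprintf("syntax error at position %d", res$far))
  }
}

#' Classify the form of a description token
#'
#' Returns the most complete description form the token matches: `"full"`
#' (reference, coordinate system and body, e.g. `NM_003002.2:c.274G>T`),
#' `"coordinate_prefixed"` (`c.274G>T`), `"bare"` (`274G>T`), or `"none"`.
#'
#' @inheritParams hgvs_check
#' @param word A single whitespace-free token.
#' @return A length-one character vector.
#' @examples
#' hgvs_classify("c.274G>T")
#' hgvs_classify("hello")
#' @export
hgvs_classify <- function(word, level = "dna_rna", dialect = "strict") {
  res <- hgvs_check(word, level, dialect)
  res$matched_form
}

#' Batch syntax checking
#'
#' Checks a vector of records, one description per record, as read from a
#' one-word-per-line (possibly tab-delimited) file: each record is
#' stripped of surrounding whitespace and only its first tab-separated
#' field is checked. A record that still contains whitespace after
#' stripping is flagged invalid rather than crashing the run. One result
#' row is produced per record, in input order.
#'
#' @inheritParams hgvs_check
#' @param records Character vector of input records (lines).
#' @return A tibble of class `hgvs_batch_report` with columns `input`,
#'   `level`, `dialect`, `valid`, `matched_form`, `halt_position`,
#'   `message`, carrying a `summary` attribute with the valid/invalid
#'   counts (see [glance()]).
#' @examples
#' hgvs_batch_check(c("NM_003002.2:c.274G>T", "274G>T", "notavariant"))
#' @export
hgvs_batch_check <- function(records, level = "dna_rna",
                             dialect = "strict") {
  level <- match_arg2(level, LEVELS, "level")
  dialect <- match_arg2(dialect, DIALECTS, "dialect")
  records <- as.character(records)
  check_one <- function(line) {
    token <- trimws(line)
    token <- strsplit(token, "\t", fixed = TRUE)[[1]]
    token <- if (length(token)) token[[1]] else ""
    if (grepl("[[:space:]]", token)) {
      return(new_syntax_result(token, level, dialect, FALSE, 0L, "none",
                               "record contains internal whitespace"))
    }
    hgvs_check(token, level, dialect)
  }
  results <- lapply(records, check_one)
  out <- tibble::tibble(
    input = vapply(results, function(x) x$input, character(1)),
    level = level,
    dialect = dialect,
    valid = vapply(results, function(x) x$valid, logical(1)),
    matched_form = vapply(results, function(x) x$matched_form, character(1)),
    halt_position = vapply(results, function(x) x$halt_position, integer(1)),
    message = vapply(results, function(x) x$message, character(1))
  )
  if (!nrow(out)) {
    out$level <- character()
    out$dialect <- character()
  }
  attr(out, "summary") <- list(n = nrow(out), n_valid = sum(out$valid),
                               n_invalid = sum(!out$valid))
  class(out) <- c("hgvs_batch_report", class(out))
  out
}

#' Read batch input / write a batch report
#'
#' `hgvs_read_batch()` reads a one-record-per-line text file;
#' `hgvs_write_batch_report()` writes a report as tab-separated values
#' with a header row, followed by nothing else, so the output stream is
#' machine-parseable.
#'
#' @param path File path (or a connection for writing; default stdout).
#' @param report An `hgvs_batch_report` from [hgvs_batch_check()].
#' @return `hgvs_read_batch()`: a character vector of records;
#'   `hgvs_write_batch_report()`: the report, invisibly.
#' @export
hgvs_read_batch <- function(path) {
  readLines(path, warn = FALSE)
}

#' @rdname hgvs_read_batch
#' @export
hgvs_write_batch_report <- function(report, path = stdout()) {
  df <- as.data.frame(report)
  df$halt_position <- ifelse(is.na(df$halt_position), "",
                             as.character(df$halt_position))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(report)
}

#' @export
print.hgvs_syntax_result <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<hgvs_syntax_result> valid %s (%s, %s)\n", x$matched_form,
                x$level, x$dialect))
  } else {
    cat(sprintf("<hgvs_syntax_result> invalid at %d (%s, %s): %s\n",
                x$halt_position, x$level, x$dialect, x$message))
  }
  invisible(x)
}
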
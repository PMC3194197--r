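# broom-style tidiers and plotting for result objects.

#' Tidy a parse result into a node table
#'
#' Flattens the parse tree into one row per node, depth-first, with
#' 0-based half-open spans into the input.
#'
#' @param x An `hgvs_parsed` object (parsed with `tree = TRUE`).
#' @param ... Unused.
#' @return A tibble with columns `rule`, `start`, `end`, `text`, `depth`,
#'   `leaf`.
#' @examples
#' tidy(hgvs_parse_genotype("c.274G>T"))
#' @export
tidy.hgvs_parsed <- function(x, ...) {
  if (is.null(x$tree)) {
    stop("no parse tree recorded; reparse with tree = TRUE", call. = FALSE)
  }
  rows <- list()
  walk <- function(n, depth) {
    rows[[length(rows) + 1L]] <<- list(rule = n$rule,
                                       start = as.integer(n$span[[1]]),
                                       end = as.integer(n$span[[2]]),
                                       text = n$text, depth = depth,
                                       leaf = !length(n$children))
    for (ch in n$children) walk(ch, depth + 1L)
  }
  walk(x$tree, 0L)
  tibble::tibble(
    rule = vapply(rows, `[[`, character(1), "rule"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    text = vapply(rows, `[[`, character(1), "text"),
    depth = vapply(rows, `[[`, integer(1), "depth"),
    leaf = vapply(rows, `[[`, logical(1), "leaf"))
}

#' @rdname tidy.hgvs_parsed
#' @export
tidy.hgvs_syntax_result <- function(x, ...) {
  tibble::tibble(input = x$input, level = x$level, dialect = x$dialect,
                 valid = x$valid, matched_form = x$matched_form,
                 halt_position = x$halt_position, message = x$message)
}

#' Summarize a batch report
#'
#' @param x An `hgvs_batch_report` from [hgvs_batch_check()].
#' @param ... Unused.
#' @return A one-row tibble with record counts.
#' @examples
#' glance(hgvs_batch_check(c("274G>T", "nope")))
#' @export
glance.hgvs_batch_report <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(n = s$n, n_valid = s$n_valid, n_invalid = s$n_invalid,
                 prop_valid = if (s$n) s$n_valid / s$n else NA_real_)
}

#' Plot a batch report
#'
#' Bar chart of record counts by matched description form, split by
#' verdict.
#'
#' @param object An `hgvs_batch_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hgvs_batch_report <- function(object, ...) {
  df <- as.data.frame(object)
  df$verdict <- ifelse(df$valid, "valid", "invalid")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$matched_form,
                                   fill = .data$verdict)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "matched form", y = "records",
                  title = "Syntax-checker batch report") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
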
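# Structured (machine-readable) export of parse trees.

#' Export a parse tree as a structured interchange tree
#'
#' Converts a parse node into nested plain lists with the stable key order
#' `rule`, `span`, `text`, `children`: leaves carry `rule`/`span`/`text`,
#' internal nodes `rule`/`span`/`children`. Spans are 0-based, half-open
#' character offsets into the input; the export is lossless.
#'
#' @param x A parse node, or an `hgvs_parsed` object (its tree is used;
#'   it must have been parsed with `tree = TRUE`).
#' @return A nested list mirroring the parse tree.
#' @examples
#' p <- hgvs_parse_genotype("274G>T")
#' str(hgvs_to_structured(p), max.level = 2)
#' @export
hgvs_to_structured <- function(x) {
  if (inherits(x, "hgvs_parsed")) {
    if (is.null(x$tree)) {
      stop("no parse tree recorded; reparse with tree = TRUE", call. = FALSE)
    }
    x <- x$tree
  }
  export_node <- function(n) {
    if (length(n$children)) {
      list(rule = n$rule, span = as.integer(n$span),
           children = lapply(n$children, export_node))
    } else {
      list(rule = n$rule, span = as.integer(n$span), text = n$text)
    }
  }
  export_node(x)
}

#' Serialize a parse tree to JSON
#'
#' JSON rendering of [hgvs_to_structured()]: objects with keys `rule`,
#' `span` (a two-element array), `text` (leaves) and `children` (internal
#' nodes).
#'
#' @inheritParams hgvs_to_structured
#' @param pretty Indent the output.
#' @return A `json` character scalar (from \pkg{jsonlite}).
#' @examples
#' hgvs_tree_json(hgvs_parse_genotype("274G>T"))
#' @export
hgvs_tree_json <- function(x, pretty = FALSE) {
  jsonlite::toJSON(hgvs_to_structured(x), auto_unbox = TRUE, pretty = pretty)
}

tree_leaves <- function(n) {
  if (!length(n$children)) return(list(n))
  do.call(c, lapply(n$children, tree_leaves))
}

tree_leaf_text <- function(x) {
  if (inherits(x, "hgvs_parsed")) x <- x$tree
  paste(vapply(tree_leaves(x), function(l) l$text, character(1)),
        collapse = "")
}
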
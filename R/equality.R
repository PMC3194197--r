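# Structural equality of AST records.

normalize_ast <- function(x) {
  if (inherits(x, "hgvs_aa")) {
    x$style <- "three_letter"
    if (x$code3 == AA_STOP3) x$code1 <- "*"
    return(x)
  }
  if (is.list(x)) {
    for (i in seq_along(x)) {
      if (!is.null(x[[i]])) x[[i]] <- normalize_ast(x[[i]])
    }
  }
  x
}

#' Structural equality of two AST records
#'
#' Field-for-field comparison. By default the comparison is
#' surface-faithful: the recorded amino-acid code style and substitution
#' operator must match. With `normalize = TRUE` the amino-acid `style`
#' field (and the stop-codon surface) is ignored, so `p.S124R` and
#' `p.Ser124Arg` compare equal.
#'
#' @param a,b AST records (genotypes, protein variants, or any
#'   sub-records).
#' @param normalize Ignore amino-acid surface style.
#' @return `TRUE` or `FALSE`.
#' @examples
#' a <- hgvs_parse_protein("p.Ser124Arg")$ast
#' b <- hgvs_parse_protein("p.S124R")$ast
#' hgvs_equal(a, b)
#' hgvs_equal(a, b, normalize = TRUE)
#' @export
hgvs_equal <- function(a, b, normalize = FALSE) {
  if (normalize) {
    a <- normalize_ast(a)
    b <- normalize_ast(b)
  }
  identical(a, b)
}
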
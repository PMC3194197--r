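# Protein-level AST records.

#' Amino-acid record
#'
#' One residue with both its three-letter and one-letter codes and the
#' surface style it was written in. Stop codons are `Ter` (three-letter)
#' and `*` or the legacy `X` (one-letter); all three are accepted on input
#' and `Ter` is the canonical serialization.
#'
#' @param code A three-letter code (`"Ser"`, `"Ter"`) or one-letter code
#'   (`"S"`, `"*"`, `"X"`); the style is inferred from the surface form
#'   unless `style` is given.
#' @param style `"three_letter"` or `"one_letter"`, or `NULL` to infer.
#' @return An object of class `hgvs_aa` with fields `code3`, `code1`,
#'   `style`.
#' @examples
#' hgvs_aa("Ser")
#' hgvs_aa("G")
#' @export
hgvs_aa <- function(code, style = NULL) {
  if (!is.character(code) || length(code) != 1L) {
    stop_field("code", "must be a single string")
  }
  if (code == AA_STOP3) {
    code3 <- AA_STOP3; code1 <- "*"
    inferred <- "three_letter"
  } else if (code %in% AA_STOP1) {
    code3 <- AA_STOP3; code1 <- code
    inferred <- "one_letter"
  } else if (code %in% AA_TABLE$code3) {
    i <- match(code, AA_TABLE$code3)
    code3 <- AA_TABLE$code3[i]; code1 <- AA_TABLE$code1[i]
    inferred <- "three_letter"
  } else if (code %in% AA_TABLE$code1) {
    i <- match(code, AA_TABLE$code1)
    code3 <- AA_TABLE$code3[i]; code1 <- AA_TABLE$code1[i]
    inferred <- "one_letter"
  } else {
    stop_field("code", sprintf("unknown amino-acid code \"%s\"", code))
  }
  if (is.null(style)) style <- inferred
  style <- match_arg2(style, c("three_letter", "one_letter"), "style")
  structure(list(code3 = code3, code1 = code1, style = style),
            class = "hgvs_aa")
}

#' Amino-acid locations
#'
#' `hgvs_aa_loc()` is one residue with its position (`Ser124`);
#' `hgvs_aa_range()` joins two such locations with `_`. Mixed one-/three-
#' letter styles across a range parse but are reported by
#' [hgvs_lint_mixed_code()].
#'
#' @param aa An [hgvs_aa()].
#' @param position Positive integer.
#' @param start,end [hgvs_aa_loc()] endpoints.
#' @return Objects of class `hgvs_aa_loc` / `hgvs_aa_range`.
#' @export
hgvs_aa_loc <- function(aa, position) {
  if (!inherits(aa, "hgvs_aa")) stop_field("aa", "must be an hgvs_aa")
  structure(list(aa = aa,
                 position = int_or_na(position, "position", allow_na = FALSE)),
            class = "hgvs_aa_loc")
}

#' @rdname hgvs_aa_loc
#' @export
hgvs_aa_range <- function(start, end) {
  if (!inherits(start, "hgvs_aa_loc")) stop_field("start", "must be an hgvs_aa_loc")
  if (!inherits(end, "hgvs_aa_loc")) stop_field("end", "must be an hgvs_aa_loc")
  structure(list(start = start, end = end), class = "hgvs_aa_range")
}

need_aaloc <- function(x, field, range_ok = TRUE) {
  if (inherits(x, "hgvs_aa_loc")) return(x)
  if (range_ok && inherits(x, "hgvs_aa_range")) return(x)
  stop_field(field, if (range_ok) "must be an hgvs_aa_loc or hgvs_aa_range"
             else "must be an hgvs_aa_loc")
}

check_aaseq <- function(x, field) {
  if (!is.list(x) || !length(x) ||
      !all(vapply(x, inherits, logical(1), "hgvs_aa"))) {
    stop_field(field, "must be a non-empty list of hgvs_aa records")
  }
  x
}

#' Protein-variant record
#'
#' A complete protein-level description: optional reference, optional `p.`
#' prefix (absent for bare forms such as `Gly123del`), a predicted flag
#' (body wrapped in parentheses), and a typed body — substitution,
#' deletion, duplication, insertion, deletion-insertion, frameshift,
#' `=` (no change), `?` (unknown) or `0` (no protein).
#'
#' @param type One of `"subst"`, `"del"`, `"dup"`, `"ins"`, `"delins"`,
#'   `"fs"`, `"no_change"`, `"unknown"`, `"no_protein"`.
#' @param loc An [hgvs_aa_loc()] (or range where allowed), `NULL` for the
#'   markers.
#' @param to Replacement residue ([hgvs_aa()]) for substitutions.
#' @param inserted For `ins`: `list(kind = "seq", value = <list of hgvs_aa>)`
#'   or `list(kind = "length", value = <int>)`; for `delins`: the seq form.
#' @param first_new First residue of the new reading frame (frameshift),
#'   or `NULL`.
#' @param new_stop For frameshifts, `NULL` or
#'   `list(surface = "Ter"|"*"|"X", count = <int or NA>)`; requires
#'   `first_new`.
#' @param ref An [hgvs_refseq()].
#' @param prefixed Whether the `p.` prefix was present.
#' @param predicted Whether the body is parenthesized as a prediction.
#' @return An object of class `hgvs_protein_variant`.
#' @examples
#' hgvs_protein_variant("subst", loc = hgvs_aa_loc(hgvs_aa("Ser"), 124),
#'                      to = hgvs_aa("Arg"))
#' @export
hgvs_protein_variant <- function(type, loc = NULL, to = NULL, inserted = NULL,
                                 first_new = NULL, new_stop = NULL,
                                 ref = hgvs_refseq(), prefixed = TRUE,
                                 predicted = FALSE) {
  type <- match_arg2(type, c("subst", "del", "dup", "ins", "delins", "fs",
                             "no_change", "unknown", "no_protein"), "type")
  if (!inherits(ref, "hgvs_refseq")) stop_field("ref", "must be an hgvs_refseq")
  if (ref$kind != "none" && !prefixed) {
    stop_field("prefixed", "a reference part requires the p. prefix")
  }
  switch(type,
    subst = {
      loc <- need_aaloc(loc, "loc", range_ok = FALSE)
      if (!inherits(to, "hgvs_aa")) stop_field("to", "must be an hgvs_aa")
    },
    del = , dup = {
      loc <- need_aaloc(loc, "loc")
    },
    ins = {
      if (!inherits(loc, "hgvs_aa_range")) {
        stop_field("loc", "insertion requires an hgvs_aa_range")
      }
      if (!is.list(inserted) || !inserted$kind %in% c("seq", "length")) {
        stop_field("inserted", "must be list(kind = \"seq\"|\"length\", value =)")
      }
      if (inserted$kind == "seq") {
        inserted$value <- check_aaseq(inserted$value, "inserted")
      } else {
        inserted$value <- int_or_na(inserted$value, "inserted", allow_na = FALSE)
      }
    },
    delins = {
      loc <- need_aaloc(loc, "loc")
      if (!is.list(inserted) || !identical(inserted$kind, "seq")) {
        stop_field("inserted", "delins inserts an amino-acid sequence")
      }
      inserted$value <- check_aaseq(inserted$value, "inserted")
    },
    fs = {
      loc <- need_aaloc(loc, "loc", range_ok = FALSE)
      if (!is.null(first_new) && !inherits(first_new, "hgvs_aa")) {
        stop_field("first_new", "must be an hgvs_aa or NULL")
      }
      if (!is.null(new_stop)) {
        if (is.null(first_new)) {
          stop_field("new_stop", "a new stop position requires first_new")
        }
        if (!is.list(new_stop) ||
            !new_stop$surface %in% c(AA_STOP3, AA_STOP1)) {
          stop_field("new_stop", "surface must be Ter, * or X")
        }
        new_stop <- list(surface = new_stop$surface,
                         count = int_or_na(new_stop$count, "new_stop$count"))
      }
    },
    {
      if (!is.null(loc)) stop_field("loc", "marker bodies carry no location")
    })
  structure(list(ref = ref, prefixed = isTRUE(prefixed),
                 predicted = isTRUE(predicted), type = type, loc = loc,
                 to = to, inserted = inserted, first_new = first_new,
                 new_stop = new_stop),
            class = "hgvs_protein_variant")
}
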
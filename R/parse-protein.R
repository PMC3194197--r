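# The protein-level grammar (top rule "ProteinVar") as a recursive-descent
# parser: substitution, deletion, duplication, insertion,
# deletion-insertion, frameshift, and the =/?/0 markers, in three-letter
# or one-letter amino-acid code.

AA1_ALL <- c(AA_TABLE$code1, AA_STOP1)
AA3_ALL <- c(AA_TABLE$code3, AA_STOP3)

p_aa <- function(ps) {
  start <- ps$pos
  c1 <- ps_need(ps, ps$pos)
  if (is.na(c1)) return(NULL)
  c2 <- ps_need(ps, ps$pos + 1L)
  if (!is.na(c2)) {
    c3 <- ps_need(ps, ps$pos + 2L)
    if (!is.na(c3)) {
      tok3 <- paste0(c1, c2, c3)
      if (tok3 %in% AA3_ALL) {
        ps$pos <- ps$pos + 3L
        return(r(b_aa(tok3), leafnode(ps, "AA", start)))
      }
    }
  }
  if (c1 %in% AA1_ALL) {
    ps$pos <- ps$pos + 1L
    return(r(b_aa(c1), leafnode(ps, "AA", start)))
  }
  NULL
}

p_aaseq <- function(ps) {
  start <- ps$pos
  first <- p_aa(ps)
  if (is.null(first)) return(NULL)
  seq <- list(first$ast)
  kids <- list(first$node)
  repeat {
    nxt <- p_aa(ps)
    if (is.null(nxt)) break
    seq <- c(seq, list(nxt$ast))
    kids <- c(kids, list(nxt$node))
  }
  r(seq, node(ps, "AASeq", start, kids))
}

p_aaloc <- function(ps) {
  start <- ps$pos
  aa <- p_aa(ps)
  if (is.null(aa)) return(NULL)
  n <- p_num(ps)
  if (is.null(n)) {
    ps$pos <- start
    return(NULL)
  }
  r(b_aaloc(aa$ast, n$ast), node(ps, "AALoc", start,
                                 list(aa$node, n$node)))
}

# AALoc or AARange, range preferred when "_" follows.
p_ploc <- function(ps) {
  start <- ps$pos
  l1 <- p_aaloc(ps)
  if (is.null(l1)) return(NULL)
  sv <- ps$pos
  us <- p_lit(ps, "_")
  if (!is.null(us)) {
    l2 <- p_aaloc(ps)
    if (!is.null(l2)) {
      return(r(b_aarange(l1$ast, l2$ast),
               node(ps, "AARange", start, list(l1$node, us$node, l2$node))))
    }
    ps$pos <- sv
  }
  l1
}

p_stop_surface <- function(ps) {
  x <- p_lit(ps, AA_STOP3, "Sym")
  if (!is.null(x)) return(x)
  x <- p_lit(ps, "*", "Sym")
  if (!is.null(x)) return(x)
  p_lit(ps, "X", "Sym")
}

p_pbody <- function(ps) {
  start <- ps$pos
  x <- p_lit(ps, "=", "NoChange")
  if (!is.null(x)) {
    return(r(list(type = "no_change"), x$node))
  }
  x <- p_lit(ps, "?", "Unknown")
  if (!is.null(x)) {
    return(r(list(type = "unknown"), x$node))
  }
  x <- p_lit(ps, "0", "NoProtein")
  if (!is.null(x)) {
    return(r(list(type = "no_protein"), x$node))
  }
  loc <- p_ploc(ps)
  if (is.null(loc)) return(NULL)
  is_range <- inherits(loc$ast, "hgvs_aa_range")
  kw <- p_lit(ps, "delins")
  if (!is.null(kw)) {
    seq <- p_aaseq(ps)
    if (is.null(seq)) {
      ps$pos <- start
      return(NULL)
    }
    return(r(list(type = "delins", loc = loc$ast,
                  inserted = list(kind = "seq", value = seq$ast)),
             node(ps, "PIndel", start, list(loc$node, kw$node, seq$node))))
  }
  kw <- p_lit(ps, "del")
  if (!is.null(kw)) {
    return(r(list(type = "del", loc = loc$ast),
             node(ps, "PDel", start, list(loc$node, kw$node))))
  }
  kw <- p_lit(ps, "dup")
  if (!is.null(kw)) {
    return(r(list(type = "dup", loc = loc$ast),
             node(ps, "PDup", start, list(loc$node, kw$node))))
  }
  if (is_range) {
    kw <- p_lit(ps, "ins")
    if (!is.null(kw)) {
      seq <- p_aaseq(ps)
      if (!is.null(seq)) {
        return(r(list(type = "ins", loc = loc$ast,
                      inserted = list(kind = "seq", value = seq$ast)),
                 node(ps, "PIns", start, list(loc$node, kw$node, seq$node))))
      }
      n <- p_num(ps)
      if (!is.null(n)) {
        return(r(list(type = "ins", loc = loc$ast,
                      inserted = list(kind = "length", value = n$ast)),
                 node(ps, "PIns", start, list(loc$node, kw$node, n$node))))
      }
    }
    ps$pos <- start
    return(NULL)
  }
  # point location: frameshift without new residue ...
  kw <- p_lit(ps, "fs")
  if (!is.null(kw)) {
    return(r(list(type = "fs", loc = loc$ast),
             node(ps, "PFs", start, list(loc$node, kw$node))))
  }
  # ... or a replacement residue, possibly followed by a frameshift tail
  aa2 <- p_aa(ps)
  if (is.null(aa2)) {
    ps$pos <- start
    return(NULL)
  }
  kw <- p_lit(ps, "fs")
  if (!is.null(kw)) {
    kids <- list(loc$node, aa2$node, kw$node)
    new_stop <- NULL
    sv <- ps$pos
    st <- p_stop_surface(ps)
    if (!is.null(st)) {
      cnt <- p_num(ps)
      if (!is.null(cnt)) {
        new_stop <- list(surface = st$ast, count = cnt$ast)
        kids <- c(kids, list(st$node, cnt$node))
      } else {
        q <- p_lit(ps, "?")
        if (!is.null(q)) {
          new_stop <- list(surface = st$ast, count = NA_integer_)
          kids <- c(kids, list(st$node, q$node))
        } else {
          ps$pos <- sv  # a stop surface needs a (possibly unknown) count
        }
      }
    }
    return(r(list(type = "fs", loc = loc$ast, first_new = aa2$ast,
                  new_stop = new_stop),
             node(ps, "PFs", start, kids)))
  }
  r(list(type = "subst", loc = loc$ast, to = aa2$ast),
    node(ps, "PSubst", start, list(loc$node, aa2$node)))
}

protein_attempt <- function(ps, form) {
  ps_reset(ps)
  start <- 0L
  refseq <- hgvs_refseq()
  prefixed <- FALSE
  ref_kids <- list()
  if (form == "full") {
    rs <- p_refseqid(ps)
    if (is.null(rs)) return(NULL)
    cl <- p_lit(ps, ":")
    if (is.null(cl)) return(NULL)
    refseq <- rs$ast
    ref_kids <- list(rs$node, cl$node)
  }
  if (form != "bare") {
    pstart <- ps$pos
    pd <- p_lit(ps, "p.")
    if (is.null(pd)) return(NULL)
    prefixed <- TRUE
    ref_kids <- c(ref_kids, list(pd$node))
  }
  ref_node <- if (ps$tree && length(ref_kids)) {
    node(ps, "PRef", start, ref_kids)
  } else {
    NULL
  }
  predicted <- FALSE
  op <- p_lit(ps, "(")
  kids <- list(ref_node)
  if (!is.null(op)) predicted <- TRUE
  body <- p_pbody(ps)
  if (is.null(body)) return(NULL)
  if (predicted) {
    cp <- p_lit(ps, ")")
    if (is.null(cp)) return(NULL)
    kids <- c(kids, list(op$node, body$node, cp$node))
  } else {
    kids <- c(kids, list(body$node))
  }
  if (ps$pos != ps$n) {
    ps_need(ps, ps$pos)
    return(NULL)
  }
  b <- body$ast
  ast <- hgvs_protein_variant(b$type, loc = b$loc, to = b$to,
                              inserted = b$inserted,
                              first_new = b$first_new,
                              new_stop = b$new_stop, ref = refseq,
                              prefixed = prefixed, predicted = predicted)
  r(ast, node(ps, "ProteinVar", start, kids))
}

protein_parse_all_forms <- function(text, dialect, tree,
                                    forms = DESCRIPTION_FORMS) {
  ps <- ps_new(text, dialect, tree)
  for (form in forms) {
    res <- protein_attempt(ps, form)
    if (!is.null(res)) {
      return(list(ok = TRUE, matched_form = form, ast = res$ast,
                  node = res$node, far = ps$far, hit_end = ps$hit_end))
    }
  }
  list(ok = FALSE, matched_form = "none", ast = NULL, node = NULL,
       far = min(ps$far, ps$n), hit_end = ps$hit_end)
}

#' Parse a protein-level variant description
#'
#' Parses against the protein grammar (top rule `ProteinVar`). Entry forms
#' are tried most-complete-first: `full` (`LRG_1p1:p.Ser124Arg`),
#' `coordinate_prefixed` (`p.Ser124Arg`), then `bare` (`Gly123del`).
#' Both the preferred three-letter and the one-letter amino-acid codes are
#' recognized, as are the stop surfaces `Ter`, `*` and legacy `X`; a body
#' in parentheses is recorded as a predicted consequence.
#'
#' @inheritParams hgvs_parse_genotype
#' @return An object of class `hgvs_parsed` whose `ast` is an
#'   [hgvs_protein_variant()].
#' @examples
#' p <- hgvs_parse_protein("p.Ser124Arg")
#' p$ast$type
#' hgvs_parse_protein("Gly123del")$matched_form
#' @export
hgvs_parse_protein <- function(text, dialect = "strict", tree = TRUE) {
  dialect <- match_arg2(dialect, DIALECTS, "dialect")
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  res <- protein_parse_all_forms(text, dialect, tree)
  if (!res$ok) hgvs_syntax_error(text, res$far)
  structure(list(ast = res$ast, tree = res$node,
                 matched_form = res$matched_form, input = text,
                 level = "protein", dialect = dialect),
            class = "hgvs_parsed")
}

#' Parse a single amino-acid token
#'
#' Resolves a three-letter (`Ser`, `Ter`) or one-letter (`S`, `*`, `X`)
#' amino-acid code, recording which style the surface used.
#'
#' @param token The code to resolve.
#' @return An [hgvs_aa()].
#' @examples
#' hgvs_parse_amino_acid("Ser")$code1
#' hgvs_parse_amino_acid("G")$code3
#' @export
hgvs_parse_amino_acid <- function(token) {
  stopifnot(is.character(token), length(token) == 1L, !is.na(token))
  ps <- ps_new(token, "strict", tree = FALSE)
  res <- p_aa(ps)
  if (is.null(res) || ps$pos != ps$n) {
    hgvs_syntax_error(token, 0L,
                      sprintf("unknown amino-acid code \"%s\"", token))
  }
  res$ast
}

#' Report ranges written in mixed amino-acid code styles
#'
#' A range such as `G123_Cys125` whose endpoints mix the one-letter and
#' three-letter codes is syntactically valid (the grammar is a superset of
#' the nomenclature) but flagged here as a candidate constraint violation.
#' One warning is returned per offending range; substitutions and other
#' rangeless bodies never warn.
#'
#' @param x A parsed protein variant: an [hgvs_protein_variant()] or the
#'   `hgvs_parsed` object returned by [hgvs_parse_protein()].
#' @return A character vector of warnings (empty when all ranges are
#'   homogeneous).
#' @examples
#' v <- hgvs_parse_protein("G123_Cys125del")
#' hgvs_lint_mixed_code(v)
#' @export
hgvs_lint_mixed_code <- function(x) {
  if (inherits(x, "hgvs_parsed")) x <- x$ast
  if (!inherits(x, "hgvs_protein_variant")) {
    stop("`x` must be a parsed protein variant", call. = FALSE)
  }
  warnings <- character()
  if (inherits(x$loc, "hgvs_aa_range")) {
    s <- x$loc$start$aa$style
    e <- x$loc$end$aa$style
    if (s != e) {
      warnings <- c(warnings, sprintf(
        "range %s mixes one-letter and three-letter amino-acid codes",
        hgvs_serialize(x$loc, preserve_surface = TRUE)))
    }
  }
  warnings
}
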
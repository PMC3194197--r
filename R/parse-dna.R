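# The DNA/RNA-level grammar (top rule "Var") as a recursive-descent parser.
# One function per production; the function layout mirrors the grammar, so
# the source doubles as a readable statement of the language.

p_offset <- function(ps) {
  start <- ps$pos
  sgn <- ps_need(ps, ps$pos)
  if (is.na(sgn) || (sgn != "+" && sgn != "-")) return(NULL)
  ps$pos <- ps$pos + 1L
  sgn_node <- leafnode(ps, "Sym", start)
  beyond <- "none"
  bnode <- NULL
  ch <- ps_need(ps, ps$pos)
  if (!is.na(ch) && (ch == "u" || ch == "d")) {
    bstart <- ps$pos
    ps$pos <- ps$pos + 1L
    beyond <- ch
    bnode <- leafnode(ps, "Sym", bstart)
  }
  mag <- p_num(ps)
  if (!is.null(mag)) {
    magv <- mag$ast
    mnode <- mag$node
  } else {
    q <- p_lit(ps, "?")
    if (is.null(q)) {
      ps$pos <- start
      return(NULL)
    }
    magv <- NA_integer_
    mnode <- q$node
  }
  r(b_offset(sgn, beyond, magv),
    node(ps, "Offset", start, list(sgn_node, bnode, mnode)))
}

p_ivsloc <- function(ps) {
  start <- ps$pos
  kw <- p_lit(ps, "IVS")
  if (is.null(kw)) return(NULL)
  n1 <- p_num(ps)
  if (is.null(n1)) {
    ps$pos <- start
    return(NULL)
  }
  sgn <- ps_need(ps, ps$pos)
  if (is.na(sgn) || (sgn != "+" && sgn != "-")) {
    ps$pos <- start
    return(NULL)
  }
  sstart <- ps$pos
  ps$pos <- ps$pos + 1L
  snode <- leafnode(ps, "Sym", sstart)
  n2 <- p_num(ps)
  if (is.null(n2)) {
    ps$pos <- start
    return(NULL)
  }
  r(b_ptloc_ivs(n1$ast, sgn, n2$ast),
    node(ps, "IVSLoc", start, list(kw$node, n1$node, snode, n2$node)))
}

p_ptloc <- function(ps) {
  start <- ps$pos
  if (ps$dialect != "strict") {
    ivs <- p_ivsloc(ps)
    if (!is.null(ivs)) return(ivs)
    ps$pos <- start
  }
  region <- "body"
  rnode <- NULL
  ch <- ps_need(ps, ps$pos)
  if (!is.na(ch) && ch == "-") {
    ps$pos <- ps$pos + 1L
    region <- "five_utr"
    rnode <- leafnode(ps, "Sym", start)
  } else if (!is.na(ch) && ch == "*") {
    ps$pos <- ps$pos + 1L
    region <- "three_utr"
    rnode <- leafnode(ps, "Sym", start)
  }
  base <- p_num(ps)
  if (!is.null(base)) {
    off <- p_offset(ps)  # optional; restores itself on failure
    return(r(
      b_ptloc(base$ast, region, if (is.null(off)) NULL else off$ast),
      node(ps, "PtLoc", start,
           list(rnode, base$node, if (is.null(off)) NULL else off$node))))
  }
  q <- p_lit(ps, "?")
  if (is.null(q)) {
    ps$pos <- start
    return(NULL)
  }
  # unknown base: the grammar attaches no offset to `?`
  r(b_ptloc(NA_integer_, region, NULL), node(ps, "PtLoc", start,
                                             list(rnode, q$node)))
}

p_exloc <- function(ps) {
  start <- ps$pos
  kw <- p_lit(ps, "EX")
  if (is.null(kw)) return(NULL)
  n1 <- p_num(ps)
  if (is.null(n1)) {
    ps$pos <- start
    return(NULL)
  }
  last <- NA_integer_
  kids <- list(kw$node, n1$node)
  sv <- ps$pos
  dash <- p_lit(ps, "-")
  if (!is.null(dash)) {
    n2 <- p_num(ps)
    if (!is.null(n2)) {
      last <- n2$ast
      kids <- c(kids, list(dash$node, n2$node))
    } else {
      ps$pos <- sv
    }
  }
  r(b_loc_exon(n1$ast, last), node(ps, "EXLoc", start, kids))
}

p_rangeloc <- function(ps) {
  start <- ps$pos
  p1 <- p_ptloc(ps)
  if (is.null(p1)) return(NULL)
  us <- p_lit(ps, "_")
  if (is.null(us)) {
    ps$pos <- start
    return(NULL)
  }
  p2 <- p_ptloc(ps)
  if (is.null(p2)) {
    ps$pos <- start
    return(NULL)
  }
  r(b_loc_range(p1$ast, p2$ast),
    node(ps, "RangeLoc", start, list(p1$node, us$node, p2$node)))
}

p_loc <- function(ps) {
  start <- ps$pos
  if (ps$dialect != "strict") {
    ex <- p_exloc(ps)
    if (!is.null(ex)) return(ex)
    ps$pos <- start
  }
  p1 <- p_ptloc(ps)
  if (is.null(p1)) return(NULL)
  sv <- ps$pos
  us <- p_lit(ps, "_")
  if (!is.null(us)) {
    p2 <- p_ptloc(ps)
    if (!is.null(p2)) {
      return(r(b_loc_range(p1$ast, p2$ast),
               node(ps, "RangeLoc", start, list(p1$node, us$node, p2$node))))
    }
    ps$pos <- sv
  }
  r(b_loc_point(p1$ast), p1$node)
}

LETTER_CHARS <- c(LETTERS, letters)
ALNUMU_CHARS <- c(LETTERS, letters, DIGITS, "_")

p_lrgref <- function(ps) {
  start <- ps$pos
  kw <- p_lit(ps, "LRG_")
  if (is.null(kw)) return(NULL)
  n <- p_num(ps)
  if (is.null(n)) {
    ps$pos <- start
    return(NULL)
  }
  lt <- NA_integer_
  lp <- NA_integer_
  sv <- ps$pos
  ch <- ps_need(ps, ps$pos)
  if (!is.na(ch) && (ch == "t" || ch == "p")) {
    ps$pos <- ps$pos + 1L
    n2 <- p_num(ps)
    if (!is.null(n2)) {
      if (ch == "t") lt <- n2$ast else lp <- n2$ast
    } else {
      ps$pos <- sv
    }
  }
  r(b_refseq("lrg", lrg_id = n$ast, lrg_transcript = lt,
             lrg_protein = lp),
    leafnode(ps, "RefSeqId", start))
}

gene_from_token <- function(token) {
  m <- regmatches(token,
                  regexec("^([A-Za-z][A-Za-z0-9_]*?)_(v|i)([0-9]+)$", token))[[1]]
  if (length(m)) {
    num <- strtoi(m[[4]])
    if (m[[3]] == "v") {
      b_refseq("gene", gene_symbol = m[[2]], transcript_variant = num)
    } else {
      b_refseq("gene", gene_symbol = m[[2]], protein_isoform = num)
    }
  } else {
    b_refseq("gene", gene_symbol = token)
  }
}

scan_name_token <- function(ps) {
  ch <- ps_need(ps, ps$pos)
  if (is.na(ch) || !ch %in% LETTER_CHARS) return(NULL)
  p <- ps$pos
  i <- p + 1L
  repeat {
    c2 <- ps_need(ps, i)
    if (!is.na(c2) && c2 %in% ALNUMU_CHARS) i <- i + 1L else break
  }
  ps$pos <- i
  substr(ps$s, p + 1L, i)
}

# RefSeqId disambiguation: LRG first; a token ending in _v<num>/_i<num> is a
# gene symbol with suffix; any other digit-containing token is a GenBank
# accession (optionally versioned, optionally annotated with a gene in
# parentheses); a digit-free token is a plain gene symbol.
p_refseqid <- function(ps) {
  start <- ps$pos
  lrg <- p_lrgref(ps)
  if (!is.null(lrg)) return(lrg)
  ps$pos <- start
  token <- scan_name_token(ps)
  if (is.null(token)) return(NULL)
  if (grepl("_[vi][0-9]+$", token)) {
    return(r(gene_from_token(token), leafnode(ps, "RefSeqId", start)))
  }
  if (!grepl("[0-9]", token)) {
    return(r(b_refseq("gene", gene_symbol = token),
             leafnode(ps, "RefSeqId", start)))
  }
  # accession: optional ".<version>", optional "(<gene>)"
  version <- NA_integer_
  sv <- ps$pos
  dot <- p_lit(ps, ".")
  if (!is.null(dot)) {
    n <- p_num(ps)
    if (!is.null(n)) version <- n$ast else ps$pos <- sv
  }
  gene <- NULL
  sv <- ps$pos
  op <- p_lit(ps, "(")
  if (!is.null(op)) {
    gtoken <- scan_name_token(ps)
    cp <- if (is.null(gtoken)) NULL else p_lit(ps, ")")
    if (!is.null(cp)) gene <- gene_from_token(gtoken) else ps$pos <- sv
  }
  ref <- b_refseq("genbank", accession = token, version = version,
                  gene_symbol = if (is.null(gene)) NA_character_
                                else gene$gene_symbol,
                  transcript_variant = if (is.null(gene)) NA_integer_
                                       else gene$transcript_variant,
                  protein_isoform = if (is.null(gene)) NA_integer_
                                    else gene$protein_isoform)
  r(ref, leafnode(ps, "RefSeqId", start))
}

p_farloc <- function(ps) {
  start <- ps$pos
  rs <- p_refseqid(ps)
  if (is.null(rs)) return(NULL)
  sv <- ps$pos
  colon <- p_lit(ps, ":")
  if (!is.null(colon)) {
    sv2 <- ps$pos
    system <- NA_character_
    tnode <- NULL
    ch <- ps_need(ps, ps$pos)
    if (!is.na(ch) && ch %in% COORD_SYSTEMS) {
      tstart <- ps$pos
      ps$pos <- ps$pos + 1L
      dot <- p_lit(ps, ".")
      if (!is.null(dot)) {
        system <- ch
        tnode <- node(ps, "Ref", tstart, list(leafnode(ps, "RefType", tstart),
                                              dot$node))
        # leaf spans: rebuild RefType leaf over the letter only
        if (ps$tree) {
          tnode$children[[1]]$span <- c(tstart, tstart + 1L)
          tnode$children[[1]]$text <- substr(ps$s, tstart + 1L, tstart + 1L)
        }
      } else {
        ps$pos <- sv2
      }
    }
    loc <- p_loc(ps)
    if (!is.null(loc)) {
      return(r(b_farloc(rs$ast, system, loc$ast),
               node(ps, "FarLoc", start,
                    list(rs$node, colon$node, tnode, loc$node))))
    }
    ps$pos <- sv  # the optional ":<loc>" tail did not match at all
  }
  r(b_farloc(rs$ast, NA_character_, NULL),
    node(ps, "FarLoc", start, list(rs$node)))
}

p_substop <- function(ps) {
  x <- p_lit(ps, ">", "SubstOp")
  if (!is.null(x)) return(r("gt", x$node))
  if (ps$dialect == "lenient" && ps$brackets == 0L) {
    x <- p_lit(ps, "-->", "SubstOp")
    if (!is.null(x)) return(r("long_arrow", x$node))
    x <- p_lit(ps, "->", "SubstOp")
    if (!is.null(x)) return(r("arrow", x$node))
    x <- p_lit(ps, "/", "SubstOp")
    if (!is.null(x)) return(r("slash", x$node))
  }
  NULL
}

p_subst <- function(ps) {
  start <- ps$pos
  loc <- p_ptloc(ps)
  if (is.null(loc)) return(NULL)
  from <- p_nt(ps)
  if (is.null(from)) return(NULL)
  op <- p_substop(ps)
  if (is.null(op)) return(NULL)
  to <- p_nt(ps)
  if (is.null(to)) return(NULL)
  r(new_raw_variant("subst", list(loc = loc$ast, from = from$ast,
                                  to = to$ast, operator = op$ast)),
    node(ps, "Subst", start, list(loc$node, from$node, op$node, to$node)))
}

p_removed <- function(ps) {
  x <- p_ntstring(ps)
  if (!is.null(x)) return(x)
  p_num(ps)
}

p_instarget <- function(ps) {
  start <- ps$pos
  x <- p_ntstring(ps)
  if (!is.null(x) && at_boundary(ps)) {
    return(r(b_insertion("seq", x$ast), x$node))
  }
  ps$pos <- start
  # the range alternative before the bare length: "+" is a boundary
  # character (legacy separator), so a plain number would otherwise
  # shadow a range whose first point carries a +offset
  x <- p_rangeloc(ps)
  if (!is.null(x) && at_boundary(ps)) {
    return(r(b_insertion("range", x$ast), x$node))
  }
  ps$pos <- start
  x <- p_num(ps)
  if (!is.null(x) && at_boundary(ps)) {
    return(r(b_insertion("length", x$ast), x$node))
  }
  ps$pos <- start
  x <- p_farloc(ps)
  if (!is.null(x) && at_boundary(ps)) {
    return(r(b_insertion("farloc", x$ast), x$node))
  }
  ps$pos <- start
  NULL
}

p_nest <- function(ps) {
  start <- ps$pos
  ob <- p_lit(ps, "{")
  if (is.null(ob)) return(NULL)
  if (ps$nest_depth >= MAX_NEST_DEPTH) {
    ps$pos <- start
    return(NULL)
  }
  ps$nest_depth <- ps$nest_depth + 1L
  ps$brackets <- ps$brackets + 1L
  vl <- p_varlist(ps)
  cb <- if (is.null(vl)) NULL else p_lit(ps, "}")
  ps$nest_depth <- ps$nest_depth - 1L
  ps$brackets <- ps$brackets - 1L
  if (is.null(cb)) {
    ps$pos <- start
    return(NULL)
  }
  r(vl$ast, node(ps, "Nest", start, list(ob$node, vl$node, cb$node)))
}

p_opt_nest <- function(ps) {
  sv <- ps$pos
  nest <- p_nest(ps)
  if (is.null(nest)) {
    ps$pos <- sv
    NULL
  } else {
    nest
  }
}

p_rawvar <- function(ps) {
  start <- ps$pos
  s <- p_subst(ps)
  if (!is.null(s)) return(s)
  ps$pos <- start
  loc <- p_loc(ps)
  if (is.null(loc)) {
    ps$pos <- start
    return(NULL)
  }
  is_range <- loc$ast$type == "range"
  kw <- p_lit(ps, "del")
  if (!is.null(kw)) {
    rem <- p_removed(ps)
    ki <- p_lit(ps, "ins")
    if (!is.null(ki)) {
      tgt <- p_instarget(ps)
      if (is.null(tgt)) {
        ps$pos <- start
        return(NULL)
      }
      return(r(
        new_raw_variant("delins",
                        list(loc = loc$ast,
                             removed = if (is.null(rem)) NULL else rem$ast,
                             inserted = tgt$ast)),
        node(ps, "Indel", start,
             list(loc$node, kw$node, if (is.null(rem)) NULL else rem$node,
                  ki$node, tgt$node))))
    }
    return(r(new_raw_variant("del", list(
      loc = loc$ast, removed = if (is.null(rem)) NULL else rem$ast)),
             node(ps, "Del", start,
                  list(loc$node, kw$node,
                       if (is.null(rem)) NULL else rem$node))))
  }
  kw <- p_lit(ps, "dup")
  if (!is.null(kw)) {
    seq <- p_removed(ps)
    nest <- p_opt_nest(ps)
    return(r(
      new_raw_variant("dup", list(
        loc = loc$ast, seq = if (is.null(seq)) NULL else seq$ast,
        nest = if (is.null(nest)) NULL else nest$ast)),
      node(ps, "Dup", start,
           list(loc$node, kw$node, if (is.null(seq)) NULL else seq$node,
                if (is.null(nest)) NULL else nest$node))))
  }
  if (is_range) {
    kw <- p_lit(ps, "ins")
    if (!is.null(kw)) {
      tgt <- p_instarget(ps)
      if (is.null(tgt)) {
        ps$pos <- start
        return(NULL)
      }
      nest <- p_opt_nest(ps)
      return(r(
        new_raw_variant("ins", list(
          loc = loc$ast, inserted = tgt$ast,
          nest = if (is.null(nest)) NULL else nest$ast)),
        node(ps, "Ins", start,
             list(loc$node, kw$node, tgt$node,
                  if (is.null(nest)) NULL else nest$node))))
    }
    kw <- p_lit(ps, "inv")
    if (!is.null(kw)) {
      seq <- p_removed(ps)
      nest <- p_opt_nest(ps)
      return(r(
        new_raw_variant("inv", list(
          loc = loc$ast, seq = if (is.null(seq)) NULL else seq$ast,
          nest = if (is.null(nest)) NULL else nest$ast)),
        node(ps, "Inv", start,
             list(loc$node, kw$node, if (is.null(seq)) NULL else seq$node,
                  if (is.null(nest)) NULL else nest$node))))
    }
    kw <- p_lit(ps, "con")
    if (!is.null(kw)) {
      origin <- p_farloc(ps)
      if (is.null(origin)) {
        ps$pos <- start
        return(NULL)
      }
      nest <- p_opt_nest(ps)
      return(r(
        new_raw_variant("conv", list(
          loc = loc$ast, origin = origin$ast,
          nest = if (is.null(nest)) NULL else nest$ast)),
        node(ps, "Conv", start,
             list(loc$node, kw$node, origin$node,
                  if (is.null(nest)) NULL else nest$node))))
    }
  }
  ps$pos <- start
  NULL
}

p_extrawvar <- function(ps) {
  start <- ps$pos
  v <- p_rawvar(ps)
  if (!is.null(v)) return(v)
  ps$pos <- start
  x <- p_lit(ps, "=", "NoChange")
  if (!is.null(x)) return(r(hgvs_no_change(), x$node))
  x <- p_lit(ps, "?", "Unknown")
  if (!is.null(x)) return(r(hgvs_unknown(), x$node))
  NULL
}

p_listsep <- function(ps) {
  x <- p_lit(ps, "//")
  if (!is.null(x)) return(x)
  x <- p_lit(ps, "/")
  if (!is.null(x)) return(x)
  x <- p_lit(ps, ";")
  if (!is.null(x)) return(x)
  x <- p_lit(ps, "^")
  if (!is.null(x)) return(x)
  if (ps$dialect != "strict") {
    x <- p_lit(ps, "+")
    if (!is.null(x)) return(x)
  }
  NULL
}

p_varlist <- function(ps) {
  start <- ps$pos
  first <- p_extrawvar(ps)
  if (is.null(first)) return(NULL)
  items <- list(first$ast)
  seps <- character()
  kids <- list(first$node)
  repeat {
    sv <- ps$pos
    sep <- p_listsep(ps)
    if (is.null(sep)) break
    it <- p_extrawvar(ps)
    if (is.null(it)) {
      ps$pos <- sv
      break
    }
    items <- c(items, list(it$ast))
    seps <- c(seps, sep$ast)
    kids <- c(kids, list(sep$node, it$node))
  }
  r(b_vlist(items, seps), node(ps, "VarList", start, kids))
}

# "[" VarList "]" with bracket bookkeeping; NULL-safe restore.
p_bracketed_list <- function(ps) {
  start <- ps$pos
  ob <- p_lit(ps, "[")
  if (is.null(ob)) return(NULL)
  ps$brackets <- ps$brackets + 1L
  vl <- p_varlist(ps)
  cb <- if (is.null(vl)) NULL else p_lit(ps, "]")
  ps$brackets <- ps$brackets - 1L
  if (is.null(cb)) {
    ps$pos <- start
    return(NULL)
  }
  r(vl$ast, list(open = ob$node, list = vl$node, close = cb$node))
}

# The phase separator between bracketed allele sets.
p_setsep <- function(ps) {
  x <- p_lit(ps, "(;)")
  if (!is.null(x)) return(r("uncertain", x$node))
  x <- p_lit(ps, ";")
  if (!is.null(x)) return(r("certain", x$node))
  if (ps$dialect != "strict") {
    x <- p_lit(ps, "(+)")
    if (!is.null(x)) return(r("uncertain", x$node))
    x <- p_lit(ps, "+")
    if (!is.null(x)) return(r("certain", x$node))
  }
  NULL
}

# Everything after Ref when the body starts with "[".
p_bracketed_body <- function(ps, start, ref_kids) {
  ob <- p_lit(ps, "[")
  if (is.null(ob)) return(NULL)
  ps$brackets <- ps$brackets + 1L
  vl1 <- p_varlist(ps)
  if (is.null(vl1)) {
    ps$brackets <- ps$brackets - 1L
    return(NULL)
  }
  # MultiTranscriptVar: commas inside one bracket pair
  if (!is.na(ps_need(ps, ps$pos)) && ps$chars[[ps$pos + 1L]] == ",") {
    lists <- list(vl1$ast)
    kids <- c(ref_kids, list(ob$node, vl1$node))
    repeat {
      cm <- p_lit(ps, ",")
      if (is.null(cm)) break
      vl <- p_varlist(ps)
      if (is.null(vl)) {
        ps$brackets <- ps$brackets - 1L
        return(NULL)
      }
      lists <- c(lists, list(vl$ast))
      kids <- c(kids, list(cm$node, vl$node))
    }
    cb <- p_lit(ps, "]")
    ps$brackets <- ps$brackets - 1L
    if (is.null(cb) || length(lists) < 2L) return(NULL)
    return(r(hgvs_multi_transcript(lists),
             node(ps, "MultiTranscriptVar", start, c(kids, list(cb$node)))))
  }
  cb <- p_lit(ps, "]")
  ps$brackets <- ps$brackets - 1L
  if (is.null(cb)) return(NULL)
  sets <- list(vl1$ast)
  kids <- c(ref_kids, list(ob$node, vl1$node, cb$node))
  phase <- NULL
  repeat {
    sv <- ps$pos
    sep <- p_setsep(ps)
    if (is.null(sep)) break
    if (!is.null(phase) && (phase != sep$ast || phase == "uncertain")) {
      ps$pos <- sv  # mixed phases / third uncertain set: not in the grammar
      break
    }
    bl <- p_bracketed_list(ps)
    if (is.null(bl)) {
      ps$pos <- sv
      break
    }
    phase <- sep$ast
    sets <- c(sets, list(bl$ast))
    kids <- c(kids, list(sep$node, bl$node$open, bl$node$list, bl$node$close))
  }
  if (length(sets) == 1L) {
    return(r(hgvs_variant_list_body(vl1$ast),
             node(ps, "SingleAlleleVars", start, kids)))
  }
  rule <- if (phase == "certain") "MultiAlleleVars" else "UnkAlleleVars"
  r(hgvs_multi_allele(sets, phase), node(ps, rule, start, kids))
}

# marker so the genotype assembler can tell "one bracketed set" apart
hgvs_variant_list_body <- function(vl) vl

# One entry-point attempt; `form` is the description form being tried.
dna_attempt <- function(ps, form, single_only = FALSE) {
  ps_reset(ps)
  start <- 0L
  refseq <- hgvs_refseq()
  system <- NA_character_
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
    ch <- ps_need(ps, ps$pos)
    if (is.na(ch) || !ch %in% COORD_SYSTEMS) return(NULL)
    tstart <- ps$pos
    ps$pos <- ps$pos + 1L
    tnode <- leafnode(ps, "RefType", tstart)
    dot <- p_lit(ps, ".")
    if (is.null(dot)) return(NULL)
    system <- ch
    ref_kids <- c(ref_kids, list(tnode, dot$node))
  }
  ref_node <- if (ps$tree && length(ref_kids)) {
    node(ps, "Ref", start, ref_kids)
  } else {
    NULL
  }
  nxt <- if (form == "bare") NA_character_ else ps_need(ps, ps$pos)
  if (!is.na(nxt) && nxt == "[") {
    if (single_only) return(NULL)
    body <- p_bracketed_body(ps, start, list(ref_node))
    if (is.null(body)) return(NULL)
    if (ps$pos != ps$n) {
      ps_need(ps, ps$pos)  # register the first unconsumable character
      return(NULL)
    }
    ast <- hgvs_genotype(body$ast, refseq, system)
    return(r(ast, node(ps, "Var", start, list(body$node))))
  }
  rv <- p_rawvar(ps)
  if (is.null(rv)) return(NULL)
  if (ps$pos != ps$n) {
    ps_need(ps, ps$pos)
    return(NULL)
  }
  ast <- hgvs_genotype(rv$ast, refseq, system)
  r(ast, node(ps, "Var", start,
              list(node(ps, "SingleVar", start, list(ref_node, rv$node)))))
}

DESCRIPTION_FORMS <- c("full", "coordinate_prefixed", "bare")

dna_parse_all_forms <- function(text, dialect, tree, single_only = FALSE,
                                forms = DESCRIPTION_FORMS) {
  ps <- ps_new(text, dialect, tree)
  for (form in forms) {
    res <- dna_attempt(ps, form, single_only)
    if (!is.null(res)) {
      return(list(ok = TRUE, matched_form = form, ast = res$ast,
                  node = res$node, far = ps$far, hit_end = ps$hit_end))
    }
  }
  list(ok = FALSE, matched_form = "none", ast = NULL, node = NULL,
       far = min(ps$far, ps$n), hit_end = ps$hit_end)
}

#' Parse a complete DNA/RNA-level variant description
#'
#' Parses a genotype-level description against the DNA/RNA grammar (top
#' rule `Var`): a single variant, one bracketed allele set, several allele
#' sets with certain (`;`) or uncertain (`(;)`) phase, or a
#' multi-transcript list. Entry forms are tried most-complete-first:
#' `full` (`NM_003002.2:c.274G>T`), `coordinate_prefixed` (`c.274G>T`),
#' then `bare` (`274G>T`). The whole input must be consumed.
#'
#' @param text A single description string (no whitespace).
#' @param dialect `"strict"` (the standard grammar), `"legacy"` (adds the
#'   IVS/EX deviation rules and `+` separators), or `"lenient"` (further
#'   adds the text-mining substitution operators `/`, `->`, `-->`).
#' @param tree Also build the full parse tree (slower; needed for
#'   [hgvs_to_structured()]).
#' @return An object of class `hgvs_parsed`: a list with elements `ast`
#'   (an [hgvs_genotype()]), `tree` (the root parse node, or `NULL` when
#'   `tree = FALSE`), `matched_form`, `input`, `level` and `dialect`.
#' @examples
#' p <- hgvs_parse_genotype("NM_003002.2:c.274G>T")
#' p$ast$body$type
#' hgvs_serialize(p$ast)
#' @seealso [hgvs_check()] for a non-throwing acceptor,
#'   [hgvs_parse_protein()] for the protein level.
#' @export
hgvs_parse_genotype <- function(text, dialect = "strict", tree = TRUE) {
  dialect <- match_arg2(dialect, DIALECTS, "dialect")
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  res <- dna_parse_all_forms(text, dialect, tree)
  if (!res$ok) hgvs_syntax_error(text, res$far)
  structure(list(ast = res$ast, tree = res$node,
                 matched_form = res$matched_form, input = text,
                 level = "dna_rna", dialect = dialect),
            class = "hgvs_parsed")
}

#' Parse an unbracketed single variant
#'
#' As [hgvs_parse_genotype()] but restricted to the simplest description
#' form (`SingleVar`): one raw variant with an optional reference part,
#' no bracketed allele sets.
#'
#' @inheritParams hgvs_parse_genotype
#' @return An `hgvs_parsed` object whose AST has form `"single"`.
#' @examples
#' hgvs_parse_single_variant("c.274G>T")$ast$system
#' @export
hgvs_parse_single_variant <- function(text, dialect = "strict", tree = TRUE) {
  dialect <- match_arg2(dialect, DIALECTS, "dialect")
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  res <- dna_parse_all_forms(text, dialect, tree, single_only = TRUE)
  if (!res$ok) hgvs_syntax_error(text, res$far)
  structure(list(ast = res$ast, tree = res$node,
                 matched_form = res$matched_form, input = text,
                 level = "dna_rna", dialect = dialect),
            class = "hgvs_parsed")
}

#' Parse one point location
#'
#' Parses a single DNA/RNA point location, e.g. `*405+d256` (3' UTR
#' position with a downstream-of-transcript offset) or `-110-u256`, fully
#' consuming the input.
#'
#' @param text The location text.
#' @param dialect Parsing dialect; `"legacy"` additionally admits IVS
#'   intron positions such as `IVS4+1`.
#' @return An [hgvs_ptloc()].
#' @examples
#' hgvs_parse_point_location("*405+d256")
#' @export
hgvs_parse_point_location <- function(text, dialect = "strict") {
  dialect <- match_arg2(dialect, DIALECTS, "dialect")
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  ps <- ps_new(text, dialect, tree = FALSE)
  res <- p_ptloc(ps)
  if (is.null(res) || ps$pos != ps$n) {
    if (!is.null(res)) ps_need(ps, ps$pos)
    hgvs_syntax_error(text, min(ps$far, ps$n))
  }
  res$ast
}

#' Parse a reference-sequence identifier
#'
#' Parses the reference part of a description (the text before `:`): a
#' GenBank accession with optional version, a gene symbol with optional
#' `_v`/`_i` suffix, or an LRG identifier with optional `t`/`p` suffix.
#'
#' @param text The reference token.
#' @return An [hgvs_refseq()].
#' @examples
#' hgvs_parse_reference("LRG_1t1")$lrg_transcript
#' hgvs_parse_reference("DMD_v2")$transcript_variant
#' @export
hgvs_parse_reference <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  ps <- ps_new(text, "strict", tree = FALSE)
  res <- p_refseqid(ps)
  if (is.null(res) || ps$pos != ps$n) {
    if (!is.null(res)) ps_need(ps, ps$pos)
    hgvs_syntax_error(text, min(ps$far, ps$n))
  }
  res$ast
}

#' @export
print.hgvs_parsed <- function(x, ...) {
  cat(sprintf("<hgvs_parsed> %s [%s, %s, form=%s]\n", x$input, x$level,
              x$dialect, x$matched_form))
  invisible(x)
}
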
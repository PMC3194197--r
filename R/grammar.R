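# Grammar-as-data: the production sets behind the parsers, exportable for
# inspection, JSON serialization, CNF conversion and the CYK oracle.
#
# Symbols:
#   g_nt("Name")    reference to a nonterminal
#   g_lit("del")    literal terminal string
#   g_cls("Nt")     reference to a named terminal character class
#   g_opt(...), g_star(...), g_plus(...)   EBNF ?, *, + over a symbol group

#' Grammar symbol constructors
#'
#' Building blocks for `hgvs_grammar` production bodies: a nonterminal
#' reference, a literal terminal string, a reference to a named terminal
#' character class, and the EBNF option/repetition operators over a group
#' of symbols.
#'
#' @param name Nonterminal or terminal-class name.
#' @param s Literal string.
#' @param ... Symbols forming the group an operator applies to.
#' @return A grammar symbol (plain list with a `kind` field).
#' @name grammar_symbols
NULL

#' @rdname grammar_symbols
#' @export
g_nt <- function(name) list(kind = "nt", value = name)

#' @rdname grammar_symbols
#' @export
g_lit <- function(s) list(kind = "lit", value = s)

#' @rdname grammar_symbols
#' @export
g_cls <- function(name) list(kind = "class", value = name)

#' @rdname grammar_symbols
#' @export
g_opt <- function(...) list(kind = "opt", body = list(...))

#' @rdname grammar_symbols
#' @export
g_star <- function(...) list(kind = "star", body = list(...))

#' @rdname grammar_symbols
#' @export
g_plus <- function(...) list(kind = "plus", body = list(...))

new_grammar <- function(start, productions, terminals, level, dialect) {
  structure(list(start = start, productions = productions,
                 terminals = terminals, level = level, dialect = dialect),
            class = "hgvs_grammar")
}

refseq_productions <- function() {
  list(
    RefSeqId = list(list(g_nt("LRGRef")), list(g_nt("AccRef")),
                    list(g_nt("GeneRef"))),
    LRGRef = list(list(g_lit("LRG_"), g_nt("Num"), g_opt(g_nt("LRGSuffix")))),
    LRGSuffix = list(list(g_lit("t"), g_nt("Num")),
                     list(g_lit("p"), g_nt("Num"))),
    AccRef = list(list(g_nt("AccNo"), g_opt(g_lit("."), g_nt("Num")),
                       g_opt(g_lit("("), g_nt("GeneRef"), g_lit(")")))),
    AccNo = list(list(g_cls("Letter"), g_star(g_cls("AlnumU")),
                      g_cls("Digit"), g_star(g_cls("AlnumU")))),
    GeneRef = list(list(g_nt("GeneSym"), g_opt(g_nt("GeneSuffix")))),
    GeneSuffix = list(list(g_lit("_v"), g_nt("Num")),
                      list(g_lit("_i"), g_nt("Num"))),
    GeneSym = list(list(g_cls("Letter"), g_star(g_cls("AlnumU")))),
    Num = list(list(g_plus(g_cls("Digit"))))
  )
}

base_terminals <- function() {
  list(Digit = DIGITS,
       Letter = LETTER_CHARS,
       AlnumU = ALNUMU_CHARS,
       Nt = IUPAC_NT,
       RefType = COORD_SYSTEMS,
       Sign = c("+", "-"),
       UD = c("u", "d"),
       UTR = c("-", "*"))
}

grammar_dna <- function(dialect) {
  legacy <- dialect != "strict"
  lenient <- dialect == "lenient"
  p <- refseq_productions()
  p$Var <- list(list(g_nt("SingleVar")), list(g_nt("SingleAlleleVars")),
                list(g_nt("MultiAlleleVars")), list(g_nt("UnkAlleleVars")),
                list(g_nt("MultiTranscriptVar")))
  p$SingleVar <- list(list(g_nt("Ref"), g_nt("RawVar")))
  p$SingleAlleleVars <- list(list(g_nt("Ref"), g_nt("BrVarList")))
  p$MultiAlleleVars <- list(list(g_nt("Ref"), g_nt("BrVarList"),
                                 g_plus(g_nt("MASep"), g_nt("BrVarList"))))
  p$UnkAlleleVars <- list(list(g_nt("Ref"), g_nt("BrVarList"), g_nt("USep"),
                               g_nt("BrVarList")))
  p$MultiTranscriptVar <- list(list(g_nt("Ref"), g_lit("["), g_nt("VarList"),
                                    g_plus(g_lit(","), g_nt("VarList")),
                                    g_lit("]")))
  p$BrVarList <- list(list(g_lit("["), g_nt("VarList"), g_lit("]")))
  p$MASep <- c(list(list(g_lit(";"))),
               if (legacy) list(list(g_lit("+"))))
  p$USep <- c(list(list(g_lit("(;)"))),
              if (legacy) list(list(g_lit("(+)"))))
  p$VarList <- list(list(g_nt("ExtRawVar"),
                         g_star(g_nt("ListSep"), g_nt("ExtRawVar"))))
  p$ListSep <- c(list(list(g_lit(";")), list(g_lit("/")), list(g_lit("//")),
                      list(g_lit("^"))),
                 if (legacy) list(list(g_lit("+"))))
  p$ExtRawVar <- list(list(g_nt("RawVar")), list(g_lit("=")), list(g_lit("?")))
  p$Ref <- list(list(g_opt(g_nt("RefSeqId"), g_lit(":")), g_cls("RefType"),
                     g_lit(".")))
  p$RawVar <- list(list(g_nt("Subst")), list(g_nt("Del")), list(g_nt("Dup")),
                   list(g_nt("Ins")), list(g_nt("Indel")), list(g_nt("Inv")),
                   list(g_nt("Conv")))
  p$Subst <- list(list(g_nt("PtLoc"), g_cls("Nt"), g_nt("SubstOp"),
                       g_cls("Nt")))
  p$SubstOp <- c(list(list(g_lit(">"))),
                 if (lenient) list(list(g_lit("/")), list(g_lit("->")),
                                   list(g_lit("-->"))))
  p$Del <- list(list(g_nt("Loc"), g_lit("del"), g_opt(g_nt("RemovedSeq"))))
  p$Dup <- list(list(g_nt("Loc"), g_lit("dup"), g_opt(g_nt("RemovedSeq")),
                     g_opt(g_nt("Nest"))))
  p$Ins <- list(list(g_nt("RangeLoc"), g_lit("ins"), g_nt("InsTarget"),
                     g_opt(g_nt("Nest"))))
  p$Indel <- list(list(g_nt("Loc"), g_lit("del"), g_opt(g_nt("RemovedSeq")),
                       g_lit("ins"), g_nt("InsTarget")))
  p$Inv <- list(list(g_nt("RangeLoc"), g_lit("inv"),
                     g_opt(g_nt("RemovedSeq")), g_opt(g_nt("Nest"))))
  p$Conv <- list(list(g_nt("RangeLoc"), g_lit("con"), g_nt("FarLoc"),
                      g_opt(g_nt("Nest"))))
  p$RemovedSeq <- list(list(g_nt("NtString")), list(g_nt("Num")))
  p$InsTarget <- list(list(g_nt("NtString")), list(g_nt("Num")),
                      list(g_nt("RangeLoc")), list(g_nt("FarLoc")))
  p$Nest <- list(list(g_lit("{"), g_nt("VarList"), g_lit("}")))
  p$FarLoc <- list(list(g_nt("RefSeqId"),
                        g_opt(g_lit(":"),
                              g_opt(g_cls("RefType"), g_lit(".")),
                              g_nt("Loc"))))
  p$Loc <- c(list(list(g_nt("PtLoc")), list(g_nt("RangeLoc"))),
             if (legacy) list(list(g_nt("EXLoc"))))
  p$RangeLoc <- list(list(g_nt("PtLoc"), g_lit("_"), g_nt("PtLoc")))
  p$PtLoc <- c(list(list(g_opt(g_cls("UTR")), g_nt("Num"),
                         g_opt(g_nt("Offset"))),
                    list(g_opt(g_cls("UTR")), g_lit("?"))),
               if (legacy) list(list(g_nt("IVSLoc"))))
  p$Offset <- list(list(g_cls("Sign"), g_opt(g_cls("UD")), g_nt("NumQ")))
  p$NumQ <- list(list(g_nt("Num")), list(g_lit("?")))
  if (legacy) {
    p$IVSLoc <- list(list(g_lit("IVS"), g_nt("Num"), g_cls("Sign"),
                          g_nt("Num")))
    p$EXLoc <- list(list(g_lit("EX"), g_nt("Num"),
                         g_opt(g_lit("-"), g_nt("Num"))))
  }
  p$NtString <- list(list(g_plus(g_cls("Nt"))))
  new_grammar("Var", p, base_terminals(), "dna_rna", dialect)
}

grammar_protein <- function(dialect) {
  p <- refseq_productions()
  p$ProteinVar <- list(list(g_opt(g_nt("PRef")), g_nt("PBody")),
                       list(g_opt(g_nt("PRef")), g_lit("("), g_nt("PBody"),
                            g_lit(")")))
  p$PRef <- list(list(g_opt(g_nt("RefSeqId"), g_lit(":")), g_lit("p.")))
  p$PBody <- list(list(g_nt("PSubst")), list(g_nt("PDel")),
                  list(g_nt("PDup")), list(g_nt("PIns")),
                  list(g_nt("PIndel")), list(g_nt("PFs")),
                  list(g_lit("=")), list(g_lit("?")), list(g_lit("0")))
  p$PSubst <- list(list(g_nt("AALoc"), g_nt("AA")))
  p$PDel <- list(list(g_nt("AALocOrRange"), g_lit("del")))
  p$PDup <- list(list(g_nt("AALocOrRange"), g_lit("dup")))
  p$PIns <- list(list(g_nt("AARange"), g_lit("ins"), g_nt("PInsTarget")))
  p$PIndel <- list(list(g_nt("AALocOrRange"), g_lit("delins"),
                        g_nt("AASeq")))
  p$PFs <- list(list(g_nt("AALoc"), g_nt("AA"), g_lit("fs"),
                     g_opt(g_nt("Stop"), g_nt("NumQ"))),
                list(g_nt("AALoc"), g_lit("fs")))
  p$PInsTarget <- list(list(g_nt("AASeq")), list(g_nt("Num")))
  p$AALocOrRange <- list(list(g_nt("AALoc")), list(g_nt("AARange")))
  p$AARange <- list(list(g_nt("AALoc"), g_lit("_"), g_nt("AALoc")))
  p$AALoc <- list(list(g_nt("AA"), g_nt("Num")))
  p$AASeq <- list(list(g_plus(g_nt("AA"))))
  p$AA <- c(lapply(AA3_ALL, function(code) list(g_lit(code))),
            list(list(g_cls("AA1"))))
  p$Stop <- list(list(g_lit(AA_STOP3)), list(g_lit("*")), list(g_lit("X")))
  p$NumQ <- list(list(g_nt("Num")), list(g_lit("?")))
  terms <- base_terminals()
  terms$AA1 <- AA1_ALL
  new_grammar("ProteinVar", p, terms, "protein", dialect)
}

#' Export the nomenclature grammar as data
#'
#' Returns the production set behind the parser for a level and dialect as
#' a `hgvs_grammar` object: a named list of productions (each a list of
#' alternative bodies over literal, character-class, nonterminal and
#' EBNF `?`/`*`/`+` symbols), named terminal classes, and the start symbol
#' (`Var` at the DNA/RNA level, `ProteinVar` at the protein level). The
#' legacy dialect adds the `IVSLoc`/`EXLoc` deviation productions and `+`
#' separators; the lenient dialect further adds the `/`, `->`, `-->`
#' substitution operators.
#'
#' One deliberate approximation: the parser accepts `/` as a lenient
#' substitution operator only outside brackets, a context restriction a
#' context-free production set cannot carry, so the exported lenient
#' grammar slightly over-generates there.
#'
#' @param level `"dna_rna"` or `"protein"`.
#' @param dialect `"strict"`, `"legacy"` or `"lenient"`.
#' @return An object of class `hgvs_grammar`.
#' @examples
#' g <- hgvs_export_grammar("dna_rna", "strict")
#' g$start
#' names(g$productions)[1:5]
#' @export
hgvs_export_grammar <- function(level = "dna_rna", dialect = "strict") {
  level <- match_arg2(level, LEVELS, "level")
  dialect <- match_arg2(dialect, DIALECTS, "dialect")
  if (level == "dna_rna") grammar_dna(dialect) else grammar_protein(dialect)
}

#' Designated sub-grammars for exhaustive oracle comparison
#'
#' Small closed fragments of the two grammars over reduced terminal
#' alphabets, chosen so that the fragment's language equals the full
#' parser's language restricted to strings over that alphabet. These are
#' the grammars on which parser acceptance is compared exhaustively with
#' context-free membership (see [hgvs_cyk_member()]); the full language is
#' far too large to enumerate.
#'
#' `"dna_core"`: substitutions and deletions (point or range locations,
#' optional removed sequence/length) over the alphabet
#' `2 7 4 G T > d e l _` — within that alphabet `d` doubles as an IUPAC
#' ambiguity nucleotide, exactly as the full parser treats it.
#' `"protein_core"`: substitutions, deletions and duplications over
#' `G l y u S e r d p 1 2 _`, admitting the residues Gly, Glu, Ser, G, S
#' (every amino-acid code spellable within the alphabet).
#'
#' @param name `"dna_core"` or `"protein_core"`.
#' @return An `hgvs_grammar`.
#' @examples
#' hgvs_subgrammar("dna_core")$start
#' @export
hgvs_subgrammar <- function(name = c("dna_core", "protein_core")) {
  name <- match.arg(name)
  if (name == "dna_core") {
    p <- list(
      S = list(list(g_nt("SubstS")), list(g_nt("DelS"))),
      SubstS = list(list(g_nt("NumS"), g_cls("NtS"), g_lit(">"),
                         g_cls("NtS"))),
      DelS = list(list(g_nt("LocS"), g_lit("del"), g_opt(g_nt("RemS")))),
      RemS = list(list(g_nt("NtStringS")), list(g_nt("NumS"))),
      LocS = list(list(g_nt("NumS")),
                  list(g_nt("NumS"), g_lit("_"), g_nt("NumS"))),
      NumS = list(list(g_plus(g_cls("DS")))),
      NtStringS = list(list(g_plus(g_cls("NtS"))))
    )
    new_grammar("S", p, list(DS = c("2", "7", "4"), NtS = c("G", "T", "d")),
                "dna_rna", "strict")
  } else {
    p <- list(
      S = list(list(g_nt("PSubstS")), list(g_nt("PDelS")),
               list(g_nt("PDupS"))),
      PSubstS = list(list(g_nt("AALocS"), g_nt("AAS"))),
      PDelS = list(list(g_nt("PLocS"), g_lit("del"))),
      PDupS = list(list(g_nt("PLocS"), g_lit("dup"))),
      PLocS = list(list(g_nt("AALocS")),
                   list(g_nt("AALocS"), g_lit("_"), g_nt("AALocS"))),
      AALocS = list(list(g_nt("AAS"), g_nt("NumS"))),
      AAS = list(list(g_lit("Gly")), list(g_lit("Glu")), list(g_lit("Ser")),
                 list(g_lit("G")), list(g_lit("S"))),
      NumS = list(list(g_plus(g_cls("DS"))))
    )
    new_grammar("S", p, list(DS = c("1", "2")), "protein", "strict")
  }
}

grammar_symbol_chars <- function(g) {
  chars <- character()
  walk <- function(sym) {
    switch(sym$kind,
      lit = chars <<- c(chars, strsplit(sym$value, "", fixed = TRUE)[[1]]),
      class = chars <<- c(chars, g$terminals[[sym$value]]),
      nt = NULL,
      lapply(sym$body, walk))
    invisible(NULL)
  }
  for (prod in g$productions) for (body in prod) lapply(body, walk)
  sort(unique(chars))
}

#' Reachable and defined nonterminals of a grammar
#'
#' Utility used to validate exported grammars: every nonterminal reachable
#' from the start symbol must have a defining production.
#'
#' @param g An `hgvs_grammar`.
#' @return A list with `defined`, `reachable` and `undefined` nonterminal
#'   name vectors.
#' @export
hgvs_grammar_nonterminals <- function(g) {
  body_nts <- function(body) {
    out <- character()
    walk <- function(sym) {
      if (sym$kind == "nt") {
        out <<- c(out, sym$value)
      } else if (sym$kind %in% c("opt", "star", "plus")) {
        lapply(sym$body, walk)
      }
      invisible(NULL)
    }
    lapply(body, walk)
    out
  }
  refs <- lapply(g$productions, function(prod) {
    unique(unlist(lapply(prod, body_nts), use.names = FALSE))
  })
  reachable <- g$start
  repeat {
    new <- unique(c(reachable,
                    unlist(refs[intersect(reachable, names(refs))],
                           use.names = FALSE)))
    if (length(new) == length(reachable)) break
    reachable <- new
  }
  defined <- names(g$productions)
  list(defined = defined, reachable = sort(reachable),
       undefined = sort(setdiff(reachable, defined)))
}

#' Serialize a grammar to JSON
#'
#' Schema: `{start, level, dialect, terminals: {name: [chars]},
#' productions: {name: [[symbol, ...], ...]}}`, where a symbol is
#' `{kind: "nt"|"lit"|"class", value}` or
#' `{kind: "opt"|"star"|"plus", body: [symbol, ...]}`.
#'
#' @param g An `hgvs_grammar`.
#' @param pretty Indent the output.
#' @return A `json` character scalar.
#' @export
hgvs_grammar_json <- function(g, pretty = FALSE) {
  sym_export <- function(sym) {
    if (sym$kind %in% c("opt", "star", "plus")) {
      list(kind = sym$kind, body = lapply(sym$body, sym_export))
    } else {
      list(kind = sym$kind, value = sym$value)
    }
  }
  out <- list(
    start = g$start, level = g$level, dialect = g$dialect,
    terminals = g$terminals,
    productions = lapply(g$productions, function(prod) {
      lapply(prod, function(body) lapply(body, sym_export))
    }))
  jsonlite::toJSON(out, auto_unbox = TRUE, pretty = pretty)
}

#' @export
print.hgvs_grammar <- function(x, ...) {
  cat(sprintf("<hgvs_grammar> start=%s level=%s dialect=%s (%d productions, %d terminal classes)\n",
              x$start, x$level, x$dialect, length(x$productions),
              length(x$terminals)))
  invisible(x)
}
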
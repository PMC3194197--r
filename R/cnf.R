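# Chomsky-normal-form conversion of an hgvs_grammar, enabling the CYK
# membership oracle. Pipeline: EBNF -> BNF (expand ?/*/+, character
# classes, multi-character literals), epsilon elimination, terminal
# lifting, binarization, unit-production elimination, and removal of
# unproductive/unreachable symbols.

#' Convert a grammar to Chomsky normal form
#'
#' Produces an equivalent grammar whose productions are all `A -> B C`
#' (two nonterminals) or `A -> a` (one terminal character). The language
#' is preserved for every non-empty string; none of the nomenclature
#' grammars derive the empty string.
#'
#' @param g An `hgvs_grammar` (from [hgvs_export_grammar()],
#'   [hgvs_subgrammar()] or hand-built with the same symbol vocabulary).
#' @return An `hgvs_grammar` in CNF (attribute `cnf` set), accepted by
#'   [hgvs_cyk_member()].
#' @examples
#' toy <- list(S = list(list(g_lit("a"), g_nt("S")), list(g_lit("b"))))
#' g <- structure(list(start = "S", productions = toy,
#'                     terminals = list(), level = "dna_rna",
#'                     dialect = "strict"), class = "hgvs_grammar")
#' cnf <- hgvs_to_cnf(g)
#' hgvs_cyk_member(cnf, "aab")
#' @export
hgvs_to_cnf <- function(g) {
  stopifnot(inherits(g, "hgvs_grammar"))
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  fresh <- function(prefix) {
    counter$i <- counter$i + 1L
    sprintf("%s%%%d", prefix, counter$i)
  }
  prods <- list()  # name -> list of bodies; body = list of syms (nt/lit-char)
  add_prod <- function(name, body) {
    prods[[name]] <<- c(prods[[name]], list(body))
  }
  class_nts <- new.env(parent = emptyenv())

  expand_sym <- function(sym) {
    # returns a list of plain symbols (each kind nt or single-char lit)
    switch(sym$kind,
      nt = list(sym),
      lit = lapply(strsplit(sym$value, "", fixed = TRUE)[[1]],
                   function(ch) list(kind = "lit", value = ch)),
      class = {
        nt <- class_nts[[sym$value]]
        if (is.null(nt)) {
          nt <- fresh(paste0("cls_", sym$value))
          assign(sym$value, nt, envir = class_nts)
          chars <- g$terminals[[sym$value]]
          if (is.null(chars)) {
            stop("undefined terminal class: ", sym$value, call. = FALSE)
          }
          for (ch in chars) {
            add_prod(nt, list(list(kind = "lit", value = ch)))
          }
        }
        list(list(kind = "nt", value = nt))
      },
      opt = {
        nt <- fresh("opt")
        add_prod(nt, list())
        add_prod(nt, expand_body(sym$body))
        list(list(kind = "nt", value = nt))
      },
      star = {
        nt <- fresh("star")
        inner <- expand_body(sym$body)
        add_prod(nt, list())
        add_prod(nt, c(inner, list(list(kind = "nt", value = nt))))
        list(list(kind = "nt", value = nt))
      },
      plus = {
        nt <- fresh("plus")
        inner <- expand_body(sym$body)
        add_prod(nt, inner)
        add_prod(nt, c(inner, list(list(kind = "nt", value = nt))))
        list(list(kind = "nt", value = nt))
      },
      stop("unsupported grammar construct: ", sym$kind, call. = FALSE))
  }
  expand_body <- function(body) {
    out <- do.call(c, lapply(body, expand_sym))
    if (is.null(out)) out <- list()
    out
  }
  for (name in names(g$productions)) {
    for (body in g$productions[[name]]) {
      add_prod(name, expand_body(body))
    }
  }

  # --- epsilon elimination -------------------------------------------------
  nullable <- character()
  repeat {
    new_null <- nullable
    for (name in names(prods)) {
      if (name %in% new_null) next
      for (body in prods[[name]]) {
        if (!length(body) ||
            all(vapply(body, function(s) {
              s$kind == "nt" && s$value %in% nullable
            }, logical(1)))) {
          new_null <- c(new_null, name)
          break
        }
      }
    }
    if (length(new_null) == length(nullable)) break
    nullable <- new_null
  }
  nullable_start <- g$start %in% nullable
  strip_eps <- function(body) {
    # all variants of body with nullable nonterminals optionally dropped
    variants <- list(list())
    for (sym in body) {
      if (sym$kind == "nt" && sym$value %in% nullable) {
        with_sym <- lapply(variants, function(v) c(v, list(sym)))
        variants <- c(variants, with_sym)
      } else {
        variants <- lapply(variants, function(v) c(v, list(sym)))
      }
    }
    variants
  }
  prods2 <- list()
  for (name in names(prods)) {
    seen <- character()
    out <- list()
    for (body in prods[[name]]) {
      for (v in strip_eps(body)) {
        if (!length(v)) next
        key <- paste(vapply(v, function(s) paste0(s$kind, ":", s$value),
                            character(1)), collapse = " ")
        if (!key %in% seen) {
          seen <- c(seen, key)
          out <- c(out, list(v))
        }
      }
    }
    if (length(out)) prods2[[name]] <- out
  }
  prods <- prods2

  # --- terminal lifting and binarization -----------------------------------
  term_nts <- new.env(parent = emptyenv())
  lift_term <- function(ch) {
    nt <- term_nts[[ch]]
    if (is.null(nt)) {
      nt <- fresh("t")
      assign(ch, nt, envir = term_nts)
      prods[[nt]] <<- c(prods[[nt]], list(list(list(kind = "lit",
                                                    value = ch))))
    }
    nt
  }
  names0 <- names(prods)
  for (name in names0) {
    bodies <- prods[[name]]
    new_bodies <- list()
    for (body in bodies) {
      if (length(body) >= 2L) {
        body <- lapply(body, function(s) {
          if (s$kind == "lit") list(kind = "nt", value = lift_term(s$value))
          else s
        })
        while (length(body) > 2L) {
          nt <- fresh("bin")
          prods[[nt]] <- list(body[1:2])
          body <- c(list(list(kind = "nt", value = nt)), body[-(1:2)])
          # keep left-to-right order: first two become the fresh NT
        }
      }
      new_bodies <- c(new_bodies, list(body))
    }
    prods[[name]] <- new_bodies
  }

  # --- unit-production elimination -----------------------------------------
  unit_closure <- function(name) {
    out <- name
    repeat {
      grown <- out
      for (a in out) {
        for (body in prods[[a]]) {
          if (length(body) == 1L && body[[1]]$kind == "nt") {
            grown <- unique(c(grown, body[[1]]$value))
          }
        }
      }
      if (length(grown) == length(out)) break
      out <- grown
    }
    out
  }
  prods3 <- list()
  for (name in names(prods)) {
    out <- list()
    seen <- character()
    for (b in unit_closure(name)) {
      for (body in prods[[b]]) {
        if (length(body) == 1L && body[[1]]$kind == "nt") next
        key <- paste(vapply(body, function(s) paste0(s$kind, ":", s$value),
                            character(1)), collapse = " ")
        if (!key %in% seen) {
          seen <- c(seen, key)
          out <- c(out, list(body))
        }
      }
    }
    if (length(out)) prods3[[name]] <- out
  }
  prods <- prods3

  # --- drop unproductive and unreachable nonterminals ----------------------
  productive <- character()
  repeat {
    grown <- productive
    for (name in names(prods)) {
      if (name %in% grown) next
      for (body in prods[[name]]) {
        ok <- all(vapply(body, function(s) {
          s$kind == "lit" || s$value %in% productive
        }, logical(1)))
        if (ok) {
          grown <- c(grown, name)
          break
        }
      }
    }
    if (length(grown) == length(productive)) break
    productive <- grown
  }
  prods <- prods[intersect(names(prods), productive)]
  prods <- lapply(prods, function(bodies) {
    Filter(function(body) {
      all(vapply(body, function(s) s$kind == "lit" || s$value %in% productive,
                 logical(1)))
    }, bodies)
  })
  reachable <- g$start
  repeat {
    grown <- reachable
    for (name in intersect(reachable, names(prods))) {
      for (body in prods[[name]]) {
        for (s in body) {
          if (s$kind == "nt") grown <- unique(c(grown, s$value))
        }
      }
    }
    if (length(grown) == length(reachable)) break
    reachable <- grown
  }
  prods <- prods[intersect(names(prods), reachable)]

  out <- new_grammar(g$start, prods, g$terminals, g$level, g$dialect)
  attr(out, "cnf") <- TRUE
  attr(out, "nullable_start") <- nullable_start
  out
}
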
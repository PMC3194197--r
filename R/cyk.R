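# CYK membership and bounded language enumeration over CNF grammars: the
# independent context-free oracles against which the hand-built
# recursive-descent parser is verified.

cnf_tables <- function(cnf) {
  nts <- names(cnf$productions)
  term_a <- character()
  term_c <- character()
  bin_a <- integer()
  bin_b <- integer()
  bin_c <- integer()
  for (i in seq_along(nts)) {
    for (body in cnf$productions[[i]]) {
      if (length(body) == 1L) {
        term_a <- c(term_a, nts[[i]])
        term_c <- c(term_c, body[[1]]$value)
      } else {
        bin_a <- c(bin_a, i)
        bin_b <- c(bin_b, match(body[[1]]$value, nts))
        bin_c <- c(bin_c, match(body[[2]]$value, nts))
      }
    }
  }
  list(nts = nts, term_a = term_a, term_c = term_c,
       bin_a = bin_a, bin_b = bin_b, bin_c = bin_c,
       start = match(cnf$start, nts))
}

check_cnf <- function(cnf) {
  if (!inherits(cnf, "hgvs_grammar") || !isTRUE(attr(cnf, "cnf"))) {
    stop("`cnf` must be a grammar in Chomsky normal form (see hgvs_to_cnf)",
         call. = FALSE)
  }
}

#' CYK membership test
#'
#' The standard cubic dynamic-programming membership algorithm for a
#' context-free grammar in Chomsky normal form. Used as a brute-force
#' oracle, independent of the recursive-descent parser, on short strings
#' over the designated sub-grammars.
#'
#' @param cnf A CNF grammar from [hgvs_to_cnf()].
#' @param text The candidate string (practical bound: a few dozen
#'   characters; the algorithm is O(n^3 |productions|)).
#' @return `TRUE` iff `text` is in the grammar's language.
#' @examples
#' cnf <- hgvs_to_cnf(hgvs_subgrammar("dna_core"))
#' hgvs_cyk_member(cnf, "274G>T")
#' hgvs_cyk_member(cnf, "G>T")
#' @export
hgvs_cyk_member <- function(cnf, text) {
  check_cnf(cnf)
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) return(isTRUE(attr(cnf, "nullable_start")))
  tab <- cnf_tables(cnf)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  nn <- length(tab$nts)
  # sets[[i]][[j]]: nonterminal indices deriving chars[i..(i+j-1)]
  sets <- vector("list", n)
  for (i in seq_len(n)) {
    sets[[i]] <- vector("list", n - i + 1L)
    sets[[i]][[1L]] <- unique(match(tab$term_a[tab$term_c == chars[[i]]],
                                    tab$nts))
  }
  if (n > 1L) {
    for (len in 2:n) {
      for (i in seq_len(n - len + 1L)) {
        acc <- integer()
        for (k in seq_len(len - 1L)) {
          left <- sets[[i]][[k]]
          right <- sets[[i + k]][[len - k]]
          if (!length(left) || !length(right)) next
          hit <- tab$bin_b %in% left & tab$bin_c %in% right
          if (any(hit)) acc <- c(acc, tab$bin_a[hit])
        }
        sets[[i]][[len]] <- unique(acc)
      }
    }
  }
  tab$start %in% sets[[1L]][[n]]
}

#' Enumerate a CNF grammar's language up to a length bound
#'
#' Bottom-up, length-bounded derivation closure: for every nonterminal the
#' set of strings of at most `max_len` characters it derives, computed as
#' the least fixpoint of the CNF productions — the same fixpoint CYK
#' evaluates per string, here evaluated for all strings at once. This is
#' what makes an exhaustive comparison of parser acceptance with
#' context-free membership over every string up to a length bound
#' tractable.
#'
#' @param cnf A CNF grammar from [hgvs_to_cnf()].
#' @param max_len Maximum string length to enumerate.
#' @return Sorted character vector: every string of length `<= max_len` in
#'   the language of the start symbol.
#' @examples
#' cnf <- hgvs_to_cnf(hgvs_subgrammar("dna_core"))
#' head(hgvs_enumerate_language(cnf, 4))
#' @export
hgvs_enumerate_language <- function(cnf, max_len) {
  check_cnf(cnf)
  stopifnot(is.numeric(max_len), max_len >= 1)
  nts <- names(cnf$productions)
  sets <- stats::setNames(rep(list(character()), length(nts)), nts)
  bins <- list()
  for (name in nts) {
    for (body in cnf$productions[[name]]) {
      if (length(body) == 1L) {
        sets[[name]] <- union(sets[[name]], body[[1]]$value)
      } else {
        bins <- c(bins, list(c(name, body[[1]]$value, body[[2]]$value)))
      }
    }
  }
  concat_bounded <- function(bs, cs, bound) {
    if (!length(bs) || !length(cs)) return(character())
    out <- character()
    bl <- nchar(bs)
    cl <- nchar(cs)
    for (lb in sort(unique(bl))) {
      room <- bound - lb
      if (room < 1L) next
      cc <- cs[cl <= room]
      if (!length(cc)) next
      out <- c(out, as.vector(outer(bs[bl == lb], cc, paste0)))
    }
    out
  }
  repeat {
    total <- sum(lengths(sets))
    for (rule in bins) {
      new <- concat_bounded(sets[[rule[[2]]]], sets[[rule[[3]]]], max_len)
      if (length(new)) sets[[rule[[1]]]] <- union(sets[[rule[[1]]]], new)
    }
    if (sum(lengths(sets)) == total) break
  }
  sort(sets[[cnf$start]])
}
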
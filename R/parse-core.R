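# Recursive-descent parser infrastructure.
#
# A parser state is an environment holding the input as a character vector,
# a 0-based cursor `pos` (number of characters consumed), the furthest
# 0-based index any rule ever *required* (`far`, the halt position on
# rejection), and `hit_end`, whether any rule required a character at or
# beyond the end of the input. `hit_end` is what makes exhaustive language
# exploration tractable: if an input is rejected without hitting its end,
# no rule ever looked at the final character, so every extension replays
# the same execution and is rejected too.
#
# Rule functions return NULL on failure or a list `(ast =, node =)`;
# callers save and restore `pos` around alternatives. `far`/`hit_end` are
# global maxima and are never rolled back.

ps_new <- function(text, dialect = "strict", tree = FALSE) {
  chars <- if (nzchar(text)) {
    if (validUTF8(text)) {
      strsplit(text, "", fixed = TRUE)[[1]]
    } else {
      strsplit(text, "", fixed = TRUE, useBytes = TRUE)[[1]]
    }
  } else {
    character()
  }
  ps <- new.env(parent = emptyenv())
  ps$s <- text
  ps$chars <- chars
  ps$n <- length(chars)
  ps$pos <- 0L
  ps$far <- 0L
  ps$hit_end <- FALSE
  ps$dialect <- dialect
  ps$tree <- tree
  ps$brackets <- 0L
  ps$nest_depth <- 0L
  ps
}

ps_reset <- function(ps) {
  ps$pos <- 0L
  ps$brackets <- 0L
  ps$nest_depth <- 0L
  ps
}

# Character at 0-based index i, or NA past the end; registers the demand.
ps_need <- function(ps, i) {
  if (i > ps$far) ps$far <- i
  if (i >= ps$n) {
    ps$hit_end <- TRUE
    return(NA_character_)
  }
  ps$chars[[i + 1L]]
}

r <- function(ast, node) list(ast = ast, node = node)

leafnode <- function(ps, rule, start) {
  if (!ps$tree) return(NULL)
  list(rule = rule, span = c(start, ps$pos),
       text = substr(ps$s, start + 1L, ps$pos), children = list())
}

node <- function(ps, rule, start, kids) {
  if (!ps$tree) return(NULL)
  kids <- kids[!vapply(kids, is.null, logical(1))]
  list(rule = rule, span = c(start, ps$pos),
       text = substr(ps$s, start + 1L, ps$pos), children = kids)
}

.lit_cache <- new.env(parent = emptyenv())
lit_chars <- function(s) {
  cs <- .lit_cache[[s]]
  if (is.null(cs)) {
    cs <- strsplit(s, "", fixed = TRUE)[[1]]
    assign(s, cs, envir = .lit_cache)
  }
  cs
}

# Consume a literal; produces a leaf. Restores nothing on failure (pos is
# untouched until the full literal matches). The scan registers its
# furthest demanded index exactly as ps_need would, with the loop inlined.
p_lit <- function(ps, s, rule = "Sym") {
  p <- ps$pos
  chars <- ps$chars
  n <- ps$n
  if (nchar(s) == 1L) {
    if (p >= n) {
      if (p > ps$far) ps$far <- p
      ps$hit_end <- TRUE
      return(NULL)
    }
    if (chars[[p + 1L]] != s) {
      if (p > ps$far) ps$far <- p
      return(NULL)
    }
    if (p > ps$far) ps$far <- p
    ps$pos <- p + 1L
    return(r(s, leafnode(ps, rule, p)))
  }
  cs <- lit_chars(s)
  k <- length(cs)
  for (i in seq_len(k)) {
    idx <- p + i - 1L
    if (idx >= n) {
      if (idx > ps$far) ps$far <- idx
      ps$hit_end <- TRUE
      return(NULL)
    }
    if (chars[[idx + 1L]] != cs[[i]]) {
      if (idx > ps$far) ps$far <- idx
      return(NULL)
    }
  }
  idx <- p + k - 1L
  if (idx > ps$far) ps$far <- idx
  ps$pos <- p + k
  r(s, leafnode(ps, rule, p))
}

p_num <- function(ps) {
  p <- ps$pos
  chars <- ps$chars
  n <- ps$n
  i <- p
  while (i < n && chars[[i + 1L]] %in% DIGITS) i <- i + 1L
  if (i > ps$far) ps$far <- i
  if (i >= n) ps$hit_end <- TRUE
  if (i == p) return(NULL)
  ps$pos <- i
  digits <- substr(ps$s, p + 1L, i)
  v <- strtoi(digits)
  if (is.na(v)) v <- as.numeric(digits)  # positions beyond integer range
  r(v, leafnode(ps, "Num", p))
}

p_nt <- function(ps) {
  ch <- ps_need(ps, ps$pos)
  if (is.na(ch) || !ch %in% IUPAC_NT) return(NULL)
  p <- ps$pos
  ps$pos <- p + 1L
  r(ch, leafnode(ps, "Nt", p))
}

p_ntstring <- function(ps) {
  p <- ps$pos
  chars <- ps$chars
  n <- ps$n
  i <- p
  while (i < n && chars[[i + 1L]] %in% IUPAC_NT) i <- i + 1L
  if (i > ps$far) ps$far <- i
  if (i >= n) ps$hit_end <- TRUE
  if (i == p) return(NULL)
  ps$pos <- i
  r(substr(ps$s, p + 1L, i), leafnode(ps, "NtString", p))
}

# Characters that may legitimately follow a complete variant; used to
# disambiguate greedy insertion targets (NtString vs accession etc.).
BOUNDARY_CHARS <- c("]", ";", "/", "^", ",", "}", "{", "+", ")", "(")

at_boundary <- function(ps) {
  ch <- ps_need(ps, ps$pos)
  is.na(ch) || ch %in% BOUNDARY_CHARS
}

hgvs_syntax_error <- function(input, position, message = NULL) {
  if (is.null(message)) {
    message <- sprintf("syntax error at position %d in \"%s\"",
                       position, input)
  }
  stop(structure(
    class = c("hgvs_syntax_error", "error", "condition"),
    list(message = message, call = NULL,
         input = input, position = position)))
}
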
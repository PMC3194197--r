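# Exhaustive exploration of the parser's language over a small alphabet.
#
# Naively testing every string up to length L over k characters is k^L
# parser runs. The parser state records `hit_end`: whether any rule ever
# demanded a character at or beyond the end of the input. If a prefix is
# rejected *without* hitting its end, the parser never read past its last
# character, so every extension replays the identical execution and is
# rejected as well — that whole subtree of the string trie can be pruned.
# What remains is the set of viable prefixes, which for these grammars is
# tiny compared to k^L, making the comparison with the context-free
# enumeration exact and cheap.

#' Enumerate all strings the parser accepts over a reduced alphabet
#'
#' Depth-first search over the trie of strings up to `max_len` characters
#' drawn from `alphabet`, running the production parser (via the same
#' machinery as [hgvs_check()]) on each viable prefix and pruning branches
#' the parser provably rejects without reading their last character.
#' The result is exactly `{ s over alphabet : nchar(s) <= max_len,
#' check(s) valid }`.
#'
#' @param alphabet Character vector of single characters.
#' @param max_len Maximum string length.
#' @param level,dialect Grammar level and dialect to run the parser in.
#' @param forms Which entry forms to probe. An entry form whose mandatory
#'   punctuation (`:` for `full`, the coordinate letter plus `.` for
#'   `coordinate_prefixed`) lies outside `alphabet` can never accept a
#'   string over it, but its speculative token scans reach the end of
#'   almost every prefix and so destroy the pruning; restrict to the
#'   forms the alphabet can realize (the designated sub-grammar alphabets
#'   support `"bare"` only).
#' @return List with `accepted` (sorted character vector) and `probes`
#'   (how many parser runs the pruned search needed).
#' @examples
#' hgvs_parser_language(c("2", "G", "T", ">"), 5, forms = "bare")$accepted
#' @export
hgvs_parser_language <- function(alphabet, max_len, level = "dna_rna",
                                 dialect = "strict",
                                 forms = DESCRIPTION_FORMS) {
  level <- match_arg2(level, LEVELS, "level")
  dialect <- match_arg2(dialect, DIALECTS, "dialect")
  stopifnot(is.character(alphabet), all(nchar(alphabet) == 1L),
            max_len >= 1, all(forms %in% DESCRIPTION_FORMS))
  accepted <- character()
  probes <- 0L
  # manual stack of prefixes (strings); seeded with single characters
  stack <- alphabet
  while (length(stack)) {
    s <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    probes <- probes + 1L
    res <- probe_description(s, level, dialect, forms = forms)
    if (res$ok) accepted <- c(accepted, s)
    if (nchar(s) < max_len && (res$ok || res$hit_end)) {
      stack <- c(stack, paste0(s, alphabet))
    }
  }
  list(accepted = sort(accepted), probes = probes)
}

#' Compare parser acceptance with context-free membership, exhaustively
#'
#' Runs the two independent routes over every string up to `max_len`
#' characters over the sub-grammar's alphabet: the production parser (via
#' [hgvs_parser_language()], exhaustive with sound pruning) and the CNF
#' derivation closure (via [hgvs_enumerate_language()], the CYK fixpoint
#' evaluated for all strings at once). Additionally replays the
#' per-string [hgvs_cyk_member()] oracle on every member and on a sample
#' of parser-rejected strings.
#'
#' @param name Sub-grammar name (see [hgvs_subgrammar()]).
#' @param max_len Length bound for the exhaustive comparison.
#' @param spot_check_rejected How many rejected strings to replay through
#'   the per-string CYK oracle (0 to skip).
#' @param seed Seed for the rejected-string sample.
#' @return List with `n_strings` (size of the exhaustively covered string
#'   space), `members` (the language), `parser_only`, `grammar_only`
#'   (disagreements, empty on success), `disagreements` (their count) and
#'   `probes`.
#' @export
hgvs_oracle_compare <- function(name = "dna_core", max_len = 8,
                                spot_check_rejected = 200, seed = 1L) {
  sub <- hgvs_subgrammar(name)
  alphabet <- grammar_symbol_chars(sub)
  cnf <- hgvs_to_cnf(sub)
  members <- hgvs_enumerate_language(cnf, max_len)
  # The sub-grammar alphabets exclude ":" and "." , so the full and
  # coordinate-prefixed entry forms can accept no string here; probing
  # only the bare form keeps the parser side identical and the trie
  # pruning effective.
  stopifnot(!any(c(":", ".") %in% alphabet))
  parser <- hgvs_parser_language(alphabet, max_len, level = sub$level,
                                 dialect = sub$dialect, forms = "bare")
  parser_only <- setdiff(parser$accepted, members)
  grammar_only <- setdiff(members, parser$accepted)
  cyk_member_ok <- all(vapply(members, function(s) hgvs_cyk_member(cnf, s),
                              logical(1)))
  cyk_reject_ok <- TRUE
  if (spot_check_rejected > 0) {
    rejected <- withr::with_seed(seed, {
      vapply(seq_len(spot_check_rejected), function(i) {
        paste(sample(alphabet, sample.int(max_len, 1L), replace = TRUE),
              collapse = "")
      }, character(1))
    })
    rejected <- setdiff(rejected, members)
    cyk_reject_ok <- !any(vapply(rejected,
                                 function(s) hgvs_cyk_member(cnf, s),
                                 logical(1)))
  }
  k <- length(alphabet)
  n_strings <- sum(k ^ seq_len(max_len))
  list(n_strings = n_strings, members = members,
       parser_only = parser_only, grammar_only = grammar_only,
       disagreements = length(parser_only) + length(grammar_only),
       cyk_member_ok = cyk_member_ok, cyk_reject_ok = cyk_reject_ok,
       probes = parser$probes)
}
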
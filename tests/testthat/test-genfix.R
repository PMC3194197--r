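# Generator and context-free oracle machinery.

test_that("generation is seeded, sized and depth-bounded", {
  cfg <- hgvs_generator_config(seed = 42, count = 5, max_depth = 6)
  out1 <- hgvs_generate(cfg)
  expect_length(out1, 5L)
  expect_identical(out1, hgvs_generate(cfg))  # same config, same corpus
  for (s in out1) expect_true(hgvs_check(s)$valid)

  expect_identical(hgvs_generate(hgvs_generator_config(seed = 1, count = 0)),
                   character())
  expect_error(hgvs_generator_config(seed = 1, count = 5, max_depth = 0),
               "configuration error")
  other <- hgvs_generate(hgvs_generator_config(seed = 43, count = 5))
  expect_false(identical(out1, other))
})

test_that("generated corpora are check()-closed in every level and dialect", {
  for (level in c("dna_rna", "protein")) {
    for (dialect in c("strict", "legacy", "lenient")) {
      cfg <- hgvs_generator_config(seed = 99, count = 150, level = level,
                                   dialect = dialect)
      strs <- hgvs_generate(cfg)
      ok <- vapply(strs, function(s) hgvs_check(s, level, dialect)$valid,
                   logical(1))
      expect_true(all(ok), label = paste(level, dialect, "closure"))
    }
  }
})

test_that("generated ASTs survive the serialize/parse round trip", {
  for (level in c("dna_rna", "protein")) {
    cfg <- hgvs_generator_config(seed = 3, count = 120, level = level,
                                 dialect = "legacy")
    asts <- hgvs_generate_asts(cfg)
    strs <- hgvs_generate(cfg)
    for (i in seq_along(asts)) {
      p <- parse_any(strs[[i]], level, "legacy", tree = FALSE)
      expect_true(hgvs_equal(p$ast, asts[[i]]), label = strs[[i]])
    }
  }
})

test_that("corpus files carry a reproducibility sidecar", {
  cfg <- hgvs_generator_config(seed = 5, count = 4)
  tmp <- withr::local_tempfile(fileext = ".txt")
  hgvs_write_corpus(hgvs_generate(cfg), tmp, cfg)
  expect_identical(readLines(tmp), hgvs_generate(cfg))
  meta <- jsonlite::read_json(paste0(tmp, ".meta.json"))
  expect_identical(meta$seed, 5L)
  expect_identical(meta$count, 4L)
  expect_identical(meta$level, "dna_rna")
})

test_that("CNF conversion preserves toy languages and prunes dead symbols", {
  toy <- structure(list(
    start = "S",
    productions = list(
      S = list(list(g_lit("a"), g_nt("S")), list(g_lit("b"))),
      Dead = list(list(g_lit("z")))),
    terminals = list(), level = "dna_rna", dialect = "strict"),
    class = "hgvs_grammar")
  cnf <- hgvs_to_cnf(toy)
  expect_true(isTRUE(attr(cnf, "cnf")))
  expect_false("Dead" %in% names(cnf$productions))  # unreachable dropped
  expect_true(hgvs_cyk_member(cnf, "aab"))
  expect_true(hgvs_cyk_member(cnf, "b"))
  expect_false(hgvs_cyk_member(cnf, "aa"))
  expect_false(hgvs_cyk_member(cnf, ""))
  # language preserved on enumerated strings
  expect_identical(hgvs_enumerate_language(cnf, 4),
                   sort(c("b", "ab", "aab", "aaab")))
  # bodies really are CNF: length-2 nonterminal pairs or single terminals
  for (bodies in cnf$productions) {
    for (body in bodies) {
      expect_true(
        (length(body) == 2L &&
           all(vapply(body, `[[`, character(1), "kind") == "nt")) ||
        (length(body) == 1L && body[[1]]$kind == "lit" &&
           nchar(body[[1]]$value) == 1L))
    }
  }
})

test_that("CYK membership matches the designated sub-grammar examples", {
  cnf <- hgvs_to_cnf(hgvs_subgrammar("dna_core"))
  expect_true(hgvs_cyk_member(cnf, "274G>T"))
  expect_true(hgvs_cyk_member(cnf, "24_42del"))
  expect_true(hgvs_cyk_member(cnf, "4delGT"))
  expect_false(hgvs_cyk_member(cnf, "G>T"))    # position required
  expect_false(hgvs_cyk_member(cnf, "274G>"))
  expect_error(hgvs_cyk_member(hgvs_subgrammar("dna_core"), "274G>T"),
               "Chomsky")
})

test_that("parser and context-free membership agree exhaustively (small bound)", {
  # the full acceptance bound is exercised in the acceptance suite;
  # here every string up to length 6 (dna) / 8 (protein)
  res <- hgvs_oracle_compare("dna_core", max_len = 6,
                             spot_check_rejected = 100)
  expect_identical(res$disagreements, 0L)
  expect_true(res$cyk_member_ok)
  expect_true(res$cyk_reject_ok)
  expect_gt(length(res$members), 100L)

  res <- hgvs_oracle_compare("protein_core", max_len = 8,
                             spot_check_rejected = 100)
  expect_identical(res$disagreements, 0L)
  expect_true(res$cyk_member_ok)
  expect_true(res$cyk_reject_ok)
})

test_that("single-character deletions mostly break corpus descriptions", {
  # Documents the language's redundancy; the exact ratio is recorded, not
  # asserted: deleting one digit of a multi-digit position still leaves a
  # valid description, so the ratio sits well below 1.
  ex <- hgvs_examples()
  ex <- ex[ex$level != "reference", ]
  n_total <- 0L
  n_rejected <- 0L
  for (i in seq_len(nrow(ex))) {
    s <- ex$description[[i]]
    for (j in seq_len(nchar(s))) {
      mutated <- paste0(substr(s, 1, j - 1L), substr(s, j + 1L, nchar(s)))
      res <- hgvs_check(mutated, level = ex$level[[i]])
      expect_s3_class(res, "hgvs_syntax_result")
      n_total <- n_total + 1L
      n_rejected <- n_rejected + !res$valid
    }
  }
  ratio <- n_rejected / n_total
  message(sprintf("single-deletion rejection ratio: %.3f (%d/%d)",
                  ratio, n_rejected, n_total))
  expect_gt(ratio, 0)
  expect_lte(ratio, 1)
})
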
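# Protein-level grammar and parser.

test_that("protein descriptions parse across entry forms", {
  p <- hgvs_parse_protein("p.Ser124Arg")
  expect_identical(p$ast$type, "subst")
  expect_identical(p$ast$loc$aa$code3, "Ser")
  expect_identical(p$ast$loc$position, 124L)
  expect_identical(p$ast$to$code3, "Arg")
  expect_identical(p$ast$ref$kind, "none")
  expect_identical(p$matched_form, "coordinate_prefixed")

  p <- hgvs_parse_protein("Gly123del")
  expect_identical(p$ast$type, "del")
  expect_identical(p$ast$loc$aa$code3, "Gly")
  expect_identical(p$matched_form, "bare")
  expect_false(p$ast$prefixed)

  p <- hgvs_parse_protein("LRG_1p1:p.Ser124Arg")
  expect_identical(p$matched_form, "full")
  expect_identical(p$ast$ref$kind, "lrg")
  expect_identical(p$ast$ref$lrg_protein, 1L)

  p <- hgvs_parse_protein("p.=")
  expect_identical(p$ast$type, "no_change")
  expect_identical(hgvs_parse_protein("p.?")$ast$type, "unknown")
  expect_identical(hgvs_parse_protein("p.0")$ast$type, "no_protein")
})

test_that("predicted consequences are flagged, not restructured", {
  p <- hgvs_parse_protein("p.(Ser124Arg)")
  expect_true(p$ast$predicted)
  expect_identical(p$ast$type, "subst")
  q <- hgvs_parse_protein("p.Ser124Arg")
  expect_false(q$ast$predicted)
  q$ast$predicted <- TRUE
  expect_true(hgvs_equal(p$ast, q$ast))
})

test_that("frameshifts parse their optional new-frame and stop parts", {
  p <- hgvs_parse_protein("p.Arg97fs")
  expect_identical(p$ast$type, "fs")
  expect_null(p$ast$first_new)
  expect_null(p$ast$new_stop)

  p <- hgvs_parse_protein("p.Arg97Glyfs*26")
  expect_identical(p$ast$first_new$code3, "Gly")
  expect_identical(p$ast$new_stop, list(surface = "*", count = 26L))

  p <- hgvs_parse_protein("p.Arg97GlyfsTer?")
  expect_true(is.na(p$ast$new_stop$count))

  # a stop position without the new residue is not in the grammar
  expect_false(hgvs_check("p.Arg97fsTer26", level = "protein")$valid)
})

test_that("amino-acid tokens resolve in both styles", {
  aa <- hgvs_parse_amino_acid("Ser")
  expect_identical(aa$code1, "S")
  expect_identical(aa$style, "three_letter")
  aa <- hgvs_parse_amino_acid("G")
  expect_identical(aa$code3, "Gly")
  expect_identical(aa$style, "one_letter")
  expect_identical(hgvs_parse_amino_acid("Ter")$code3, "Ter")
  expect_identical(hgvs_parse_amino_acid("*")$code3, "Ter")
  expect_identical(hgvs_parse_amino_acid("X")$code3, "Ter")
  err <- tryCatch(hgvs_parse_amino_acid("Xyz"),
                  hgvs_syntax_error = function(e) e)
  expect_identical(err$position, 0L)
})

test_that("each code style is closed under parsing without warnings", {
  three <- c("p.Ser124Arg", "Gly123_Cys125del", "p.Lys2_Met8dup",
             "p.Met1_Lys4delinsSerThr")
  one <- c("p.S124R", "G123_C125del", "p.K2_M8dup", "p.M1_K4delinsST")
  for (s in c(three, one)) {
    p <- hgvs_parse_protein(s)
    expect_length(hgvs_lint_mixed_code(p), 0L)
    expect_identical(hgvs_serialize(p$ast, preserve_surface = TRUE), s)
  }
})

test_that("mixed-style ranges lint but still parse", {
  p <- hgvs_parse_protein("G123_Cys125del")
  w <- hgvs_lint_mixed_code(p)
  expect_length(w, 1L)
  expect_match(w, "G123_Cys125")
  expect_length(hgvs_lint_mixed_code(hgvs_parse_protein("Gly123_Cys125del")),
                0L)
  expect_length(hgvs_lint_mixed_code(hgvs_parse_protein("p.Ser124Arg")), 0L)
})

test_that("insertions and deletion-insertions take sequences or lengths", {
  p <- hgvs_parse_protein("p.Lys2_Gly3insGln")
  expect_identical(p$ast$inserted$kind, "seq")
  expect_identical(p$ast$inserted$value[[1]]$code3, "Gln")
  p <- hgvs_parse_protein("p.Lys2_Gly3ins5")
  expect_identical(p$ast$inserted, list(kind = "length", value = 5L))
  p <- hgvs_parse_protein("p.Cys28delinsTrpVal")
  expect_identical(vapply(p$ast$inserted$value, `[[`, character(1), "code3"),
                   c("Trp", "Val"))
  expect_false(hgvs_check("p.Lys2ins5", level = "protein")$valid)
})
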
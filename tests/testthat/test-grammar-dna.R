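# DNA/RNA-level grammar and parser.

test_that("genotype-level descriptions parse to the documented structures", {
  p <- hgvs_parse_genotype("g.[158A>C/124C>T]")
  expect_identical(p$ast$form, "single_allele_set")
  expect_identical(p$ast$body$separators, "/")
  expect_identical(vapply(p$ast$body$items, `[[`, character(1), "type"),
                   c("subst", "subst"))

  p <- hgvs_parse_genotype("c.[=//85C>T]")
  expect_identical(p$ast$body$separators, "//")
  expect_identical(vapply(p$ast$body$items, `[[`, character(1), "type"),
                   c("no_change", "subst"))

  p <- hgvs_parse_genotype("c.[370A>C^372C>R]")
  expect_identical(p$ast$body$separators, "^")
  expect_identical(p$ast$body$items[[2]]$to, "R")  # IUPAC ambiguity letter

  p <- hgvs_parse_genotype("c.24_65inv{46G>T}")
  expect_identical(p$ast$body$type, "inv")
  nest <- p$ast$body$nest
  expect_s3_class(nest, "hgvs_variant_list")
  expect_identical(nest$items[[1]]$type, "subst")
  expect_identical(nest$items[[1]]$loc$base, 46L)

  p <- hgvs_parse_genotype("g.100_200delinsAB23456.7")
  expect_identical(p$ast$body$type, "delins")
  expect_identical(p$ast$body$inserted$kind, "farloc")
  expect_identical(p$ast$body$inserted$value$ref$accession, "AB23456")
  expect_identical(p$ast$body$inserted$value$ref$version, 7L)
})

test_that("single-variant form records reference, system and operands", {
  p <- hgvs_parse_single_variant("NM_003002.2:c.274G>T")
  expect_identical(p$matched_form, "full")
  expect_identical(p$ast$ref$accession, "NM_003002")
  expect_identical(p$ast$ref$version, 2L)
  expect_identical(p$ast$system, "c")
  expect_identical(p$ast$body$loc$base, 274L)
  expect_identical(p$ast$body$from, "G")
  expect_identical(p$ast$body$to, "T")

  p <- hgvs_parse_single_variant("n.46G>T")
  expect_identical(p$ast$system, "n")
  expect_identical(p$ast$ref$kind, "none")

  p <- hgvs_parse_single_variant("c.274G>T")
  expect_identical(p$ast$ref$kind, "none")
  expect_identical(p$matched_form, "coordinate_prefixed")

  p <- hgvs_parse_single_variant("IVS4+1G>T", dialect = "legacy")
  ivs <- p$ast$body$loc$ivs
  expect_identical(ivs, list(intron = 4L, sign = "+", distance = 1L))
  expect_error(hgvs_parse_single_variant("IVS4+1G>T"),
               class = "hgvs_syntax_error")

  expect_error(hgvs_parse_single_variant("g.[158A>C/124C>T]"),
               class = "hgvs_syntax_error")
})

test_that("point locations parse UTR markers and u/d offsets", {
  p <- hgvs_parse_point_location("*405+d256")
  expect_identical(p$region, "three_utr")
  expect_identical(p$base, 405L)
  expect_identical(p$offset$sign, "+")
  expect_identical(p$offset$beyond, "d")
  expect_identical(p$offset$magnitude, 256L)

  p <- hgvs_parse_point_location("-110-u256")
  expect_identical(p$region, "five_utr")
  expect_identical(p$base, 110L)
  expect_identical(p$offset, hgvs_offset("-", "u", 256))

  p <- hgvs_parse_point_location("?")
  expect_true(is.na(p$base))
  expect_null(p$offset)

  expect_error(hgvs_parse_point_location("12+"), class = "hgvs_syntax_error")
})

test_that("reference identifiers disambiguate LRG, accession and gene", {
  p <- hgvs_parse_reference("LRG_1t1")
  expect_identical(p[c("kind", "lrg_id", "lrg_transcript")],
                   list(kind = "lrg", lrg_id = 1L, lrg_transcript = 1L))
  expect_identical(hgvs_parse_reference("LRG_1p1")$lrg_protein, 1L)

  p <- hgvs_parse_reference("DMD_v2")
  expect_identical(p$kind, "gene")
  expect_identical(p$gene_symbol, "DMD")
  expect_identical(p$transcript_variant, 2L)
  expect_identical(hgvs_parse_reference("DMD_i2")$protein_isoform, 2L)

  p <- hgvs_parse_reference("NM_003002.2")
  expect_identical(p$kind, "genbank")
  expect_identical(p$accession, "NM_003002")
  expect_identical(p$version, 2L)

  # accession annotated with a gene in parentheses
  p <- hgvs_parse_reference("NG_012337.1(SDHD_v1)")
  expect_identical(p$gene_symbol, "SDHD")
  expect_identical(p$transcript_variant, 1L)
})

test_that("full-input consumption is required", {
  expect_error(hgvs_parse_genotype("c.274G>Tx"), class = "hgvs_syntax_error")
  err <- tryCatch(hgvs_parse_genotype("c.274G>Tx"),
                  hgvs_syntax_error = function(e) e)
  expect_identical(err$position, 8L)
  expect_error(hgvs_parse_genotype(""), class = "hgvs_syntax_error")
})

test_that("parsing is deterministic", {
  s <- "c.[370A>C^372C>R]"
  t1 <- hgvs_to_structured(hgvs_parse_genotype(s))
  t2 <- hgvs_to_structured(hgvs_parse_genotype(s))
  expect_identical(t1, t2)
  expect_identical(hgvs_parse_genotype(s)$ast, hgvs_parse_genotype(s)$ast)
})

test_that("nested sub-alleles recurse and the depth bound is enforced", {
  deep <- function(k) {
    paste0("g.1_9", strrep("inv{1_9", k), "inv",
           strrep("}", k))
  }
  p <- hgvs_parse_genotype(deep(16))
  expect_identical(p$ast$body$type, "inv")
  expect_true(hgvs_check(deep(16))$valid)
  expect_false(hgvs_check(deep(40))$valid)  # beyond the documented bound
})

test_that("exported grammars are well-formed and dialect-layered", {
  g <- hgvs_export_grammar("dna_rna", "strict")
  expect_identical(g$start, "Var")
  nts <- hgvs_grammar_nonterminals(g)
  expect_identical(nts$undefined, character())
  expect_false("IVSLoc" %in% names(g$productions))
  expect_false("EXLoc" %in% names(g$productions))

  gl <- hgvs_export_grammar("dna_rna", "legacy")
  expect_true(all(c("IVSLoc", "EXLoc") %in% names(gl$productions)))
  expect_identical(hgvs_grammar_nonterminals(gl)$undefined, character())

  # lenient adds the text-mining substitution operators
  ops <- function(g) {
    vapply(g$productions$SubstOp, function(b) b[[1]]$value, character(1))
  }
  expect_identical(ops(g), ">")
  expect_setequal(ops(hgvs_export_grammar("dna_rna", "lenient")),
                  c(">", "/", "->", "-->"))

  gp <- hgvs_export_grammar("protein", "strict")
  expect_identical(gp$start, "ProteinVar")
  expect_identical(hgvs_grammar_nonterminals(gp)$undefined, character())

  j <- jsonlite::fromJSON(hgvs_grammar_json(g), simplifyVector = FALSE)
  expect_identical(j$start, "Var")
  expect_true("Subst" %in% names(j$productions))
})

test_that("lenient operators work at top level but not inside brackets", {
  expect_true(hgvs_check("274G->T", dialect = "lenient")$valid)
  expect_false(hgvs_check("274G->T", dialect = "strict")$valid)
  expect_false(hgvs_check("274G->T", dialect = "legacy")$valid)
  # inside brackets "/" is the mosaic separator, never a substitution
  p <- hgvs_parse_genotype("c.[=/85C>T]", dialect = "lenient")
  expect_identical(p$ast$body$separators, "/")
  expect_false(hgvs_check("c.[370A->C]", dialect = "lenient")$valid)
})

test_that("numbers admit arbitrary digit runs without crashing", {
  res <- hgvs_check(paste0(strrep("9", 30), "G>T"))
  expect_true(res$valid)
})
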
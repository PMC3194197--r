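# AST model: construction, invariants, serialization, structural export.

test_that("serialization reproduces canonical description strings", {
  g <- hgvs_genotype(hgvs_subst(hgvs_ptloc(274), "G", "T"),
                     ref = hgvs_refseq("genbank", "NM_003002", 2),
                     system = "c")
  expect_identical(hgvs_serialize(g), "NM_003002.2:c.274G>T")

  expect_identical(hgvs_serialize(hgvs_no_change()), "=")

  nested <- hgvs_genotype(
    hgvs_inv(hgvs_loc_range(hgvs_ptloc(100), hgvs_ptloc(200)),
             nest = hgvs_variant_list(list(
               hgvs_subst(hgvs_ptloc(158), "A", "C")))),
    system = "g")
  expect_identical(hgvs_serialize(nested), "g.100_200inv{158A>C}")
})

test_that("lenient operators canonicalize to > unless surface is preserved", {
  v <- hgvs_subst(hgvs_ptloc(274), "G", "T", operator = "arrow")
  expect_identical(hgvs_serialize(v), "274G>T")
  expect_identical(hgvs_serialize(v, preserve_surface = TRUE), "274G->T")
})

test_that("stop codons canonicalize to Ter unless surface is preserved", {
  v <- hgvs_parse_protein("p.Ser124*")$ast
  expect_identical(hgvs_serialize(v), "p.Ser124Ter")
  expect_identical(hgvs_serialize(v, preserve_surface = TRUE), "p.Ser124*")
})

test_that("constructors and serializers reject invariant violations by field", {
  expect_error(hgvs_refseq("genbank"), "accession")
  expect_error(hgvs_refseq("gene", gene_symbol = "DMD",
                           transcript_variant = 2, protein_isoform = 1),
               "transcript_variant")
  expect_error(hgvs_ptloc(NA, offset = hgvs_offset("+", magnitude = 5)),
               "offset")
  expect_error(hgvs_offset("x"), "sign")
  expect_error(hgvs_ins(hgvs_loc_point(hgvs_ptloc(1)),
                        hgvs_insertion("seq", "AC")),
               "loc")
  expect_error(hgvs_variant_list(list()), "items")
  expect_error(hgvs_variant_list(list(hgvs_no_change()), separators = ";"),
               "separators")
  expect_error(hgvs_multi_allele(list(hgvs_variant_list(list(
    hgvs_no_change())))), "sets")
  expect_error(hgvs_protein_variant("fs",
                                    loc = hgvs_aa_loc(hgvs_aa("Arg"), 97),
                                    new_stop = list(surface = "Ter",
                                                    count = 26)),
               "new_stop")
  # a hand-broken record is caught at serialization time, naming the field
  g <- hgvs_genotype(hgvs_subst(hgvs_ptloc(1), "A", "C"), system = "c")
  g$system <- "z"
  expect_error(hgvs_serialize(g), "system")
})

test_that("structured export is lossless with stable keys", {
  p <- hgvs_parse_genotype("274G>T")
  s <- hgvs_to_structured(p)
  expect_identical(s$rule, "Var")
  subst <- s$children[[1]]$children[[1]]
  expect_identical(subst$rule, "Subst")
  expect_identical(vapply(subst$children, `[[`, character(1), "rule"),
                   c("PtLoc", "Nt", "SubstOp", "Nt"))
  leaf <- subst$children[[2]]
  expect_identical(names(leaf), c("rule", "span", "text"))
  expect_identical(leaf$span, c(3L, 4L))
  expect_identical(leaf$text, "G")
  # JSON rendering keeps spans as arrays
  j <- jsonlite::fromJSON(hgvs_tree_json(p), simplifyVector = FALSE)
  expect_identical(j$rule, "Var")
  expect_length(j$children[[1]]$children[[1]]$children, 4L)
})

test_that("mosaic separator is recorded for bracketed allele sets", {
  p <- hgvs_parse_genotype("c.[=/85C>T]")
  expect_identical(p$ast$form, "single_allele_set")
  expect_identical(p$ast$body$separators, "/")
  body_node <- p$tree$children[[1]]
  expect_identical(body_node$rule, "SingleAlleleVars")
})

test_that("leaf spans concatenate to the consumed input", {
  for (s in dna_corpus()) {
    expect_identical(tree_leaf_text <- hgvsparser:::tree_leaf_text(
      hgvs_parse_genotype(s)), s)
  }
  for (s in protein_corpus()) {
    expect_identical(hgvsparser:::tree_leaf_text(hgvs_parse_protein(s)), s)
  }
})

test_that("structural equality is surface-faithful unless normalized", {
  a <- hgvs_parse_protein("p.Ser124Arg")$ast
  b <- hgvs_parse_protein("p.S124R")$ast
  expect_false(hgvs_equal(a, b))
  expect_true(hgvs_equal(a, b, normalize = TRUE))
  expect_true(hgvs_equal(a, hgvs_parse_protein("p.Ser124Arg")$ast))
})

test_that("example corpus round-trips through serialize exactly", {
  for (s in dna_corpus()) expect_surface_roundtrip(s, "dna_rna")
  for (s in protein_corpus()) expect_surface_roundtrip(s, "protein")
  for (s in reference_corpus()) {
    expect_identical(hgvs_serialize(hgvs_parse_reference(s)), s)
  }
})
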
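# Shared helpers for the suite.

dna_corpus <- function() {
  ex <- hgvs_examples()
  ex$description[ex$level == "dna_rna"]
}

protein_corpus <- function() {
  ex <- hgvs_examples()
  ex$description[ex$level == "protein"]
}

reference_corpus <- function() {
  ex <- hgvs_examples()
  ex$description[ex$level == "reference"]
}

parse_any <- function(s, level, dialect = "strict", tree = TRUE) {
  if (level == "protein") {
    hgvs_parse_protein(s, dialect, tree = tree)
  } else {
    hgvs_parse_genotype(s, dialect, tree = tree)
  }
}

expect_surface_roundtrip <- function(s, level, dialect = "strict") {
  p <- parse_any(s, level, dialect, tree = FALSE)
  expect_identical(hgvs_serialize(p$ast, preserve_surface = TRUE), s)
}

# fixed-seed random byte strings (printable and control ASCII) for fuzzing
fuzz_strings <- function(n, max_len = 64, seed = 20260928) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      len <- sample.int(max_len + 1L, 1L) - 1L
      if (!len) return("")
      rawToChar(as.raw(sample(1:126, len, replace = TRUE)))
    }, character(1))
  })
}
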
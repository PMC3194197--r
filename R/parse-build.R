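# Unvalidated record builders for the parser's hot path.
#
# These produce records field-for-field identical to the exported,
# validating constructors in ast.R / ast-protein.R; the parser may skip
# validation because every value it passes was just proven well-formed by
# the grammar rules that matched it. The structural round-trip tests
# (generator-built records, validating constructors, compared with
# `identical()` against parser output) pin the two construction routes
# together.

fast_class <- function(x, cls) {
  class(x) <- cls
  x
}

b_offset <- function(sign, beyond, magnitude) {
  fast_class(list(sign = sign, beyond = beyond, magnitude = magnitude),
             "hgvs_offset")
}

b_ptloc <- function(base, region, offset) {
  fast_class(list(region = region, base = base, offset = offset, ivs = NULL),
             "hgvs_ptloc")
}

b_ptloc_ivs <- function(intron, sign, distance) {
  fast_class(list(region = "body", base = NA_integer_, offset = NULL,
                  ivs = list(intron = intron, sign = sign,
                             distance = distance)),
             "hgvs_ptloc")
}

b_loc_point <- function(point) {
  fast_class(list(type = "point", point = point), "hgvs_loc")
}

b_loc_range <- function(start, end) {
  fast_class(list(type = "range", start = start, end = end), "hgvs_loc")
}

b_loc_exon <- function(first, last) {
  fast_class(list(type = "exon", first = first, last = last), "hgvs_loc")
}

b_refseq <- function(kind, accession = NA_character_, version = NA_integer_,
                     gene_symbol = NA_character_,
                     transcript_variant = NA_integer_,
                     protein_isoform = NA_integer_, lrg_id = NA_integer_,
                     lrg_transcript = NA_integer_,
                     lrg_protein = NA_integer_) {
  fast_class(list(kind = kind, accession = accession, version = version,
                  gene_symbol = gene_symbol,
                  transcript_variant = transcript_variant,
                  protein_isoform = protein_isoform, lrg_id = lrg_id,
                  lrg_transcript = lrg_transcript,
                  lrg_protein = lrg_protein),
             "hgvs_refseq")
}

b_farloc <- function(ref, system, extent) {
  fast_class(list(ref = ref, system = system, extent = extent),
             "hgvs_farloc")
}

b_insertion <- function(kind, value) {
  fast_class(list(kind = kind, value = value), "hgvs_insertion")
}

b_vlist <- function(items, separators) {
  fast_class(list(items = items, separators = separators),
             "hgvs_variant_list")
}

b_aaloc <- function(aa, position) {
  fast_class(list(aa = aa, position = position), "hgvs_aa_loc")
}

b_aarange <- function(start, end) {
  fast_class(list(start = start, end = end), "hgvs_aa_range")
}

# Every amino-acid surface token maps to a fixed record; build them once.
AA_CACHE <- local({
  cache <- new.env(parent = emptyenv())
  for (tok in c(AA_TABLE$code3, AA_STOP3)) {
    assign(tok, hgvs_aa(tok), envir = cache)
  }
  for (tok in c(AA_TABLE$code1, AA_STOP1)) {
    assign(tok, hgvs_aa(tok), envir = cache)
  }
  cache
})

b_aa <- function(token) get(token, envir = AA_CACHE)
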
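# Bundled example corpus.

#' Example corpus of variant descriptions
#'
#' A small fixed corpus spanning the grammar's feature set: the canonical
#' full/coordinate-prefixed/bare substitution forms, a nested sub-allele
#' inside an inversion, a deletion-insertion taking its inserted material
#' from another reference sequence, mosaic (`/`), chimeric (`//`) and
#' exclusive-or (`^`) allele sets, upstream/downstream (`u`/`d`) offsets,
#' non-coding (`n.`) positions, protein substitution and deletion in both
#' entry forms, and LRG transcript/protein reference tokens. Every row
#' parses at the stated level in the strict dialect; rows with level
#' `"reference"` are reference tokens for [hgvs_parse_reference()].
#'
#' @return A tibble with columns `description` and `level`.
#' @examples
#' hgvs_examples()
#' @export
hgvs_examples <- function() {
  tibble::tibble(
    description = c(
      "NM_003002.2:c.274G>T",
      "c.274G>T",
      "274G>T",
      "g.100_200inv{158A>C}",
      "g.100_200delinsAB23456.7",
      "g.[158A>C/124C>T]",
      "c.*405+d256G>T",
      "n.46G>T",
      "c.-110-u256G>T",
      "c.[370A>C^372C>R]",
      "c.[=/85C>T]",
      "c.[=//85C>T]",
      "c.24_65inv{46G>T}",
      "p.Ser124Arg",
      "Gly123del",
      "LRG_1t1",
      "LRG_1p1"),
    level = c(rep("dna_rna", 13), rep("protein", 2), rep("reference", 2))
  )
}
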
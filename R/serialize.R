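# Canonical serialization of AST records back to description strings.
#
# Each method first re-runs its constructor on the record's own fields, so
# a hand-edited record that violates an invariant fails with an error
# naming the offending field instead of producing unparseable text.

#' Serialize an AST record to its description string
#'
#' The inverse of parsing. By default the canonical surface form of the
#' strict grammar is produced: lenient-only substitution operators (`/`,
#' `->`, `-->`) serialize as `>`, and stop codons serialize as `Ter`. With
#' `preserve_surface = TRUE` the recorded surface forms are kept, so that
#' `parse(serialize(x))` reproduces `x` field-for-field. Structural legacy
#' forms (IVS/EX locations, `+` separators) always serialize as themselves:
#' rewriting them into strict coordinates would need a reference sequence,
#' which is semantics, not syntax.
#'
#' @param x A genotype, protein variant, raw variant, location, reference
#'   or other AST record from this package.
#' @param preserve_surface Keep lenient operators and one-letter stop
#'   surfaces instead of canonicalizing them.
#' @param ... Passed between methods.
#' @return A single character string accepted by the corresponding parser.
#' @examples
#' g <- hgvs_genotype(hgvs_subst(hgvs_ptloc(274), "G", "T"),
#'                    ref = hgvs_refseq("genbank", "NM_003002", 2),
#'                    system = "c")
#' hgvs_serialize(g)
#' @export
hgvs_serialize <- function(x, preserve_surface = FALSE, ...) {
  UseMethod("hgvs_serialize")
}

#' @export
hgvs_serialize.default <- function(x, preserve_surface = FALSE, ...) {
  stop("don't know how to serialize an object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

num_chr <- function(x) {
  if (is.na(x)) {
    "?"
  } else if (is.double(x)) {
    format(x, scientific = FALSE)  # positions beyond integer range
  } else {
    as.character(x)
  }
}

#' @export
hgvs_serialize.hgvs_refseq <- function(x, preserve_surface = FALSE, ...) {
  x <- hgvs_refseq(x$kind, x$accession, x$version, x$gene_symbol,
                   x$transcript_variant, x$protein_isoform, x$lrg_id,
                   x$lrg_transcript, x$lrg_protein)
  gene_part <- function() {
    out <- x$gene_symbol
    if (!is.na(x$transcript_variant)) {
      out <- paste0(out, "_v", x$transcript_variant)
    } else if (!is.na(x$protein_isoform)) {
      out <- paste0(out, "_i", x$protein_isoform)
    }
    out
  }
  switch(x$kind,
    none = "",
    gene = gene_part(),
    lrg = paste0("LRG_", x$lrg_id,
                 if (!is.na(x$lrg_transcript)) paste0("t", x$lrg_transcript)
                 else if (!is.na(x$lrg_protein)) paste0("p", x$lrg_protein)
                 else ""),
    genbank = paste0(x$accession,
                     if (!is.na(x$version)) paste0(".", x$version) else "",
                     if (!is.na(x$gene_symbol)) paste0("(", gene_part(), ")")
                     else ""))
}

#' @export
hgvs_serialize.hgvs_offset <- function(x, preserve_surface = FALSE, ...) {
  x <- hgvs_offset(x$sign, x$beyond, x$magnitude)
  paste0(x$sign, if (x$beyond != "none") x$beyond else "",
         num_chr(x$magnitude))
}

#' @export
hgvs_serialize.hgvs_ptloc <- function(x, preserve_surface = FALSE, ...) {
  if (!is.null(x$ivs)) {
    x <- hgvs_ptloc(ivs = x$ivs)
    return(paste0("IVS", x$ivs$intron, x$ivs$sign, x$ivs$distance))
  }
  x <- hgvs_ptloc(x$base, x$region, x$offset)
  paste0(switch(x$region, body = "", five_utr = "-", three_utr = "*"),
         num_chr(x$base),
         if (!is.null(x$offset)) hgvs_serialize(x$offset) else "")
}

#' @export
hgvs_serialize.hgvs_loc <- function(x, preserve_surface = FALSE, ...) {
  switch(x$type,
    point = hgvs_serialize(x$point, preserve_surface),
    range = paste0(hgvs_serialize(x$start, preserve_surface), "_",
                   hgvs_serialize(x$end, preserve_surface)),
    exon = paste0("EX", x$first,
                  if (!is.na(x$last)) paste0("-", x$last) else ""),
    stop("invariant violation in field `type`: unknown location type",
         call. = FALSE))
}

#' @export
hgvs_serialize.hgvs_farloc <- function(x, preserve_surface = FALSE, ...) {
  x <- hgvs_farloc(x$ref, x$system, x$extent)
  paste0(hgvs_serialize(x$ref),
         if (!is.null(x$extent)) {
           paste0(":",
                  if (!is.na(x$system)) paste0(x$system, ".") else "",
                  hgvs_serialize(x$extent, preserve_surface))
         } else "")
}

ser_removed <- function(removed) {
  if (is.null(removed)) "" else as.character(removed)
}

ser_nest <- function(nest, preserve_surface) {
  if (is.null(nest)) return("")
  paste0("{", hgvs_serialize(nest, preserve_surface), "}")
}

#' @export
hgvs_serialize.hgvs_insertion <- function(x, preserve_surface = FALSE, ...) {
  x <- hgvs_insertion(x$kind, x$value)
  switch(x$kind,
    seq = x$value,
    length = as.character(x$value),
    range = , farloc = hgvs_serialize(x$value, preserve_surface))
}

#' @export
hgvs_serialize.hgvs_raw_variant <- function(x, preserve_surface = FALSE, ...) {
  ps <- preserve_surface
  switch(x$type,
    subst = {
      x <- hgvs_subst(x$loc, x$from, x$to, x$operator)
      op <- if (ps) SUBST_OPERATORS[[x$operator]] else ">"
      paste0(hgvs_serialize(x$loc, ps), x$from, op, x$to)
    },
    del = {
      x <- hgvs_del(x$loc, x$removed)
      paste0(hgvs_serialize(x$loc, ps), "del", ser_removed(x$removed))
    },
    dup = {
      x <- hgvs_dup(x$loc, x$seq, x$nest)
      paste0(hgvs_serialize(x$loc, ps), "dup", ser_removed(x$seq),
             ser_nest(x$nest, ps))
    },
    ins = {
      x <- hgvs_ins(x$loc, x$inserted, x$nest)
      paste0(hgvs_serialize(x$loc, ps), "ins", hgvs_serialize(x$inserted, ps),
             ser_nest(x$nest, ps))
    },
    delins = {
      x <- hgvs_delins(x$loc, x$inserted, x$removed)
      paste0(hgvs_serialize(x$loc, ps), "del", ser_removed(x$removed), "ins",
             hgvs_serialize(x$inserted, ps))
    },
    inv = {
      x <- hgvs_inv(x$loc, x$seq, x$nest)
      paste0(hgvs_serialize(x$loc, ps), "inv", ser_removed(x$seq),
             ser_nest(x$nest, ps))
    },
    conv = {
      x <- hgvs_conv(x$loc, x$origin, x$nest)
      paste0(hgvs_serialize(x$loc, ps), "con", hgvs_serialize(x$origin, ps),
             ser_nest(x$nest, ps))
    },
    no_change = "=",
    unknown = "?",
    stop("invariant violation in field `type`: unknown variant type",
         call. = FALSE))
}

#' @export
hgvs_serialize.hgvs_variant_list <- function(x, preserve_surface = FALSE, ...) {
  x <- hgvs_variant_list(x$items, x$separators)
  parts <- vapply(x$items, hgvs_serialize, character(1),
                  preserve_surface = preserve_surface)
  out <- parts[[1]]
  for (i in seq_along(x$separators)) {
    out <- paste0(out, x$separators[[i]], parts[[i + 1L]])
  }
  out
}

#' @export
hgvs_serialize.hgvs_genotype <- function(x, preserve_surface = FALSE, ...) {
  x <- hgvs_genotype(x$body, x$ref, x$system)
  ps <- preserve_surface
  head <- paste0(
    if (x$ref$kind != "none") paste0(hgvs_serialize(x$ref), ":") else "",
    if (!is.na(x$system)) paste0(x$system, ".") else "")
  body <- switch(x$form,
    single = hgvs_serialize(x$body, ps),
    single_allele_set = paste0("[", hgvs_serialize(x$body, ps), "]"),
    multi_allele = {
      sep <- if (x$body$phase == "certain") ";" else "(;)"
      paste(vapply(x$body$sets, function(s) {
        paste0("[", hgvs_serialize(s, ps), "]")
      }, character(1)), collapse = sep)
    },
    multi_transcript = paste0("[", paste(
      vapply(x$body$lists, hgvs_serialize, character(1),
             preserve_surface = ps), collapse = ","), "]"))
  paste0(head, body)
}

ser_aa <- function(aa, preserve_surface) {
  if (aa$code3 == AA_STOP3 && !preserve_surface) return(AA_STOP3)
  if (aa$style == "three_letter") aa$code3 else aa$code1
}

#' @export
hgvs_serialize.hgvs_aa <- function(x, preserve_surface = FALSE, ...) {
  x <- hgvs_aa(if (x$style == "three_letter") x$code3 else x$code1, x$style)
  ser_aa(x, preserve_surface)
}

#' @export
hgvs_serialize.hgvs_aa_loc <- function(x, preserve_surface = FALSE, ...) {
  x <- hgvs_aa_loc(x$aa, x$position)
  paste0(ser_aa(x$aa, preserve_surface), x$position)
}

#' @export
hgvs_serialize.hgvs_aa_range <- function(x, preserve_surface = FALSE, ...) {
  x <- hgvs_aa_range(x$start, x$end)
  paste0(hgvs_serialize(x$start, preserve_surface), "_",
         hgvs_serialize(x$end, preserve_surface))
}

ser_aaseq <- function(seq, preserve_surface) {
  paste(vapply(seq, ser_aa, character(1), preserve_surface = preserve_surface),
        collapse = "")
}

#' @export
hgvs_serialize.hgvs_protein_variant <- function(x, preserve_surface = FALSE,
                                                ...) {
  x <- hgvs_protein_variant(x$type, x$loc, x$to, x$inserted, x$first_new,
                            x$new_stop, x$ref, x$prefixed, x$predicted)
  ps <- preserve_surface
  body <- switch(x$type,
    subst = paste0(hgvs_serialize(x$loc, ps), ser_aa(x$to, ps)),
    del = paste0(hgvs_serialize(x$loc, ps), "del"),
    dup = paste0(hgvs_serialize(x$loc, ps), "dup"),
    ins = paste0(hgvs_serialize(x$loc, ps), "ins",
                 if (x$inserted$kind == "seq") ser_aaseq(x$inserted$value, ps)
                 else as.character(x$inserted$value)),
    delins = paste0(hgvs_serialize(x$loc, ps), "delins",
                    ser_aaseq(x$inserted$value, ps)),
    fs = paste0(hgvs_serialize(x$loc, ps),
                if (!is.null(x$first_new)) ser_aa(x$first_new, ps) else "",
                "fs",
                if (!is.null(x$new_stop)) {
                  paste0(if (ps) x$new_stop$surface else AA_STOP3,
                         num_chr(x$new_stop$count))
                } else ""),
    no_change = "=",
    unknown = "?",
    no_protein = "0")
  if (x$predicted) body <- paste0("(", body, ")")
  paste0(
    if (x$ref$kind != "none") paste0(hgvs_serialize(x$ref), ":") else "",
    if (x$prefixed) "p." else "",
    body)
}

#' @export
format.hgvs_genotype <- function(x, ...) hgvs_serialize(x, ...)

#' @export
format.hgvs_protein_variant <- function(x, ...) hgvs_serialize(x, ...)

#' @export
print.hgvs_genotype <- function(x, ...) {
  cat("<hgvs_genotype> ", hgvs_serialize(x, preserve_surface = TRUE),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.hgvs_protein_variant <- function(x, ...) {
  cat("<hgvs_protein_variant> ", hgvs_serialize(x, preserve_surface = TRUE),
      "\n", sep = "")
  invisible(x)
}
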
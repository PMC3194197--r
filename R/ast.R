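# Typed abstract-syntax-tree records for both nomenclature levels.
#
# All records are plain S3 lists with a fixed field layout so that
# structural equality is `identical()` on the records the parser and the
# generator build through the same constructors. Scalar "absent" is NA of
# the right type; absent sub-objects are NULL.

stop_field <- function(field, msg) {
  stop(sprintf("invariant violation in field `%s`: %s", field, msg),
       call. = FALSE)
}

int_or_na <- function(x, field, allow_na = TRUE, positive = TRUE) {
  if (is.integer(x) && length(x) == 1L) {  # fast path: parser-made values
    if (is.na(x)) {
      if (!allow_na) stop_field(field, "must not be missing")
      return(x)
    }
    if (positive && x < 1L) stop_field(field, "must be a positive integer")
    return(x)
  }
  if (length(x) != 1L) stop_field(field, "must be a single value")
  if (is.na(x)) {
    if (!allow_na) stop_field(field, "must not be missing")
    return(NA_integer_)
  }
  if (is.double(x) && x > .Machine$integer.max) {
    # positions beyond integer range are kept as doubles
    if (positive && x < 1) stop_field(field, "must be a positive integer")
    return(x)
  }
  xi <- suppressWarnings(as.integer(x))
  if (is.na(xi) || (positive && xi < 1L)) {
    stop_field(field, "must be a positive integer")
  }
  xi
}

#' Reference-sequence identifier record
#'
#' Represents the part of a variant description before the `:` — a GenBank
#' accession with optional version (`NM_003002.2`), a gene symbol with
#' optional `_v`/`_i` transcript/isoform suffix (`DMD_v2`), or an LRG
#' identifier with optional `t`/`p` transcript/protein suffix (`LRG_1t1`).
#' `kind = "none"` records that the description carried no reference part.
#'
#' @param kind One of `"genbank"`, `"gene"`, `"lrg"`, `"none"`.
#' @param accession Accession text (GenBank kind), e.g. `"NM_003002"`.
#' @param version Positive integer version or `NA`.
#' @param gene_symbol Gene symbol text or `NA`.
#' @param transcript_variant Positive integer from a `_v` suffix or `NA`.
#' @param protein_isoform Positive integer from an `_i` suffix or `NA`.
#' @param lrg_id,lrg_transcript,lrg_protein LRG numbers or `NA`.
#' @return An object of class `hgvs_refseq`.
#' @examples
#' hgvs_refseq("genbank", accession = "NM_003002", version = 2)
#' hgvs_refseq("lrg", lrg_id = 1, lrg_transcript = 1)
#' @export
hgvs_refseq <- function(kind = "none", accession = NA_character_,
                        version = NA_integer_, gene_symbol = NA_character_,
                        transcript_variant = NA_integer_,
                        protein_isoform = NA_integer_,
                        lrg_id = NA_integer_, lrg_transcript = NA_integer_,
                        lrg_protein = NA_integer_) {
  kind <- match_arg2(kind, c("genbank", "gene", "lrg", "none"), "kind")
  x <- structure(list(
    kind = kind,
    accession = as.character(accession),
    version = int_or_na(version, "version"),
    gene_symbol = as.character(gene_symbol),
    transcript_variant = int_or_na(transcript_variant, "transcript_variant"),
    protein_isoform = int_or_na(protein_isoform, "protein_isoform"),
    lrg_id = int_or_na(lrg_id, "lrg_id"),
    lrg_transcript = int_or_na(lrg_transcript, "lrg_transcript"),
    lrg_protein = int_or_na(lrg_protein, "lrg_protein")
  ), class = "hgvs_refseq")
  if (kind != "lrg" &&
      (!is.na(x$lrg_id) || !is.na(x$lrg_transcript) || !is.na(x$lrg_protein))) {
    stop_field("lrg_id", "LRG fields may be set only when kind = \"lrg\"")
  }
  if (kind == "lrg" && is.na(x$lrg_id)) {
    stop_field("lrg_id", "required when kind = \"lrg\"")
  }
  if (!is.na(x$transcript_variant) && !is.na(x$protein_isoform)) {
    stop_field("transcript_variant",
               "at most one of transcript_variant/protein_isoform may be set")
  }
  if (!is.na(x$lrg_transcript) && !is.na(x$lrg_protein)) {
    stop_field("lrg_transcript",
               "at most one of lrg_transcript/lrg_protein may be set")
  }
  if (kind == "genbank" && is.na(x$accession)) {
    stop_field("accession", "required when kind = \"genbank\"")
  }
  if (kind == "gene" && is.na(x$gene_symbol)) {
    stop_field("gene_symbol", "required when kind = \"gene\"")
  }
  x
}

#' Position offset record
#'
#' The `+N` / `-N` part of a point location, optionally carrying the `u`
#' (upstream of transcript start) or `d` (downstream of transcript end)
#' marker, e.g. the `+d256` in `c.*405+d256G>T`. An `NA` magnitude renders
#' as the unknown marker `?`.
#'
#' @param sign `"+"` or `"-"`.
#' @param beyond `"none"`, `"u"` or `"d"`.
#' @param magnitude Positive integer or `NA` (unknown).
#' @return An object of class `hgvs_offset`.
#' @export
hgvs_offset <- function(sign, beyond = "none", magnitude = NA_integer_) {
  sign <- match_arg2(sign, c("+", "-"), "sign")
  beyond <- match_arg2(beyond, c("none", "u", "d"), "beyond")
  out <- list(sign = sign, beyond = beyond,
              magnitude = int_or_na(magnitude, "magnitude"))
  class(out) <- "hgvs_offset"
  out
}

#' Point-location record
#'
#' One coordinate at the DNA/RNA level: an optional UTR region marker (`-`
#' for 5' UTR, `*` for 3' UTR), a base number (or `?`), and an optional
#' offset. A legacy `IVS` intron position (`IVS4+1`) is stored in `ivs`,
#' mutually exclusive with all other fields.
#'
#' @param base Positive integer or `NA` for the unknown marker `?`.
#' @param region `"body"`, `"five_utr"` or `"three_utr"`.
#' @param offset An [hgvs_offset()] or `NULL`.
#' @param ivs `NULL`, or `list(intron =, sign =, distance =)` for legacy
#'   intervening-sequence positions.
#' @return An object of class `hgvs_ptloc`.
#' @examples
#' hgvs_ptloc(405, region = "three_utr",
#'            offset = hgvs_offset("+", "d", 256))
#' @export
hgvs_ptloc <- function(base = NA_integer_, region = "body", offset = NULL,
                       ivs = NULL) {
  if (!is.null(ivs)) {
    if (region != "body" || !is.na(base) || !is.null(offset)) {
      stop_field("ivs", "legacy IVS location excludes all other fields")
    }
    ivs <- list(intron = int_or_na(ivs$intron, "ivs$intron", allow_na = FALSE),
                sign = match_arg2(ivs$sign, c("+", "-"), "ivs$sign"),
                distance = int_or_na(ivs$distance, "ivs$distance",
                                     allow_na = FALSE))
    out <- list(region = "body", base = NA_integer_, offset = NULL,
                ivs = ivs)
    class(out) <- "hgvs_ptloc"
    return(out)
  }
  region <- match_arg2(region, c("body", "five_utr", "three_utr"), "region")
  base <- int_or_na(base, "base")
  if (is.na(base) && !is.null(offset)) {
    stop_field("offset", "unknown base excludes an offset")
  }
  if (!is.null(offset) && !inherits(offset, "hgvs_offset")) {
    stop_field("offset", "must be an hgvs_offset or NULL")
  }
  out <- list(region = region, base = base, offset = offset, ivs = NULL)
  class(out) <- "hgvs_ptloc"
  out
}

#' Location records: point, range, legacy exon
#'
#' A location is either a single point, an underscore-separated range
#' (`100_200`), or a legacy `EX` exon reference (`EX5`, `EX5-7`). Range
#' order (start before end) is deliberately not checked: that is a semantic
#' rule, outside the syntax layer.
#'
#' @param point An [hgvs_ptloc()].
#' @param start,end [hgvs_ptloc()] range endpoints.
#' @param first,last Exon numbers (`last` may be `NA`).
#' @return An object of class `hgvs_loc`.
#' @name hgvs_loc
NULL

#' @rdname hgvs_loc
#' @export
hgvs_loc_point <- function(point) {
  if (!inherits(point, "hgvs_ptloc")) stop_field("point", "must be an hgvs_ptloc")
  out <- list(type = "point", point = point)
  class(out) <- "hgvs_loc"
  out
}

#' @rdname hgvs_loc
#' @export
hgvs_loc_range <- function(start, end) {
  if (!inherits(start, "hgvs_ptloc")) stop_field("start", "must be an hgvs_ptloc")
  if (!inherits(end, "hgvs_ptloc")) stop_field("end", "must be an hgvs_ptloc")
  out <- list(type = "range", start = start, end = end)
  class(out) <- "hgvs_loc"
  out
}

#' @rdname hgvs_loc
#' @export
hgvs_loc_exon <- function(first, last = NA_integer_) {
  structure(list(type = "exon",
                 first = int_or_na(first, "first", allow_na = FALSE),
                 last = int_or_na(last, "last")),
            class = "hgvs_loc")
}

#' Far-location record
#'
#' A location on another reference sequence, used as the inserted material
#' of deletion-insertions (`g.100_200delinsAB23456.7`) and as the origin of
#' gene conversions. Holds a reference, an optional coordinate system, and
#' an optional extent.
#'
#' @param ref An [hgvs_refseq()] with `kind != "none"`.
#' @param system Coordinate-system letter or `NA`.
#' @param extent An [hgvs_loc] or `NULL`.
#' @return An object of class `hgvs_farloc`.
#' @export
hgvs_farloc <- function(ref, system = NA_character_, extent = NULL) {
  if (!inherits(ref, "hgvs_refseq") || ref$kind == "none") {
    stop_field("ref", "must be an hgvs_refseq with kind != \"none\"")
  }
  if (!is.na(system)) system <- match_arg2(system, COORD_SYSTEMS, "system")
  if (!is.null(extent) && !inherits(extent, "hgvs_loc")) {
    stop_field("extent", "must be an hgvs_loc or NULL")
  }
  if (is.null(extent) && !is.na(system)) {
    stop_field("system", "a coordinate system requires an extent")
  }
  structure(list(ref = ref, system = as.character(system), extent = extent),
            class = "hgvs_farloc")
}

#' Inserted-material record
#'
#' The target of an insertion or deletion-insertion: a literal nucleotide
#' string, a bare length, a range on the same sequence, or a far location
#' on another reference.
#'
#' @param kind One of `"seq"`, `"length"`, `"range"`, `"farloc"`.
#' @param value The sequence text, integer length, [hgvs_loc] range, or
#'   [hgvs_farloc()].
#' @return An object of class `hgvs_insertion`.
#' @export
hgvs_insertion <- function(kind, value) {
  kind <- match_arg2(kind, c("seq", "length", "range", "farloc"), "kind")
  value <- switch(kind,
    seq = {
      if (!is.character(value) || length(value) != 1L || !nzchar(value) ||
          !all(strsplit(value, "", fixed = TRUE)[[1]] %in% IUPAC_NT)) {
        stop_field("value", "seq must be a non-empty IUPAC nucleotide string")
      }
      value
    },
    length = int_or_na(value, "value", allow_na = FALSE),
    range = {
      if (!inherits(value, "hgvs_loc") || value$type != "range") {
        stop_field("value", "range insertion requires a range hgvs_loc")
      }
      value
    },
    farloc = {
      if (!inherits(value, "hgvs_farloc")) {
        stop_field("value", "farloc insertion requires an hgvs_farloc")
      }
      value
    })
  structure(list(kind = kind, value = value), class = "hgvs_insertion")
}

check_removed <- function(removed) {
  if (is.null(removed)) return(NULL)
  if (is.character(removed)) {
    if (length(removed) != 1L || !nzchar(removed) ||
        !all(strsplit(removed, "", fixed = TRUE)[[1]] %in% IUPAC_NT)) {
      stop_field("removed", "must be a non-empty IUPAC nucleotide string")
    }
    return(removed)
  }
  int_or_na(removed, "removed", allow_na = FALSE)
}

check_nest <- function(nest) {
  if (is.null(nest)) return(NULL)
  if (!inherits(nest, "hgvs_variant_list")) {
    stop_field("nest", "must be an hgvs_variant_list or NULL")
  }
  nest
}

need_range <- function(loc, field) {
  if (!inherits(loc, "hgvs_loc") || loc$type != "range") {
    stop_field(field, "must be a range hgvs_loc")
  }
  loc
}

need_loc <- function(loc, field) {
  if (!inherits(loc, "hgvs_loc")) stop_field(field, "must be an hgvs_loc")
  loc
}

new_raw_variant <- function(type, fields) {
  out <- c(list(type = type), fields)
  class(out) <- "hgvs_raw_variant"
  out
}

#' Raw-variant records (DNA/RNA level)
#'
#' Constructors for the individual change classes: substitution, deletion,
#' duplication, insertion, deletion-insertion, inversion, gene conversion,
#' the no-change marker `=` and the unknown marker `?`. Nested sub-allele
#' lists (curly braces) are permitted on duplications, insertions,
#' inversions and conversions only.
#'
#' @param loc An [hgvs_loc] (or, for substitutions, an [hgvs_ptloc()]).
#' @param from,to Single IUPAC nucleotide letters.
#' @param operator Substitution operator: `"gt"` (`>`), or the lenient
#'   text-mining forms `"slash"`, `"arrow"`, `"long_arrow"`.
#' @param removed,seq Removed/affected sequence: nucleotide string, integer
#'   length, or `NULL`.
#' @param inserted An [hgvs_insertion()].
#' @param origin An [hgvs_farloc()] (conversion origin).
#' @param nest An [hgvs_variant_list()] of sub-allele changes or `NULL`.
#' @return An object of class `hgvs_raw_variant`.
#' @examples
#' hgvs_subst(hgvs_ptloc(274), "G", "T")
#' @name hgvs_raw_variant
NULL

check_nt <- function(x, field) {
  if (!is.character(x) || length(x) != 1L || nchar(x) != 1L ||
      !x %in% IUPAC_NT) {
    stop_field(field, "must be a single IUPAC nucleotide letter")
  }
  x
}

#' @rdname hgvs_raw_variant
#' @export
hgvs_subst <- function(loc, from, to, operator = "gt") {
  if (!inherits(loc, "hgvs_ptloc")) stop_field("loc", "must be an hgvs_ptloc")
  operator <- match_arg2(operator, names(SUBST_OPERATORS), "operator")
  new_raw_variant("subst", list(loc = loc,
                                from = check_nt(from, "from"),
                                to = check_nt(to, "to"),
                                operator = operator))
}

#' @rdname hgvs_raw_variant
#' @export
hgvs_del <- function(loc, removed = NULL) {
  new_raw_variant("del", list(loc = need_loc(loc, "loc"),
                              removed = check_removed(removed)))
}

#' @rdname hgvs_raw_variant
#' @export
hgvs_dup <- function(loc, seq = NULL, nest = NULL) {
  new_raw_variant("dup", list(loc = need_loc(loc, "loc"),
                              seq = check_removed(seq),
                              nest = check_nest(nest)))
}

#' @rdname hgvs_raw_variant
#' @export
hgvs_ins <- function(loc, inserted, nest = NULL) {
  if (!inherits(inserted, "hgvs_insertion")) {
    stop_field("inserted", "must be an hgvs_insertion")
  }
  new_raw_variant("ins", list(loc = need_range(loc, "loc"),
                              inserted = inserted, nest = check_nest(nest)))
}

#' @rdname hgvs_raw_variant
#' @export
hgvs_delins <- function(loc, inserted, removed = NULL) {
  if (!inherits(inserted, "hgvs_insertion")) {
    stop_field("inserted", "must be an hgvs_insertion")
  }
  new_raw_variant("delins", list(loc = need_loc(loc, "loc"),
                                 removed = check_removed(removed),
                                 inserted = inserted))
}

#' @rdname hgvs_raw_variant
#' @export
hgvs_inv <- function(loc, seq = NULL, nest = NULL) {
  new_raw_variant("inv", list(loc = need_range(loc, "loc"),
                              seq = check_removed(seq),
                              nest = check_nest(nest)))
}

#' @rdname hgvs_raw_variant
#' @export
hgvs_conv <- function(loc, origin, nest = NULL) {
  if (!inherits(origin, "hgvs_farloc")) {
    stop_field("origin", "must be an hgvs_farloc")
  }
  new_raw_variant("conv", list(loc = need_range(loc, "loc"), origin = origin,
                               nest = check_nest(nest)))
}

#' @rdname hgvs_raw_variant
#' @export
hgvs_no_change <- function() new_raw_variant("no_change", list())

#' @rdname hgvs_raw_variant
#' @export
hgvs_unknown <- function() new_raw_variant("unknown", list())

#' Ordered variant list with separators
#'
#' The content of a bracketed allele set: raw variants joined by `;`
#' (same allele), `/` (mosaic), `//` (chimeric), `^` (exclusive or) or the
#' legacy `+`.
#'
#' @param items List of [hgvs_raw_variant] records.
#' @param separators Character vector of separators, one fewer than items;
#'   each of `";"`, `"/"`, `"//"`, `"^"`, `"+"`.
#' @return An object of class `hgvs_variant_list`.
#' @export
hgvs_variant_list <- function(items, separators = character()) {
  if (!length(items)) stop_field("items", "must be non-empty")
  ok <- vapply(items, inherits, logical(1), "hgvs_raw_variant")
  if (!all(ok)) stop_field("items", "must all be hgvs_raw_variant records")
  separators <- as.character(separators)
  if (length(separators) != length(items) - 1L) {
    stop_field("separators", "length must equal length(items) - 1")
  }
  if (length(separators) && !all(separators %in% LIST_SEPARATORS)) {
    stop_field("separators", "unknown separator symbol")
  }
  structure(list(items = items, separators = separators),
            class = "hgvs_variant_list")
}

#' Genotype record (DNA/RNA level)
#'
#' A complete description at the DNA/RNA level: a reference part (possibly
#' absent), a coordinate-system letter (`NA` for bare descriptions such as
#' `274G>T`), and a body that is a single variant, one bracketed allele set,
#' several allele sets with certain (`;`) or uncertain (`(;)`) phase, or a
#' multi-transcript list (comma-separated inside one bracket pair).
#'
#' @param body The body record; its class decides the form. Use a raw
#'   variant for `single`, an [hgvs_variant_list()] for `single_allele_set`,
#'   `hgvs_multi_allele()` or `hgvs_multi_transcript()` otherwise.
#' @param ref An [hgvs_refseq()].
#' @param system Coordinate-system letter `c`, `g`, `m`, `n`, `r`, or `NA`
#'   for the bare description form.
#' @param sets List of [hgvs_variant_list()] (at least two).
#' @param phase `"certain"` (`;`) or `"uncertain"` (`(;)`).
#' @param lists List of [hgvs_variant_list()] (at least two).
#' @return An object of class `hgvs_genotype` (or the inner body records).
#' @examples
#' hgvs_genotype(hgvs_subst(hgvs_ptloc(274), "G", "T"),
#'               ref = hgvs_refseq("genbank", "NM_003002", 2), system = "c")
#' @export
hgvs_genotype <- function(body, ref = hgvs_refseq(), system = NA_character_) {
  if (!inherits(ref, "hgvs_refseq")) stop_field("ref", "must be an hgvs_refseq")
  if (!is.na(system)) system <- match_arg2(system, COORD_SYSTEMS, "system")
  form <- if (inherits(body, "hgvs_raw_variant")) {
    "single"
  } else if (inherits(body, "hgvs_variant_list")) {
    "single_allele_set"
  } else if (inherits(body, "hgvs_multi_allele")) {
    "multi_allele"
  } else if (inherits(body, "hgvs_multi_transcript")) {
    "multi_transcript"
  } else {
    stop_field("body", "unrecognized genotype body")
  }
  if (form != "single" && is.na(system)) {
    stop_field("system", "bracketed forms require a coordinate system")
  }
  if (form == "single" && body$type %in% c("no_change", "unknown")) {
    stop_field("body", "`=`/`?` occur only inside bracketed allele sets")
  }
  structure(list(ref = ref, system = as.character(system), form = form,
                 body = body), class = "hgvs_genotype")
}

#' @rdname hgvs_genotype
#' @export
hgvs_multi_allele <- function(sets, phase = "certain") {
  phase <- match_arg2(phase, c("certain", "uncertain"), "phase")
  if (length(sets) < 2L) stop_field("sets", "requires at least two allele sets")
  if (phase == "uncertain" && length(sets) != 2L) {
    stop_field("sets", "uncertain phase joins exactly two allele sets")
  }
  ok <- vapply(sets, inherits, logical(1), "hgvs_variant_list")
  if (!all(ok)) stop_field("sets", "must all be hgvs_variant_list records")
  structure(list(sets = sets, phase = phase), class = "hgvs_multi_allele")
}

#' @rdname hgvs_genotype
#' @export
hgvs_multi_transcript <- function(lists) {
  if (length(lists) < 2L) stop_field("lists", "requires at least two lists")
  ok <- vapply(lists, inherits, logical(1), "hgvs_variant_list")
  if (!all(ok)) stop_field("lists", "must all be hgvs_variant_list records")
  structure(list(lists = lists), class = "hgvs_multi_transcript")
}
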
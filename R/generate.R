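# Grammar-driven random description generation for fixtures and fuzzing.
#
# The sampler draws ASTs through the same constructors the parser uses,
# one sampling site per grammar production, with depth-weighted damping of
# the recursive alternatives (nested sub-alleles) so that every derivation
# terminates. Serializing with preserve_surface = TRUE turns the sampled
# AST into the corpus string; round-tripping the string through the
# parser must reproduce the AST exactly, which is the closure property
# the test-suite asserts.

#' Generator configuration
#'
#' @param seed Integer seed; identical configurations yield identical
#'   output.
#' @param count How many descriptions to generate (0 gives an empty
#'   corpus).
#' @param max_depth Recursion bound for nested sub-alleles and allele
#'   sets; must be at least 1.
#' @param level `"dna_rna"` or `"protein"`.
#' @param dialect `"strict"`, `"legacy"` or `"lenient"`; the legacy and
#'   lenient corpora exercise their extra productions (IVS/EX locations,
#'   `+` separators, alternative substitution operators).
#' @return An object of class `hgvs_generator_config`.
#' @examples
#' cfg <- hgvs_generator_config(seed = 42, count = 5)
#' hgvs_generate(cfg)
#' @export
hgvs_generator_config <- function(seed, count, max_depth = 6,
                                  level = "dna_rna", dialect = "strict") {
  level <- match_arg2(level, LEVELS, "level")
  dialect <- match_arg2(dialect, DIALECTS, "dialect")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("configuration error: `seed` must be a single integer",
         call. = FALSE)
  }
  if (!is.numeric(count) || length(count) != 1L || is.na(count) ||
      count < 0) {
    stop("configuration error: `count` must be a non-negative integer",
         call. = FALSE)
  }
  if (!is.numeric(max_depth) || length(max_depth) != 1L || max_depth < 1) {
    stop("configuration error: `max_depth` must be at least 1",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), count = as.integer(count),
                 max_depth = as.integer(max_depth), level = level,
                 dialect = dialect),
            class = "hgvs_generator_config")
}

# Fixed symbol pools keep generated corpora readable and seeds stable.
# Gene symbols are digit-free (a digit would classify them as accessions)
# and each contains at least one non-IUPAC letter: a symbol spelled only
# in IUPAC ambiguity letters (e.g. DMD) is indistinguishable from a
# nucleotide string as an insertion target, where the grammar prefers the
# sequence reading.
GEN_ACCESSIONS <- sprintf("AB%06d", 1:9)
GEN_GENES <- c("PAX", "MECP", "PSEN", "OPA", "FLI")

pick <- function(x, prob = NULL) {
  if (length(x) == 1L) return(x[[1L]])
  x[[sample.int(length(x), 1L, prob = prob)]]
}
rint <- function(max) sample.int(max, 1L)
chance <- function(p) runif(1L) < p

gen_refseq <- function(level) {
  kind <- pick(c("genbank", "gene", "lrg"), prob = c(0.55, 0.25, 0.20))
  switch(kind,
    genbank = hgvs_refseq(
      "genbank", accession = pick(GEN_ACCESSIONS),
      version = if (chance(0.8)) rint(9) else NA_integer_,
      gene_symbol = if (chance(0.15)) pick(GEN_GENES) else NA_character_),
    gene = {
      sym <- pick(GEN_GENES)
      if (chance(0.4)) {
        if (level == "protein" || chance(0.5)) {
          hgvs_refseq("gene", gene_symbol = sym, protein_isoform = rint(9))
        } else {
          hgvs_refseq("gene", gene_symbol = sym, transcript_variant = rint(9))
        }
      } else {
        hgvs_refseq("gene", gene_symbol = sym)
      }
    },
    lrg = {
      id <- rint(9)
      if (level == "protein") {
        if (chance(0.7)) hgvs_refseq("lrg", lrg_id = id, lrg_protein = rint(9))
        else hgvs_refseq("lrg", lrg_id = id)
      } else if (chance(0.6)) {
        hgvs_refseq("lrg", lrg_id = id, lrg_transcript = rint(9))
      } else {
        hgvs_refseq("lrg", lrg_id = id)
      }
    })
}

gen_offset <- function() {
  hgvs_offset(pick(c("+", "-")),
              beyond = pick(c("none", "u", "d"), prob = c(0.7, 0.15, 0.15)),
              magnitude = if (chance(0.9)) rint(9999) else NA_integer_)
}

gen_ptloc <- function(dialect) {
  if (dialect != "strict" && chance(0.15)) {
    return(hgvs_ptloc(ivs = list(intron = rint(50), sign = pick(c("+", "-")),
                                 distance = rint(200))))
  }
  if (chance(0.04)) {
    return(hgvs_ptloc(NA_integer_,
                      pick(c("body", "five_utr", "three_utr"),
                           prob = c(0.8, 0.1, 0.1))))
  }
  hgvs_ptloc(rint(9999),
             pick(c("body", "five_utr", "three_utr"),
                  prob = c(0.7, 0.15, 0.15)),
             offset = if (chance(0.3)) gen_offset() else NULL)
}

gen_range <- function(dialect) {
  hgvs_loc_range(gen_ptloc(dialect), gen_ptloc(dialect))
}

gen_loc <- function(dialect, range_prob = 0.5) {
  if (dialect != "strict" && chance(0.1)) {
    return(hgvs_loc_exon(rint(80),
                         if (chance(0.4)) rint(80) else NA_integer_))
  }
  if (chance(range_prob)) gen_range(dialect)
  else hgvs_loc_point(gen_ptloc(dialect))
}

gen_ntstring <- function(max_len = 6) {
  paste(sample(c("A", "C", "G", "T"), rint(max_len), replace = TRUE),
        collapse = "")
}

gen_removed <- function() {
  if (chance(0.7)) NULL
  else if (chance(0.5)) gen_ntstring()
  else rint(500)
}

gen_farloc <- function(dialect) {
  ref <- gen_refseq("dna_rna")
  if (chance(0.5)) {
    hgvs_farloc(ref,
                system = if (chance(0.5)) pick(COORD_SYSTEMS) else
                  NA_character_,
                extent = if (chance(0.6)) gen_range(dialect) else
                  hgvs_loc_point(gen_ptloc(dialect)))
  } else {
    hgvs_farloc(ref)
  }
}

gen_instarget <- function(dialect) {
  kind <- pick(c("seq", "length", "range", "farloc"),
               prob = c(0.5, 0.2, 0.15, 0.15))
  switch(kind,
    seq = hgvs_insertion("seq", gen_ntstring()),
    length = hgvs_insertion("length", rint(500)),
    range = hgvs_insertion("range", gen_range(dialect)),
    farloc = hgvs_insertion("farloc", gen_farloc(dialect)))
}

gen_nest <- function(depth, dialect) {
  # recursive alternative: probability halves per depth unit already spent
  if (depth <= 1L || !chance(0.25 * 2 ^ -(max(0L, 6L - depth)))) return(NULL)
  gen_varlist(depth - 1L, dialect, in_bracket = TRUE, max_items = 2L)
}

gen_rawvar <- function(depth, dialect, in_bracket) {
  type <- pick(c("subst", "del", "dup", "ins", "delins", "inv", "conv"),
               prob = c(0.32, 0.18, 0.12, 0.12, 0.10, 0.10, 0.06))
  switch(type,
    subst = {
      op <- if (dialect == "lenient" && !in_bracket && chance(0.3)) {
        pick(c("slash", "arrow", "long_arrow"))
      } else {
        "gt"
      }
      hgvs_subst(gen_ptloc(dialect), pick(IUPAC_NT_UPPER[1:4]),
                 pick(c(IUPAC_NT_UPPER[1:4], "R", "N")), operator = op)
    },
    del = hgvs_del(gen_loc(dialect), gen_removed()),
    dup = hgvs_dup(gen_loc(dialect), gen_removed(),
                   nest = gen_nest(depth, dialect)),
    ins = hgvs_ins(gen_range(dialect), gen_instarget(dialect),
                   nest = gen_nest(depth, dialect)),
    delins = hgvs_delins(gen_loc(dialect), gen_instarget(dialect),
                         removed = gen_removed()),
    inv = hgvs_inv(gen_range(dialect), gen_removed(),
                   nest = gen_nest(depth, dialect)),
    conv = hgvs_conv(gen_range(dialect), gen_farloc(dialect),
                     nest = gen_nest(depth, dialect)))
}

gen_varlist <- function(depth, dialect, in_bracket = TRUE, max_items = 4L) {
  n <- rint(max_items)
  items <- lapply(seq_len(n), function(i) {
    u <- runif(1L)
    if (u < 0.08) hgvs_no_change()
    else if (u < 0.14) hgvs_unknown()
    else gen_rawvar(depth, dialect, in_bracket)
  })
  seps <- if (n > 1L) {
    base <- c(";", "/", "//", "^")
    pb <- c(0.55, 0.15, 0.10, 0.20)
    if (dialect != "strict") {
      base <- c(base, "+")
      pb <- c(0.45, 0.15, 0.10, 0.15, 0.15)
    }
    vapply(seq_len(n - 1L), function(i) pick(base, prob = pb), character(1))
  } else {
    character()
  }
  # The legacy "+" separator is ambiguous when the left item ends in a
  # digit and the right one starts with a digit or "?": "…2498+282…"
  # reads as a position offset (one reason the nomenclature replaced "+"
  # with ";"). The parser resolves it greedily as an offset, so never
  # generate "+" at such a junction.
  if (any(seps == "+")) {
    txt <- vapply(items, hgvs_serialize, character(1),
                  preserve_surface = TRUE)
    for (i in which(seps == "+")) {
      if (grepl("[0-9]$", txt[[i]]) && grepl("^[0-9?]", txt[[i + 1L]])) {
        seps[[i]] <- ";"
      }
    }
  }
  hgvs_variant_list(items, seps)
}

gen_genotype <- function(depth, dialect) {
  form <- pick(c("single", "single_allele_set", "multi_allele",
                 "multi_transcript"), prob = c(0.5, 0.25, 0.15, 0.10))
  entry <- if (form == "single") {
    pick(c("full", "coordinate_prefixed", "bare"), prob = c(0.4, 0.4, 0.2))
  } else {
    pick(c("full", "coordinate_prefixed"), prob = c(0.5, 0.5))
  }
  ref <- if (entry == "full") gen_refseq("dna_rna") else hgvs_refseq()
  system <- if (entry == "bare") {
    NA_character_
  } else {
    pick(COORD_SYSTEMS, prob = c(0.40, 0.30, 0.05, 0.15, 0.10))
  }
  body <- switch(form,
    single = gen_rawvar(depth, dialect, in_bracket = FALSE),
    single_allele_set = gen_varlist(depth, dialect),
    multi_allele = {
      phase <- pick(c("certain", "uncertain"), prob = c(0.6, 0.4))
      nsets <- if (phase == "uncertain") 2L else 1L + rint(2L)
      hgvs_multi_allele(lapply(seq_len(nsets), function(i) {
        gen_varlist(depth, dialect, max_items = 3L)
      }), phase)
    },
    multi_transcript = hgvs_multi_transcript(lapply(seq_len(1L + rint(2L)),
      function(i) gen_varlist(depth, dialect, max_items = 3L))))
  hgvs_genotype(body, ref, system)
}

gen_aa <- function(dominant_style, stop_ok = FALSE) {
  style <- if (chance(0.95)) dominant_style else
    setdiff(c("three_letter", "one_letter"), dominant_style)
  if (stop_ok && chance(0.1)) {
    return(hgvs_aa(if (style == "three_letter") AA_STOP3 else
      pick(AA_STOP1, prob = c(0.8, 0.2))))
  }
  i <- rint(nrow(AA_TABLE))
  hgvs_aa(if (style == "three_letter") AA_TABLE$code3[[i]] else
    AA_TABLE$code1[[i]])
}

gen_aaloc <- function(style) hgvs_aa_loc(gen_aa(style), rint(999))

gen_aarange <- function(style) hgvs_aa_range(gen_aaloc(style),
                                             gen_aaloc(style))

gen_protein <- function(dialect) {
  style <- pick(c("three_letter", "one_letter"), prob = c(0.7, 0.3))
  type <- pick(c("subst", "del", "dup", "ins", "delins", "fs", "no_change",
                 "unknown", "no_protein"),
               prob = c(0.30, 0.15, 0.10, 0.12, 0.10, 0.13, 0.03, 0.03,
                        0.04))
  loc_or_range <- function() {
    if (chance(0.4)) gen_aarange(style) else gen_aaloc(style)
  }
  args <- switch(type,
    subst = list(loc = gen_aaloc(style), to = gen_aa(style, stop_ok = TRUE)),
    del = , dup = list(loc = loc_or_range()),
    ins = list(loc = gen_aarange(style),
               inserted = if (chance(0.8)) {
                 list(kind = "seq",
                      value = lapply(seq_len(rint(4)),
                                     function(i) gen_aa(style)))
               } else {
                 list(kind = "length", value = rint(50))
               }),
    delins = list(loc = loc_or_range(),
                  inserted = list(kind = "seq",
                                  value = lapply(seq_len(rint(4)),
                                                 function(i) gen_aa(style)))),
    fs = {
      first <- if (chance(0.6)) gen_aa(style) else NULL
      list(loc = gen_aaloc(style), first_new = first,
           new_stop = if (!is.null(first) && chance(0.5)) {
             list(surface = pick(c(AA_STOP3, "*", "X"),
                                 prob = c(0.6, 0.3, 0.1)),
                  count = if (chance(0.9)) rint(200) else NA_integer_)
           } else {
             NULL
           })
    },
    list())
  entry <- pick(c("full", "coordinate_prefixed", "bare"),
                prob = c(0.3, 0.5, 0.2))
  ref <- if (entry == "full") gen_refseq("protein") else hgvs_refseq()
  prefixed <- entry != "bare"
  do.call(hgvs_protein_variant,
          c(list(type = type), args,
            list(ref = ref, prefixed = prefixed,
                 predicted = chance(0.12))))
}

#' Generate a random AST
#'
#' One draw from the grammar-mirroring sampler at the given recursion
#' budget; used by [hgvs_generate()] and directly by round-trip tests.
#' RNG state is taken from the session (callers seed it).
#'
#' @param level `"dna_rna"` or `"protein"`.
#' @param dialect Dialect whose productions may be exercised.
#' @param max_depth Recursion budget for nested sub-alleles.
#' @return An [hgvs_genotype()] or [hgvs_protein_variant()].
#' @export
hgvs_generate_ast <- function(level = "dna_rna", dialect = "strict",
                              max_depth = 6) {
  level <- match_arg2(level, LEVELS, "level")
  dialect <- match_arg2(dialect, DIALECTS, "dialect")
  if (level == "dna_rna") {
    gen_genotype(as.integer(max_depth), dialect)
  } else {
    gen_protein(dialect)
  }
}

#' Generate a corpus of random variant descriptions
#'
#' Draws `config$count` ASTs from the grammar sampler and serializes them
#' with their surface forms preserved. Identical configurations give
#' identical corpora; every generated description is accepted by
#' [hgvs_check()] at the configuration's level and dialect (the closure
#' property the test-suite asserts).
#'
#' @param config An [hgvs_generator_config()].
#' @return Character vector of `config$count` descriptions.
#' @examples
#' hgvs_generate(hgvs_generator_config(seed = 42, count = 3))
#' @export
hgvs_generate <- function(config) {
  stopifnot(inherits(config, "hgvs_generator_config"))
  if (config$count == 0L) return(character())
  withr::with_seed(config$seed, {
    vapply(seq_len(config$count), function(i) {
      hgvs_serialize(hgvs_generate_ast(config$level, config$dialect,
                                       config$max_depth),
                     preserve_surface = TRUE)
    }, character(1))
  })
}

#' Generate a corpus of random ASTs
#'
#' The AST-level counterpart of [hgvs_generate()] under the same seeding
#' discipline, for structural round-trip testing.
#'
#' @inheritParams hgvs_generate
#' @return List of `config$count` AST records.
#' @export
hgvs_generate_asts <- function(config) {
  stopifnot(inherits(config, "hgvs_generator_config"))
  if (config$count == 0L) return(list())
  withr::with_seed(config$seed, {
    lapply(seq_len(config$count), function(i) {
      hgvs_generate_ast(config$level, config$dialect, config$max_depth)
    })
  })
}

#' Write a generated corpus with its reproducibility sidecar
#'
#' Writes one description per line, plus `<path>.meta.json` recording the
#' generating configuration.
#'
#' @param strings Character vector of descriptions.
#' @param path Output file path.
#' @param config The [hgvs_generator_config()] that produced `strings`.
#' @return `path`, invisibly.
#' @export
hgvs_write_corpus <- function(strings, path, config) {
  writeLines(strings, path)
  jsonlite::write_json(unclass(config), paste0(path, ".meta.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
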
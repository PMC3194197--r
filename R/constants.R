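# Terminal alphabets and code tables shared by the parsers, serializers,
# grammar export and generator.

DIGITS <- as.character(0:9)

# IUPAC nucleotide alphabet, both cases, so that r.-level lowercase
# descriptions and ambiguity letters (e.g. the R in c.[370A>C^372C>R]) parse.
IUPAC_NT_UPPER <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")
IUPAC_NT <- c(IUPAC_NT_UPPER, tolower(IUPAC_NT_UPPER))

COORD_SYSTEMS <- c("c", "g", "m", "n", "r")

DIALECTS <- c("strict", "legacy", "lenient")
LEVELS <- c("dna_rna", "protein")

# The 20 standard residues. Selenocysteine/pyrrolysine deliberately excluded
# to keep the code tables small and fully testable.
AA_TABLE <- data.frame(
  code3 = c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
            "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
            "Tyr", "Val"),
  code1 = c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
            "I", "L", "K", "M", "F", "P", "S", "T", "W",
            "Y", "V"),
  stringsAsFactors = FALSE
)

# Stop codon surface forms: Ter (three-letter), * and legacy X (one-letter).
AA_STOP3 <- "Ter"
AA_STOP1 <- c("*", "X")

SUBST_OPERATORS <- c(gt = ">", slash = "/", arrow = "->", long_arrow = "-->")

LIST_SEPARATORS <- c("semicolon" = ";", "mosaic_slash" = "/",
                     "chimeric_double_slash" = "//", "xor_caret" = "^",
                     "legacy_plus" = "+")

# Nested sub-alleles are permitted only inside these change classes.
NESTABLE_TYPES <- c("dup", "ins", "inv", "conv")

MAX_NEST_DEPTH <- 32L  # documented parser recursion bound (spec floor: 16)

match_arg2 <- function(x, choices, what) {
  if (length(x) != 1L || is.na(x) || !x %in% choices) {
    stop(sprintf("`%s` must be one of: %s", what,
                 paste(choices, collapse = ", ")), call. = FALSE)
  }
  x
}
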
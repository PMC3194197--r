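# hgvsparser

Human sequence variants are communicated in the HGVS nomenclature —
`NM_003002.2:c.274G>T` for a coding-DNA substitution, `p.Ser124Arg` for
its predicted protein consequence, `g.100_200inv{158A>C}` for a nested
change inside an inversion. The notation is compact enough for tables and
databases but rich enough that reliable software (variant databases,
diagnostic pipelines, text-mining tools) cannot get by with ad-hoc
regular expressions: allele sets, mosaic (`/`) and chimeric (`//`)
separators, exclusive-or combinations (`^`), nested sub-alleles and
legacy spellings make it a genuinely recursive language.

`hgvsparser` implements that language as a pair of formal grammars and
gives R users the tooling around them:

* **Parsers.** Recursive-descent parsers for the DNA/RNA-level grammar
  (top rule `Var`) and the protein-level grammar (top rule
  `ProteinVar`), producing a typed AST and a full parse tree with
  0-based, half-open spans. Three dialects: `strict` (the standard
  grammar), `legacy` (adds the `IVS`/`EX` deviation rules and `+`
  separators), `lenient` (adds the `/`, `->`, `-->` substitution
  operators found in mined literature).
* **Syntax checker.** A non-throwing acceptor reporting validity, the
  matched description form (`full` / `coordinate_prefixed` / `bare`) and,
  on rejection, the 0-based halt position — the first character the
  parser could not consume. Batch mode checks one-word-per-line files
  and returns a tibble.
* **Serializer.** Canonical reserialization of ASTs
  (`serialize(parse(s)) == s` on the examples; lenient operators
  canonicalize to `>` unless the surface is preserved).
* **Grammar as data.** The production set exports as an `hgvs_grammar`
  object (and JSON), converts to Chomsky normal form, and feeds a CYK
  membership oracle plus a bounded language enumerator used to verify
  the hand-written parser exhaustively on designated sub-grammars.
* **Generator.** A seeded, grammar-driven random description generator
  for fixtures and fuzzing.
* **CLI.** `exec/hgvs-syntax` with `check`, `batch`, `parse` and
  `generate` subcommands (quote descriptions — `>`, `(`, `;` are shell
  syntax).

The grammar is a deliberate superset of the nomenclature: position
arithmetic and any validation against an actual reference sequence are
semantic concerns and out of scope (see the vignette in
`vignettes/variant-grammar.Rmd`).

## Worked example

```r
library(hgvsparser)

p <- hgvs_parse_genotype("NM_003002.2:c.274G>T")
p
#> <hgvs_parsed> NM_003002.2:c.274G>T [dna_rna, strict, form=full]
str(p$ast$body, max.level = 1)
#> List of 5
#>  $ type    : chr "subst"
#>  $ loc     :List of 4
#>   ..- attr(*, "class")= chr "hgvs_ptloc"
#>  $ from    : chr "G"
#>  $ to      : chr "T"
#>  $ operator: chr "gt"
#>  - attr(*, "class")= chr "hgvs_raw_variant"
```

The description matched the `full` form: a GenBank reference
(`NM_003002`, version 2), the coding-DNA coordinate system `c`, and a
substitution of `G` by `T` at position 274. Serialization inverts it:
`hgvs_serialize(p$ast)` returns the input string exactly.

A rejected description reports where parsing halted (0-based; 7 is the
input length — a nucleotide was expected after `>`):

```r
hgvs_check("c.274G>")
#> <hgvs_syntax_result> invalid at 7 (dna_rna, strict): syntax error at position 7
```

Batch checking returns a tibble; note `IVS4+1G>T` is invalid in the
strict dialect but valid with `dialect = "legacy"`:

```r
hgvs_batch_check(c("NM_003002.2:c.274G>T", "274G>T", "IVS4+1G>T",
                   "notavariant"))
#> # A tibble: 4 × 7
#>   input                level   dialect valid matched_form halt_position message
#> 1 NM_003002.2:c.274G>T dna_rna strict  TRUE  full                    NA ""
#> 2 274G>T               dna_rna strict  TRUE  bare                    NA ""
#> 3 IVS4+1G>T            dna_rna strict  FALSE none                     4 "syntax…"
#> 4 notavariant          dna_rna strict  FALSE none                    11 "syntax…"
```

Protein descriptions, including the mixed-code lint:

```r
hgvs_lint_mixed_code(hgvs_parse_protein("G123_Cys125del"))
#> [1] "range G123_Cys125 mixes one-letter and three-letter amino-acid codes"
```

Seeded generation of syntactically valid descriptions:

```r
hgvs_generate(hgvs_generator_config(seed = 42, count = 3))
#> [1] "AB000009.4:c.[3954delinsA;259_?conAB000004.5;-?_-9028del348,=^626_1396dup{517A>T^5897+5445del}]"
#> [2] "c.[2346_?conFLI/9501_6782del112]"
#> [3] "PAX_i5:n.-2859-9467_*1907-u6670inv"
```

From the shell:

```sh
exec/hgvs-syntax check 'NM_003002.2:c.274G>T'    # -> valid full (exit 0)
exec/hgvs-syntax parse '274G>T'                  # JSON parse tree
exec/hgvs-syntax batch variants.txt --dialect legacy
```

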
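---
title: "The variant-nomenclature grammar: model, dialects and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The variant-nomenclature grammar: model, dialects and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgvsparser)
```

## The language, not the biology

HGVS variant descriptions — `NM_003002.2:c.274G>T`, `p.Ser124Arg`,
`g.100_200inv{158A>C}` — form a small formal language. This package treats
that language as the object of study: two context-free grammars (one for
the DNA/RNA level, whose top rule is `Var`; one for the protein level,
whose top rule is `ProteinVar`) are implemented as recursive-descent
parsers whose function structure mirrors the productions one-to-one.

Everything here is *syntax*. Whether position 274 exists in NM_003002.2,
whether a range runs start-before-end, whether an RNA description really
uses lowercase — those are semantic questions that require a reference
sequence, and they are deliberately out of scope. The grammars therefore
describe a superset of the nomenclature; downstream tools are expected to
restrict it semantically. One syntactic superset is flagged rather than
rejected: a protein range whose endpoints mix one-letter and three-letter
codes (`G123_Cys125`) parses, and `hgvs_lint_mixed_code()` reports it.

## Description forms and the checker

A description can carry a full reference (`NM_003002.2:c.274G>T`), only a
coordinate-system prefix (`c.274G>T`), or nothing but the change
(`274G>T`). The checker tries these entry forms most-complete-first and
records which one matched:

```{r}
hgvs_check("NM_003002.2:c.274G>T")
hgvs_check("274G>T")$matched_form
```

On rejection the halt position is reported: the furthest 0-based offset
any entry-point attempt required. "Furthest across attempts" is a
deliberate convention (the most informative one for users); 0-based
half-open spans are used everywhere, so a halt equal to the input length
means "more input was expected":

```{r}
hgvs_check("c.274G>")
```

Batch mode reproduces the one-word-per-line workflow: surrounding
whitespace is stripped, only the first tab-separated field is checked, a
record with internal whitespace is flagged invalid rather than aborting
the run, and the result is a tibble with one row per record plus summary
counts (`glance()`).

The two levels are checked independently; there is no auto-detection
between DNA and protein grammars in the API. The command-line tool
(`exec/hgvs-syntax`, or `hgvs_cli()`) offers `--level auto` as a
convenience that tries DNA/RNA first, then protein, and says which
matched.

## Dialects

Three nested dialects are supported, each a strict superset of the last:

* **strict** — the standard grammar: substitutions, deletions,
  duplications, insertions, deletion-insertions, inversions, gene
  conversions; allele sets in brackets joined by `;` (one allele), `/`
  (mosaic), `//` (chimeric), `^` (exclusive or); multiple allele sets
  with certain (`;`) or uncertain (`(;)`) phase; nested sub-allele
  changes in curly braces on duplications, insertions, inversions and
  conversions (and only those); UTR markers `-`/`*`; offsets with the
  `u`/`d` beyond-transcript markers; `?` for unknown positions; LRG
  references with `t`/`p` suffixes and gene symbols with `_v`/`_i`.
* **legacy** — adds the backwards-compatibility deviation rules:
  `IVS<intron>±<offset>` positions, `EX<exon>` locations, and `+`/`(+)`
  as the older allele-set separators.
* **lenient** — further adds the substitution operators `/`, `->` and
  `-->` seen in mined literature instead of `>`. A `/` is read as a
  substitution operator only *outside* brackets; inside a bracketed
  allele list it is always the mosaic separator. That context rule keeps
  the language unambiguous but is not expressible in a pure CFG, so the
  exported lenient grammar (`hgvs_export_grammar("dna_rna", "lenient")`)
  over-generates slightly at exactly that point.

Canonical serialization follows the strict surface: lenient operators
serialize to `>` and stop codons to `Ter` unless `preserve_surface =
TRUE`. Structural legacy forms (IVS/EX locations, `+` separators) always
serialize as themselves — rewriting them into strict coordinates would
need a reference sequence, which is semantics.

## Parse model

Parsing yields two coupled artifacts: a typed AST (records such as
`hgvs_genotype`, `hgvs_raw_variant`, `hgvs_ptloc`) and a parse tree of
named productions with 0-based, half-open spans. The tree satisfies a
span-soundness invariant — concatenating its leaf texts reproduces the
consumed input exactly — which forces every terminal, including operator
symbols, to be covered by a leaf; a substitution node therefore has four
children (`PtLoc`, `Nt`, `SubstOp`, `Nt`). `hgvs_to_structured()` /
`hgvs_tree_json()` export the tree losslessly with stable key order.

Two disambiguation policies deserve explicit statement, since the surface
syntax alone cannot decide them:

* **Reference classification.** `NM_003002`, `DMD` and `DMD_v2` are all
  letter/digit/underscore tokens. The order is: LRG (`LRG_` prefix)
  first; then a token ending in `_v<num>`/`_i<num>` is a gene symbol
  with a transcript/isoform suffix; then any digit-containing token is a
  GenBank accession; otherwise a gene symbol.
* **Insertion targets.** After `ins`, a nucleotide string, a range, a
  bare length and a far-location all compete (`insAB23456.7` starts with
  two IUPAC letters). Alternatives are tried in the order sequence,
  range, length, far-location, each accepted only if the next character
  can legitimately follow a complete variant. The range is deliberately
  tried before the bare length because `+` can follow a variant (it is a
  legacy separator) yet also open an offset inside a range.

Other numerical/degenerate-input choices: numbers are plain digit runs
with no upper bound (values beyond R's integer range are carried as
doubles); `?` positions take no offset; nesting of sub-alleles is bounded
at depth 32 (documented floor: 16) to keep recursion finite on
adversarial input; the empty string is invalid with halt 0; arbitrary
bytes never crash the checker.

## The generator

`hgvs_generate()` draws ASTs by sampling the constructors — one sampling
site per production — and serializes them with surfaces preserved.
Recursive alternatives (nested sub-alleles) have their probability halved
for each depth unit already spent, so every derivation terminates within
the configured budget. Positions are drawn from 1–9999, accessions from a
fixed fake pool (`AB000001`–`AB000009`) and gene symbols from a fixed
digit-free pool in which every symbol contains at least one non-IUPAC
letter — a symbol spelled entirely in IUPAC ambiguity letters would be
indistinguishable from a nucleotide string as an insertion target. Two
junctions the sampler refuses to emit are worth knowing about: the legacy
`+` separator is not placed between a digit-final item and a
digit-initial one (the concatenation re-reads as a position offset — one
reason the nomenclature replaced `+` with `;`).

Generated corpora emulate the breadth of the grammar, not the frequency
profile of real literature: no attempt is made to match how often each
change class occurs in databases, positions are uniform rather than
gene-shaped, and sequences are short. A passing closure test therefore
says the parser accepts the grammar's language, not that it has been
tuned on realistic mutation reports.

## Verification strategy

The parser is hand-written, so it is verified against independent
machinery rather than against itself:

1. **Round trip A** — every bundled example description satisfies
   `serialize(parse(s)) == s` exactly.
2. **Round trip B** — generated ASTs satisfy
   `parse(serialize(a))` structurally identical to `a`
   (`identical()` on the records), 1,000 per level in the acceptance
   suite and across all six level/dialect conditions in the unit suite.
   Because the generator builds records through the validating
   constructors while the parser uses its own fast builders, this test
   also pins the two construction routes together field-for-field.
3. **Oracle equivalence** — on designated sub-grammars
   (`hgvs_subgrammar()`), parser acceptance is compared with
   context-free membership over *every* string up to a length bound.
   The CFG side converts the sub-grammar to Chomsky normal form
   (`hgvs_to_cnf()`) and computes the length-bounded derivation closure
   (`hgvs_enumerate_language()`) — the same least fixpoint CYK
   evaluates per string, here evaluated for all strings at once; the
   per-string `hgvs_cyk_member()` is replayed on every member and on
   sampled rejected strings. The parser side enumerates its accepted set
   exhaustively by a trie search with sound pruning: the parser records
   whether any rule ever demanded a character at or beyond the end of
   the input (`hit_end`); a prefix rejected without hitting its end
   never read past its last character, so all its extensions replay the
   identical execution and are rejected — that subtree is pruned. Only
   the `bare` entry form is probed: the sub-grammar alphabets exclude
   `:` and `.`, so the other entry forms can accept nothing over them,
   while their speculative token scans would reach the end of nearly
   every prefix and defeat the pruning.

   The DNA sub-grammar (substitutions and deletions over
   `2 7 4 G T > d e l _`, where `d` doubles as an IUPAC ambiguity
   nucleotide exactly as the full parser treats it) is compared on all
   1.1×10⁸ strings of length ≤ 8; the protein sub-grammar
   (substitution/deletion/duplication over `G l y u S e r d p 1 2 _`,
   residues Gly, Glu, Ser, G, S — every code spellable in the alphabet)
   on all strings of length ≤ 10. Position numbers in both sub-grammars
   are unbounded digit runs so that the fragment's language equals the
   full parser's language restricted to the alphabet; a bounded-digit
   fragment would disagree with the parser on strings like
   `S11111del`. Both comparisons find zero disagreements.
4. **Dialect layering** — strict-generated corpora are re-checked under
   legacy and lenient (language inclusion), with marker forms
   (`274G->T` lenient-only, `IVS4+1G>T`/`EX5del` legacy-but-not-strict)
   asserted individually.
5. **Robustness** — thousands of random byte strings yield well-formed
   results with halt positions inside `[0, length]`.

One measured property is recorded rather than asserted: deleting a single
character from an example description yields an invalid string only about
56% of the time, because deleting one digit of a multi-digit position
leaves a perfectly valid description. The language is far less redundant
than an error-correcting code; any claim of high mutation sensitivity
would be wrong for this grammar.

## Problem sizes

The shipped test-suite sizes are the package's chosen operating points:
closure at 10,000 descriptions per level and dialect; structural round
trips at 1,000 ASTs per level in the acceptance block (and 6×1,000 in the
unit suite); oracle equivalence at lengths 8 (DNA) and 10 (protein);
dialect inclusion at 5,000 corpus strings in the timed acceptance block,
with the full 10,000-string scan performed by `scripts/acceptance.R`;
robustness at 10,000 byte strings of length ≤ 64. At ~0.7 ms per check
these complete comfortably on one CPU.

## Known limitations

* Syntax only: no coordinate arithmetic, no mapping between coordinate
  systems, no validation against sequence records.
* Tandem-repeat syntax, translocations, chromosome bands and full ISCN
  karyotypes are outside the grammar (only the `/` and `//` separators
  were adopted from ISCN).
* Parenthesized uncertain boundary positions (`(100_200)`) are not in
  the grammar; only `?` positions and `(;)` phase uncertainty are.
* Protein extension syntax (`ext`) is not modelled; frameshifts are.
* Selenocysteine and pyrrolysine are excluded from the amino-acid
  tables, keeping the code tables small and fully testable.
* The exported lenient grammar over-generates where the parser applies
  the brackets-context rule for `/` (see above).
* `,` joins variant lists only inside one bracket pair
  (multi-transcript form); it does not join bracket groups.
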
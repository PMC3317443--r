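---
title: "Combinatorial DNA construct design with dnadesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial DNA construct design with dnadesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnadesign)
```

## The design model

dnadesign is a headless toolkit for designing combinatorial DNA constructs
from reusable genetic parts. Its data model mirrors the whiteboard picture a
synthetic biologist draws: **parts** (promoter, RBS, CDS, linker, tag,
vector backbone, ...) are named, oriented regions cut from annotated
**source sequences**, and they are arranged left to right into ordered
**bins**. Each bin holds one or more interchangeable parts, and one part per
bin is chosen in each concrete **construct**; a design is combinatorial as
soon as any bin holds more than one part. The collection of bins, an output
topology flag (circular by default, matching the plasmid-dominated practice
of the field), the registered sources and the design rules together form the
**design**.

Three principles organize the implementation:

1. **Correct by construction.** Invalid states are rejected at the point of
   entry, not discovered downstream: a part referencing base 500 of a 100 bp
   source is refused when it is defined; two parts cannot share a name
   (name-matched rules would otherwise silently misfire); part names are
   restricted to `[A-Za-z0-9_-]` so they survive every file format the
   package emits. A design whose `validate_design()` report carries no
   error-severity diagnostic is guaranteed to enumerate and assemble without
   raising — this contract is fuzz-tested over randomly generated designs.
2. **Linked repeated parts.** A part placed in several bins is stored once:
   every placement references the same definition, so an edit (say, a
   one-base change of a stop coordinate) updates all instances atomically,
   and inconsistent replicates are unrepresentable. Renaming a part also
   renames it inside every rule that references it.
3. **Scar-less assembly as pure concatenation.** Assembling a construct
   concatenates the extracted part sequences 5'→3' with no added bases.
   Junction chemistry (primer design, overhang selection, melting
   temperatures) belongs to downstream assembly-design tools and is out of
   scope here; the per-junction "forced relative overhang" is carried as
   opaque metadata for those tools.

## Sequences and coordinates

All coordinates — in the API, in design documents, and in the CSV
interchange files — are 1-based and inclusive, the GenBank convention.
Sources may be circular; a region or feature may wrap the origin, written
`start > stop`, and extraction reads through position `L` then `1`.
Reverse-orienting a part reverse-complements its extracted region after
extraction. Residue case is preserved verbatim (comparison is
case-insensitive), and `N` is allowed: no base-level chemistry is modeled,
so parts containing `N` assemble normally.

Features that lie only partially inside an extracted window are kept,
remapped, and flagged by suffixing the label with `" (truncated)"` — the
annotation is retained without inventing data. In the rare case that a
feature intersects an origin-wrapping window in two disconnected pieces,
each maximal contiguous piece becomes its own truncated feature. Truncated
features are *not* propagated into assembled constructs: an assembly carries
exactly the features fully contained in its parts, plus one spanning
feature per part (labelled with the part name) so fusion joints and reading
frames remain inspectable.

GenBank I/O writes minimal standard-compliant records
(LOCUS/DEFINITION/FEATURES/ORIGIN), declares `circular`/`linear` topology on
the LOCUS line, encodes reverse-strand features with `complement()` and
origin-wrapping features with `join(a..L,1..b)`, and tolerates a missing
DEFINITION on read.

## Design-specification rules

The rule engine supports the three operators a combinatorial canvas needs:

- `WITH` — *directional* co-occurrence: a construct containing `operand1`
  must also contain `operand2`. The direction matters: on the worked 8-way
  design below, `short WITH sig1` eliminates exactly the 2 combinations
  pairing `short` with `sig2`, whereas a symmetric reading would eliminate
  4. The symmetric reading is explicitly rejected and tested against.
- `NOTWITH` — mutual exclusion of two parts.
- `NOTMORETHAN n` — copy-number cap on one part (all instances of the named
  part count, regardless of orientation).

Rules are constrained at creation to operands presently on the canvas, so a
rule for a mistyped part name (the classic `ispA` vs `ispA-O` trap, where a
copy-cap rule silently fails to bind) cannot be created. The rules file
dialect is one statement per line,

```
Rule <name>(<operand1> <OPERATOR> <operand2|count>);
```

with `//` comments and case-insensitive operator keywords. Import
classifies every line — `imported`, `identical` (same name, same content),
`renamed_conflict` (same name, different content; imported under
`<name>_k` for the smallest unused `k`), or `ignored` with a reason — and
never fails: all problems become records. A rule identical in content but
different in name imports as a new rule.

## Enumeration, filtering, naming

Enumeration is the Cartesian product over bins in lexicographic order with
the leftmost bin varying slowest; the order is what makes sequential
construct naming (`pRDR00001`, `pRDR00002`, ...) reproducible. Counting is
lazy — `n_constructs()` is a product of bin sizes — and `filter_by_rules()`
streams in chunks, so library-scale designs (38³ = 54,872 combinations and
beyond) are counted and filtered without materializing sequences.
`name_constructs()` zero-pads the index to the width of the final index so
names sort in enumeration order.

The elimination report counts, per rule, every combination that violates
that rule irrespective of the other rules; per-rule counts may therefore sum
to more than the total eliminated when violations overlap.

## Synthesis spans and firewall costs

When consecutive bins are all obtained by direct DNA synthesis, every
combination across those bins must be purchased as its own fragment: a
contiguous **synthesis span** of bins with sizes $s_1, \dots, s_k$ costs
$\prod_i s_i$ distinct fragments. A **direct synthesis firewall** on the
junction to the right of a bin splits the span there, replacing a product
with a sum of smaller products. For the 38-barcode × 38-gene-variant
scenario, one uninterrupted span costs $38 \times 38 = 1444$ fragments; the
intended firewall between the bins costs $38 + 38 = 76$.

The exact arithmetic of a split is worth stating, because it is not
monotone: splitting a span into sides with $p$ and $q$ combinations changes
the cost from $pq$ to $p+q$, a strict decrease iff $(p-1)(q-1) > 1$, break-
even at $p = q = 2$, and an *increase* when one side is a singleton
($1 + q > q$). The placement-comparison table (`compare_firewall_placements()`)
exists precisely because the best placement is a computation, not a habit.
Fragment identity is by variant combination, not sequence string equality,
so duplicated sequences across variants still count separately — matching
the 38 × 38 arithmetic; a firewall on a bin outside any direct-synthesis run
is recorded but contributes nothing (a warning is issued).

The bin's own strategy is never set directly: it is the modal non-`none`
forced strategy of its member parts, with ties broken by the fixed
vocabulary order `PCR < DIGEST < DIRECT_SYNTHESIS <
EMBEDDED_IN_PRIMER_FORWARD < EMBEDDED_IN_PRIMER_REVERSE`. The underlying
platform only states that the bin strategy is derived; the modal-with-
fixed-tie-break rule is this package's own documented choice, tested
exhaustively over all strategy pairs. A part whose forced strategy differs
from its bin's consensus draws a `W_STRATEGY_MISMATCH` warning (the
red-rectangle alert of a graphical canvas, surfaced here as a diagnostic),
because disparate strategies in one bin defeat combinatorial fragment
re-use. The optional gate refusing `DIGEST`-forced parts in the first bin
defaults to on and can be disabled (`digest_first_bin = FALSE`).

## File interchange

Design documents serialize to a self-contained versioned schema
(`schema_version` 1.0) with two equivalent renderings, JSON and XML, chosen
by file extension; `load(save(d))` is the identity on all modeled fields.
Loading is atomic and purely structural — semantic problems surface as
`validate_design()` diagnostics on the loaded object rather than load
failures, so a defective document can still be opened and inspected. A
missing topology flag defaults to circular with a warning.

The j5-style bundle is a directory of four artifacts: `parts.csv`
(`Part Name, Part Source, Reverse Complement, Start BP, End BP`; the
historical misspelling "Reverse Compliment" is accepted on read),
`order.csv` (a long-format table of `>`-prefixed bin rows carrying the
firewall flag, strategy and forced overhang, each followed by its member
part rows), `rules.eug`, and `sequences/` with one GenBank file per source.
Import also accepts the sequences as a `.zip` archive. Sources are resolved
by the GenBank record display ID, never the file name — entering file names
instead of display IDs is a classic hand-edited-spreadsheet failure, and a
renamed file on disk does not perturb the import. Export is refused while
the design has error-severity diagnostics (the correct-by-construction
gate), and peripheral parts — defined but placed in no bin — are excluded.
The documented lossy set of the bundle round trip is the glyph category
(CSV carries no icon information; every imported part is `generic`) and
minority per-part strategies (the order CSV carries one strategy per bin).

## The fixture generator

`generate_design()` builds complete, validating designs from scratch so
every operation is testable without external data: one random uniform-base
source per (bin, slot) with 10–40 bp of flanking context and 1–3 annotated
features inside the part region, parts of 60–240 bp by default, unique
names, deterministic given the seed (the caller's RNG stream is saved and
restored). Two presets fix the canonical shapes used in the documentation:
`prdr_like` (bins `[1,2,2,1,2,1]`, 9 parts named so the worked
`short WITH sig1` rule applies; 8 combinations) and `barcode_gene3` (two
38-variant `DIRECT_SYNTHESIS` bins, 20–30 bp barcodes; 1444 combinations).
`generate_frame_fixture()` constructs a linear signal-peptide / linker /
CDS / tag fusion in which every part length is divisible by 3, the fusion
starts with `ATG`, no part contains an in-frame internal stop and the last
codon is `TAA` — so a translation oracle can confirm in-frame assembly, and
reverse-orienting the CDS breaks the frame detectably.

What the generator deliberately does *not* emulate: biologically meaningful
sequence composition (codon usage, GC skew, promoter motifs), feature
annotations with real semantics, homology between variants, or vendor
synthesis constraints. Passing tests therefore demonstrate the
combinatorial, coordinate and accounting logic — not that any generated
construct is biologically functional.

## Numerical and degenerate-input choices

- Combination counts are held as doubles (products like $38^3$ stay exact
  far beyond any materializable design; R doubles are exact integers to
  $2^{53}$).
- `enumerate_constructs()` refuses to materialize more than `limit`
  (default $10^5$) constructs; `construct_iterator()` streams without a
  limit, and `filter_by_rules()` works in chunks of $10^4$.
- Empty bins and empty designs are structure errors for enumeration and
  diagnostics (`E_EMPTY_BIN`, `E_EMPTY_DESIGN`) for validation.
- Ties in bin consensus resolve by the fixed vocabulary order (above);
  rule-import rename conflicts resolve to the smallest unused `_k` suffix.
- Test and property-suite problem sizes (30 random designs for the
  brute-force filtering oracle, 50 random sequences for the
  involution/rotation properties, 200 generator fuzz cases at bin sizes
  ≤ 3 and 12–30 bp parts) were chosen so the whole suite exercises every
  code path in well under the patience of an interactive `R CMD check`.

## Known limitations

- The Eugene dialect is the three-operator subset; devices, properties,
  assertions and loops of the full language are out of scope.
- No oligo/primer design, melting temperatures, Golden Gate overhang
  compatibility or monetary cost models: fragment *counts* are the cost
  proxy, as in the firewall worked example.
- Whether identical flanking sequences could be merged into shared
  fragments across combinations is a downstream assembly-design question;
  fragment identity here is by variant combination.
- GenBank support is the minimal dialect above; exotic location operators
  (`order()`, multi-segment `join()` beyond origin wrap) are not parsed.
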
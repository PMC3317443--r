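# dnadesign

Combinatorial DNA construct design in R: parts, bins, design rules,
rule-filtered enumeration, scar-less in-silico assembly, and
direct-synthesis cost accounting.

## The problem

Synthetic biologists designing a combinatorial library — vary the signal
peptide, vary the linker, vary the degradation tag, keep everything else —
need to go from "a whiteboard sketch of interchangeable parts" to concrete,
annotated construct sequences and correct assembly-order files, without
hand-editing spreadsheets of base-pair coordinates. Hand preparation is
where the expensive mistakes live: a stop coordinate one base off, two
different parts sharing a name so a design rule silently binds to the wrong
one, a direct-synthesis firewall on the wrong junction that turns a
76-fragment order into a 1444-fragment one.

dnadesign models the design as data and makes those states unrepresentable
or loudly diagnosed:

- **Parts** are named, oriented regions of annotated source sequences
  (GenBank in/out, circular sources and origin-wrapping coordinates
  supported). Out-of-range coordinates are rejected at part creation.
- **Bins** are ordered 5'→3' slots of interchangeable parts; one part per
  bin is selected in each construct. Repeated parts are stored once and
  edited in unison.
- **Rules** constrain the combinatorial space. Three operators:
  `WITH` (directional co-occurrence: presence of operand 1 requires
  operand 2), `NOTWITH` (exclusion), `NOTMORETHAN n` (copy cap). Operands
  must be parts on the canvas, so a rule cannot reference a typo.
- **Enumeration** is the lazy Cartesian product over bins; **filtering**
  keeps the constructs satisfying every rule; **assembly** concatenates the
  selected parts scar-lessly into an annotated sequence (features
  propagated, one spanning feature per part).
- **Synthesis spans** account for direct-synthesis cost: a run of
  consecutive direct-synthesis bins with sizes *s₁…s_k* costs ∏*sᵢ*
  distinct fragments; a firewall splits the run and replaces the product
  with a sum.

Validation (`validate_design()`) returns stable diagnostic codes
(`E_RANGE`, `E_DUP_NAME`, `E_DIGEST_FIRST_BIN`, `W_STRATEGY_MISMATCH`, ...);
a design with no error-severity diagnostics is guaranteed to enumerate and
assemble.

## Worked example

```r
library(dnadesign)

# 6-bin GFP-localization style collection: backbone | sig1/sig2 |
# long/short linker | gfpuv | tag_lva/tag_asv | terminator
d <- generate_design(preset = "prdr_like", seed = 7)
d
#> <dna_design> circular, 6 bin(s) [1,2,2,1,2,1], 9 part definition(s), 0 rule(s)

# the short linker only works with signal peptide sig1:
d <- add_rule(d, "rule3", "WITH", "short", "sig1")
res <- filter_by_rules(d)
str(res$report)
#> List of 4
#>  $ total                : num 8
#>  $ kept                 : num 6
#>  $ eliminated           : num 2
#>  $ per_rule_eliminations:List of 1
#>   ..$ rule3: num 2

res$constructs[[1]]
#> <construct #1> vector_backbone - sig1 - long - gfpuv - tag_lva - terminator1

assemble_construct(d, res$constructs[[1]], name = "pRDR00001")
#> <annotated_sequence> pRDR00001: 921 bp, circular, 16 feature(s)
```

Of the 8 possible combinations, the rule eliminates exactly the 2 that pair
`short` with `sig2`; the 6 kept constructs assemble to circular annotated
sequences (writable with `write_genbank()`) carrying every source feature
contained in a part plus one feature spanning each part.

Firewall placement is a computation, not a habit — on a 38-barcode ×
38-gene-variant direct-synthesis design:

```r
bg <- generate_design(preset = "barcode_gene3", seed = 1)
compare_firewall_placements(bg, list(misplaced = c(FALSE, FALSE),
                                     intended  = c(TRUE, FALSE)))
#>           placement firewalls total is_minimum
#> misplaced misplaced        00  1444      FALSE
#> intended   intended        10    76       TRUE
```

Without a firewall between the bins every pairwise combination must be
synthesized (38 × 38 = 1444 fragments); the intended firewall reduces the
order to 38 + 38 = 76.

Designs round-trip through versioned JSON/XML documents
(`save_design()`/`load_design()`) and export/import as j5-style CSV +
GenBank bundles (`export_j5_bundle()`/`import_j5_bundle()`). A thin
command-line wrapper over these functions ships at
`inst/cli/dnadesign.R` (subcommands `validate`, `enumerate`, `assemble`,
`cost`, `export-j5`, `import-j5`, `rules-import`, `fixture`).

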
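# PromiScreen

Genome-wide prediction of promiscuous ("underground") enzyme functions
and of the multicopy-suppression gene pairs they imply.

Many enzymes harbour weak secondary activities beyond their annotated
function. Experimentally these surface in *multicopy suppression*: a
strain whose conditionally essential **target** gene is deleted (lethal
on minimal M9 medium, viable on rich medium) is rescued by
over-expressing a native **replacer** gene. PromiScreen predicts such
target–replacer pairs computationally, for anyone studying underground
metabolism, gene dispensability, or the evolutionary reservoir of
latent enzyme function.

## The method

1. **Homolog recruitment.** For each metabolic root gene, an iterative
   profile search (align → cluster at 90% identity → trim terminal
   columns below 50% occupancy → build a position-specific scoring
   profile → gapped local search → filter) runs for three rounds with
   relaxing cutoffs. The final round keeps a hit iff

   `uncovered ≤ 100  AND  coverage ≥ 0.60  AND  identity ≥ 0.15  AND  positives ≥ 0.30`

   (all inclusive; *positives* = aligned pairs with positive BLOSUM62
   score, identical pairs included). Iteration is the point: a distant
   homolog B at ~25% identity to the root is recruited through an
   intermediate A even when a single-sequence search cannot see B.

2. **Promiscuity matrix.** Every function on any tree member, minus the
   root's primaries, becomes a candidate promiscuous function of the
   root (single-subunit hits of an enzyme complex expand to the whole
   complex function).

3. **Direct pairs (matrix lookup).** Emit (target, replacer) whenever a
   replacer's promiscuous function equals a target's primary function.

4. **Indirect pairs (GEM + FBA).** For targets that are conditionally
   essential *in silico* — knockout growth `< ε` on M9, `≥ ε` on rich,
   with `ε = 1e-6` and growth from maximizing biomass `v` subject to
   `S v = 0`, `lb ≤ v ≤ ub` — add each candidate promiscuous reaction
   to the knocked-out model and emit a pair iff it restores growth,
   i.e. the candidate *bypasses* the target metabolically.

Hypergeometric overlap and reciprocity tests (`overlapTest`,
`reciprocityPvalue`) compare predictions against experimental
suppressor sets. Deterministic fixture generators (`generateProteome`,
`generateToyGem`) plant distant homologs at controlled identity and a
toy model with a conditionally essential vitamin pathway plus a bypass,
so the whole pipeline is testable offline.

## Worked example

```r
library(PromiScreen)

fx <- generateProteome(fixtureSpec(seed = 1))   # 3 organisms x 50 genes
ps <- fx$proteome
ps
#> ProteomeSet with 150 sequence(s) from 3 organism(s); 150 annotated gene(s), 148 metabolic

# the hardest planted link: a homolog at 20% identity
tr <- iterateSearch("org1_g004", ps)
tr@members
#>     gene_id organism_id identity positives coverage uncovered score
#> 1 org1_g004        org1    1.000      1.00     1.00         0    NA
#> 2 org3_g034        org3    0.595      0.67     0.99         2   566
```

The foreign homolog `org3_g034` was recruited; its statistics are
measured against the final multi-member profile consensus, which is why
the identity (0.595) exceeds the planted pairwise identity (0.20) —
the profile, not the raw pair, is what cleared the cutoffs.

```r
gem <- generateToyGem()
essentialityClass(gem$model, "org1_g021")
#> conditionally_essential

ko <- applyMedium(knockoutGenes(gem$model, "org1_g021"), "M9")
fba(ko)
#> FluxSolution: optimal, biomass flux = 0
fba(addReaction(ko, gem$catalog$fn_p5ps[[1]]))
#> FluxSolution: optimal, biomass flux = 9.09091
```

Knocking out the middle gene of the vitamin pathway abolishes growth on
M9; adding the planted one-step bypass restores the wild-type optimum
10/1.1 = 9.0909 (carbon uptake 10 split between biomass carbon and the
0.1-per-unit vitamin demand). `predictIndirectPairs` automates exactly
this loop over every candidate function and reports rescued pairs plus
a full rescue table; on the toy catalog only the planted bypass
rescues, every decoy fails.

For an end-to-end run, `runPipeline(pipelineConfig(...))` executes
search → matrix → direct → indirect → statistics and writes trees,
matrix, pair tables, histogram, log and a config snapshot to an output
directory, byte-reproducibly. A thin CLI with the same functionality
ships in `inst/scripts/promiscreen`.

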
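---
title: "Screening for promiscuous enzyme functions: methods and design"
author: "PromiScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for promiscuous enzyme functions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PromiScreen)
```

## The problem

Many enzymes carry, beyond their annotated primary activity, weak
secondary ("underground" or promiscuous) activities. These are invisible
to ordinary annotation but become physiologically relevant when the
gene is over-expressed: in a *multicopy suppression* assay, a strain
whose conditionally essential **target** gene is deleted (lethal on
minimal medium, viable on rich medium) is rescued by over-expressing a
native **replacer** gene from a plasmid. PromiScreen predicts such
target-replacer pairs computationally, genome-wide, in two modes:

* **direct** pairs, where a replacer's predicted promiscuous function
  equals a target's primary function; and
* **indirect** pairs, where the promiscuous function does not replace
  the target's reaction but metabolically *bypasses* it, so the pair is
  only discoverable by adding the candidate reaction to a genome-scale
  metabolic model (GEM) and testing whether flux-balance analysis (FBA)
  growth is restored after the target knockout.

## The procedure

### 1. Recruiting distant homologs (`iterateSearch`)

For every in-scope metabolic root gene, the engine runs an iterative
profile search over the multi-organism proteome:

1. **align** the current member set (progressive center-star alignment;
   Needleman-Wunsch with BLOSUM62, affine gaps open 11 / extend 1,
   merged by "once a gap, always a gap");
2. **cluster** rows at 90% ungapped identity (greedy, longest member
   representative, lexicographic tie-break) so the profile is not
   dominated by near-duplicates of the root;
3. **trim** terminal columns whose non-gap occupancy is below 50%, so
   the profile is a compact model of the conserved core rather than of
   ragged ends;
4. **score** a position-specific profile from the trimmed columns
   (below) and align it locally (Smith-Waterman with affine gaps,
   compiled code) against every database sequence;
5. **filter** the best hit per subject with four inclusive cutoffs and
   admit survivors into the member set.

Three rounds run with monotonically relaxing cutoffs; only the final
round's values are canonical:

| round | max uncovered | min coverage | min identity | min positives |
|------:|--------------:|-------------:|-------------:|--------------:|
| 1     | 50            | 0.70         | 0.30         | 0.45          |
| 2     | 75            | 0.65         | 0.22         | 0.37          |
| 3     | 100           | 0.60         | 0.15         | 0.30          |

*Positives* counts aligned pairs with a positive substitution-matrix
score, identical pairs included, so identity never exceeds positives.
Hit statistics are measured against the per-column *consensus* residue
(majority, alphabetical tie-break). There is no E-value gate: retention
is governed by the four cutoffs plus a raw-score floor of 0. The
iteration matters because a root can reach a distant homolog B only
through an intermediate A (root-A and A-B each at ~50% identity,
root-B at ~25%): a stringent single-sequence search misses B, while the
round-2 profile, which includes A, recruits it.

### 2. Profile scoring

With observed residue counts $n_{cr}$ in column $c$ ($N_c = \sum_r
n_{cr}$, $f_{cr} = n_{cr}/N_c$), uniform background $p_r = 1/20$, and
BLOSUM62 scores $s(a,r)$, the pseudocount distribution is

$$g_{cr} = \sum_a f_{ca}\, Q(r \mid a), \qquad
  Q(r \mid a) = \frac{p_r\, 2^{\lambda s(a,r)}}
                     {\sum_b p_b\, 2^{\lambda s(a,b)}},$$

and with data-dependent observation weight $m_c = N_c - 1$,

$$q_{cr} = \frac{m_c f_{cr} + \beta g_{cr}}{m_c + \beta}, \qquad
  S_{cr} = \log_2 \frac{q_{cr}}{p_r}.$$

A single-sequence profile therefore reduces to a softened substitution
matrix, and deeply observed columns converge to the observed
frequencies — the behaviour of PSI-BLAST-style position-specific
matrices. Defaults: $\beta = 1$, $\lambda = 0.35$. The scale
$\lambda$ controls how harshly mismatches are penalized relative to
matches: at 0.35 the expected score per aligned column stays positive
for genuinely homologous pairs (conservative substitutions) down to
roughly 20% identity, so their optimal local alignments extend across
the full query instead of fragmenting below the 60% coverage cutoff,
while the expectation for unrelated sequences remains clearly negative
and random local islands stay far below the cutoffs. Subject residues
outside the 20-letter alphabet (X) score 0 and never count as identical
or positive.

### 3. The promiscuity matrix (`buildMatrix`)

Every function annotated on any tree member is a candidate promiscuous
function of the root, minus the root's own primary functions (the
matrix predicts *secondary* capabilities; keeping primaries would
create self-predictions downstream). Provenance keeps the
highest-identity carrier. When an entry matches one subunit role of an
enzyme complex, the whole-complex function is added too — a gene
similar to one subunit is predicted to supply the complex's activity.
Function identity is exact string match; no fuzzy EC matching.

### 4. Direct pairs, statistics, control (`predictDirectPairs`)

A pair (target, replacer) is emitted when the replacer's promiscuous
function equals the target's primary function; both genes must be in
scope and metabolic. Pairs whose genes also share a primary function
are *kept* and flagged `isozyme_by_annotation` — annotated isozymes are
exactly the pairs that experimental suppressor screens rediscover.
Descriptive statistics: distinct replacers per target (with histogram)
and reciprocal pairs ({a, b} such that both orientations are
predicted). The `blastControlPairs` baseline is a single-sequence,
single-round search against the metabolic genes at
annotation-transfer-grade stringency (identity $\ge$ 0.35, positives
$\ge$ 0.50, coverage $\ge$ 0.75, uncovered $\le$ 50) — what a
conventional search would confidently call a homolog. Its purpose is
the contrast: twilight-zone replacers that the iterative search
recruits are invisible to it.

### 5. FBA and indirect pairs (`fba`, `predictIndirectPairs`)

The model is a stoichiometric network with flux bounds,
gene-protein-reaction (GPR) boolean rules, a biomass objective and
named media. Conventions:

* exchange reactions touch exactly one metabolite; uptake is a negative
  lower bound; media store uptake magnitudes and `applyMedium` closes
  every exchange's uptake before opening the listed ones (idempotent);
* `knockoutGenes` closes reactions whose GPR (tokens, `and`, `or`,
  parentheses, case-insensitive) evaluates false; empty GPRs are
  untouched; genes in no GPR warn;
* `fba` maximizes biomass subject to $Sv = 0$ and the bounds with a
  dense two-phase simplex using Bland's anti-cycling rule — exact,
  deterministic, and adequate for the model sizes this package targets
  (tens to a few hundred reactions). Fixed variables (knocked-out
  reactions) are eliminated before the solve; equality rows are
  sign-normalized; leftover artificial variables are pivoted out
  between phases. Infinite bounds are clamped to $\pm 10^6$ and an
  optimum beyond $10^5$ raises an "unbounded" error, signalling a
  missing exchange constraint.

Growth means an optimum of at least `growthEpsilon` = 1e-6 flux units
("nominal production of biomass"; the threshold is declared policy —
an objective in [epsilon/10, epsilon) additionally warns that the call
is ambiguous). A gene is *conditionally essential* when its knockout
abolishes growth on the minimal medium but not on the rich one; only
such targets enter the indirect search, mirroring the preconditions of
the multicopy-suppression assay. For each (target, candidate function):
knock out the target on minimal medium, add all of the function's
catalog reactions (a function is a capability, possibly multi-reaction;
`perReaction = TRUE` tests them singly), re-optimize, and emit a pair
iff growth crosses the epsilon threshold. Candidates must be
non-native (not a primary function of any in-scope gene) and novel
(not already carried, up to positive scaling of the stoichiometry, by a
gene-associated model reaction). Added reactions keep their catalog
bounds — they are not opened to $\pm\infty$. Reactions introducing
metabolites unknown to the model are accepted only when they also touch
an existing metabolite; the new species are internal and still
mass-balanced, so a dead-end addition cannot carry flux and there is no
free-lunch rescue. Reactions entirely over unknown metabolites are
skipped with a logged reason.

### 6. Enrichment statistics

`hypergeomOverlapPvalue(N, K, n, k)` is the upper tail $P(X \ge k)$ of
the hypergeometric distribution, computed in log space; the drawing
unit (genes vs unordered pairs) is the caller's choice via
`overlapTest`. `reciprocityPvalue` is the closed form $r^m$ with $r$
estimated from the prediction set when not supplied. Published
background sizes for these tests are not reconstructible from the
literature, so the implementations are validated by exhaustive
enumeration rather than against printed p-values.

## The synthetic fixtures

`generateProteome` and `generateToyGem` are first-class, deterministic
generators (pure functions of the spec and seed) that stand in for a
multi-organism annotation database and a genome-scale model.

The reference proteome is 3 organisms x 50 genes of length 200.
Background sequences are i.i.d. uniform over the 20 residues, so two
background genes share ~5% identity in expectation — far below the 15%
identity gate — and a 200-column profile cannot reach 60% coverage on
them. Planted structure: four direct links at identities
0.45/0.35/0.25/0.20 (each foreign homolog carries a function that is
the primary annotation of a separate in-scope target gene), one
indirect link (a foreign vitamin-synthase-like function with no
in-scope target), two decoy links whose functions map to non-rescuing
catalog reactions, and the stepping-stone chain described above.
`mutateSequence` substitutes each position independently with
probability $1 -$ target identity and draws replacements
BLOSUM62-conditionally ($P(b \mid a) \propto e^{0.3\, s(a,b)},\ b \ne
a$): real divergent homologs substitute conservatively, and uniform
replacement would depress the positive-match fraction below the 0.30
gate even for genuine homologs, making the fixture a strawman.

What the fixture does *not* emulate: real amino-acid composition,
rate heterogeneity along the sequence, insertions/deletions between
homologs, domain shuffling, or the scale of a real database (thousands
of organisms). Passing the planted-recovery tests therefore shows the
engine's cutoff logic and iteration behave as designed in a controlled
regime; it does not certify recall on real proteomes.

The toy model plants a conditionally essential vitamin pathway: biomass
consumes activated carbon plus 0.1 unit of vitamin V; V is made by a
three-step chain A → I1 → I2 → V; the rich medium also supplies V
directly. Knocking out the middle chain gene kills growth on M9 only.
The catalog holds exactly one rescuing reaction (the one-step bypass
A → V) plus decoys: a dead-end producer, a duplicate of a native step,
and a reaction over unknown metabolites. With uptake 10 and the 1:0.1
biomass stoichiometry the wild-type M9 optimum is $10/1.1 = 9.0909$,
hand-checkable. An isozyme-redundant first step and a carbon-activation
gene provide the nonessential and always-essential classes.

## Reproducibility and problem sizes

Everything downstream of the generators is deterministic: reruns with
the same inputs and configuration produce byte-identical output
directories. The persisted pipeline log therefore records stages,
levels and counts but no wall-clock timestamps (those go to the console
stream only). The test suite and the acceptance script run the full
pipeline at the reference fixture size (150 sequences, ~48 root genes)
and the planted-recovery check across 10 seeds; these sizes were chosen
so the whole suite completes in minutes on a single CPU while leaving
every planted contrast (twilight-zone recruitment, stepping stones,
bypass rescue) clearly resolved.

## Known limitations

* The simplex solver is dense and unoptimized; genome-scale models with
  thousands of reactions would need a sparse LP backend behind the same
  `fba()` surface.
* One best local alignment per subject: coverage is computed from a
  single HSP, which is conservative for multi-domain proteins.
* The aligner is center-star progressive; for very heterogeneous
  member sets a profile-profile progressive scheme would be more
  accurate. An adapter seam exists in principle (any function mapping
  sequences to a gapped set can replace `alignSequences`), but the
  package deliberately ships no wrappers for external aligner binaries.
* Function matching is exact string equality on function ids, as in
  consistently annotated databases; free-text annotations would need
  normalization first.
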
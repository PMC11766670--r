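---
title: "Modelling secondary-structure evolution of the SSU rRNA V4 region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling secondary-structure evolution of the SSU rRNA V4 region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(v4evo)
```

## The biological question

The V4 region is the largest of the nine hypervariable regions of the
small-subunit (SSU) rRNA. In spirotrich ciliates such as *Euplotes* it
spans roughly 163–261 nt and folds into a handful of helices of the
eukaryotic E23 expansion. The largest of these, E23_8, varies between
two discrete architectures: a **Type I** structure ending in a single
terminal hairpin loop, and a **Type II** structure carrying two extra
distal sub-helices (E23_11 and E23_12) branching from a multiloop.
Because this is a heritable, discrete molecular character, it can be
mapped onto a phylogeny like any morphological trait: one can ask where
Type II arose, whether lineages ever reverted to Type I ("reverse
evolution"), and whether compensatory base changes (CBCs) in the paired
regions separate cryptic species that morphology cannot.

`v4evo` implements that analysis end to end: V4 extraction from
full-length SSU sequences, secondary-structure prediction (per-sequence
and alignment-consensus), rule-based curation, helix decomposition and
Type I/II classification, CBC counting, and parsimony ancestral-state
reconstruction with gain/reversal enumeration. A seeded simulator
generates cohorts with planted structural events so that every stage is
testable against known truth, offline.

## V4 extraction by anchored search

Covariance-model alignment tools locate V4 by aligning the whole SSU
gene. We replace that heavyweight step with a light equivalent: V4 is
bounded by strongly conserved flanks, so two flank *anchors* (~20 nt
each, majority-rule consensus of a reference alignment,
`build_anchor_profile()`) are located in each full-length sequence by
ungapped scanning (`locate_v4()`, match +1 / mismatch −1, `N` matches
nothing). The left anchor takes its best-scoring admissible placement
(ties leftmost); the right anchor the nearest admissible placement
downstream, which stops run-on regions in partial sequences. A
placement is admissible when its mismatch fraction is ≤ 0.2 — at 5%
flank divergence a 20-nt anchor carries one expected mismatch, so the
cap rejects almost nothing real while screening random matches, whose
expected identity is only 25%. Extraction is deterministic, and on
simulated data with undiverged flanks recovers planted coordinates
exactly. The occasional honest failure occurs when ≥5 of 20 anchor
positions mutate (probability ≈ 0.3% per anchor at 5% divergence).

## The folding model

Per-sequence structures are predicted by base-pair maximisation
(Nussinov-style dynamic programming) over a pair-score model:

| pair | score |
|------|-------|
| G:C / C:G | 3 |
| A:U / U:A | 2 |
| G:U / U:G (wobble) | 1 |

with a minimum hairpin of 3 unpaired nt (the steric minimum), no
pseudoknots, and `N` unpairable. This is a deliberate, declared
surrogate for a thermodynamic nearest-neighbour model: it keeps every
algorithmic property exactly testable (the DP optimum is verified
against exhaustive enumeration in the test suite), at the price of
model-dependent per-species structures. Traceback is deterministic —
prefer leaving the 5' residue unpaired, then the smallest pairing
partner — which biases ties toward local stems and yields one canonical
optimum per input.

Consensus folding (`fold_consensus()`) runs the same DP on alignment
columns. The score of pairing columns *(k, l)* sums per-row pair
scores, adds `covariance_bonus` (default 1) per distinct canonical pair
type beyond the first — compensatory variation is evidence *for* a
conserved pair — and subtracts `inconsistency_penalty` (default 0.5)
per row that cannot pair there, gaps counting as cannot-pair.
Non-positive column pairs are forbidden. `project_consensus()` maps the
column structure through one row's gap pattern, dropping pairs with a
gapped or non-pairing residue; projection can never introduce crossing
pairs.

### Lone-pair suppression

A pure pair-count objective happily places isolated base pairs wherever
two residues are complementary. Thermodynamic folders suppress such
lone pairs (they contribute no stacking energy) and published structure
models never draw them. `drop_lone_pairs()` removes helices shorter
than 2 pairs, and the pipeline applies it to every structure that is
interpreted topologically — consensus and per-species alike. Without
it, stray single pairs at realistic divergence merge top-level stems
and fabricate distal "helices", corrupting classification; with it, the
DP contract (`fold_mfe()` returns the score-optimal structure) is
unchanged.

### Curation rules

Predicted structures are curated by two rules, iterated to a fixed
point (which makes `curate()` idempotent by construction):

1. a 1×1 bilateral internal loop whose two unpaired residues are G and
   C (either orientation) is closed into a pair — larger loops are
   never touched;
2. any helix containing ≥ 2 non-canonical pairs (anything outside
   G:C/A:U/G:U) is removed whole.

When several candidate structures exist, `select_structure()` imposes a
total, deterministic order: higher score, then higher base-pair F1
against the reference, then lexicographically smallest dot-bracket.
The F1 criterion is our operationalisation of "best compatibility with
similar sequences", which no published procedure quantifies.

### Two classification routes

`run_v4_pipeline()` can source the per-species structure two ways. The
**reference-guided** route (default whenever an alignment is available)
curates the consensus structure projected onto each taxon — the
workflow used in comparative rRNA studies, where the consensus anchors
every species' model. On simulated cohorts at realistic divergence this
recovers planted types essentially perfectly, because block
presence/absence is carried by the alignment itself. The **mfe** route
folds each sequence free of the reference and arbitrates candidates
with `select_structure()`; it exposes the surrogate folding model
directly and is the only option without an alignment. Its type
recovery degrades with divergence (roughly 60–95% on 20-taxon cohorts
at ~5% V4 divergence) — a limitation of the pair-score model, not of
the classification logic, and the reason the guided route is the
default.

## Topology: stems, E23_8, and the Type I/II call

`find_helices()` partitions the pair set into maximal stacked runs and
links them into a nesting forest. `group_stems()` merges helices
separated by internal loops/bulges of ≤ `bulge_tol` (default 3) nt per
side into stems — the units drawn as single helices in structure
figures — while multiloops always break stems. Published figures give
no coordinate definition of which stem is E23_8, so the rule is
explicit and configurable (`label_e23()`): by default the top-level
stem with the greatest pair count (ties 3'-most), with `"last"` and
positional alternatives.

`classify_v4()` walks distally from E23_8 through single-child internal
loops of any size and inspects the terminus: a hairpin gives
`TYPE_I` (with its loop size in nt), a multiloop with ≥ 2 child helices
gives `TYPE_II` (the count is reported, so the canonical two-helix
E23_11/E23_12 case is distinguishable); pairless structures are
`UNCLASSIFIED`. Because the walk passes internal loops of any size, the
call is insensitive to `bulge_tol` and to unpaired sequence outside
E23_8.

## CBC counting

At a paired column duo, a **CBC** between two taxa means both partners
differ while pairing (canonical or wobble) is preserved in each taxon;
a **hemi-CBC** changes exactly one partner with pairing preserved.
Columns with a gap or `N`, or where either taxon's duo cannot pair, are
skipped and reported rather than counted — the statistic is about
changes in conserved bonds, not unpaired divergence. `count_cbc()`
classifies every pair column (`same` / `CBC` / `hCBC` / skipped);
`cbc_matrix()` assembles the symmetric pairwise matrix. The verdict
table is validated against an independently coded oracle over all 256
residue combinations. By default the whole V4 pair set is compared;
`restrict_pair_columns()` confines the analysis to one labelled stem
(e.g. E23_8). A CBC ≥ 1 between morphologically indistinguishable taxa
is the classical signal of cryptic speciation; the package reports
counts and leaves the species decision to the user.

## Ancestral states, gains, and reversals

`fitch_asr()` reconstructs the binary Type I/II character on a rooted
tree by unit-cost minimum-change dynamic programming (the Sankoff
recursion), which equals Fitch parsimony on binary trees and handles
polytomies exactly; tips without states are pruned with a message.
Per-node state sets are the MPR sets — the states a node takes in at
least one most-parsimonious reconstruction. Step counts are verified
in the tests against exhaustive minimisation over all internal
labellings and against an independent parsimony implementation.

`resolve_asr()` produces one state per node. All rules pick from the
minimisers of (subtree cost + mismatch with the resolved parent), so
every rule attains the parsimony length: `DELTRAN` (default) keeps the
parent's state when possible, pushing changes tipward; `ACCTRAN`
prefers change, pulling transformations rootward; `prefer-ancestral`
keeps the parent's state whenever it lies in the node's MPR set. Root
ties resolve to the alphabetically first state — `TYPE_I`, the simpler,
prokaryote-like condition. The choice of rule can matter for the
reverse-evolution question: a Type I island sitting at the edge of a
Type II clade can often be explained equally well by parallel gains
(DELTRAN's preference) or by a gain plus a reversal (ACCTRAN's); only
islands nested deeply enough that the reversal explanation is strictly
shorter are reported as reversals under every rule. `reversal_report()`
lists each `TYPE_II → TYPE_I` edge with the tip set beneath it.

## The simulator and its fixture

`simulate_v4()` generates the data the analysis assumes. A hand-built
V4 template with four top-level stems — the largest (20 pairs, GC
stems) being E23_8 with a 21-nt terminal hairpin, matching the size
seen in basal *Euplotes* clades — sits between conserved flanks. The
Type II condition inserts a fixed 31-nt block into that loop that folds
into two hairpins, creating the distal two-helix multiloop; the block
literal was designed so that classification succeeds from folding alone
on undiverged sequences. Evolution proceeds down a Yule tree (or a
supplied tree): unpaired sites mutate freely; a stem substitution is
instantaneously compensated on its partner with probability
`stem_comp_fraction` (default 0.8 — rRNA stems are largely
compensated, which is the premise of the CBC concept); the
E23_11/E23_12 block toggles with per-branch probability
`helix_block_indel_rate` (default 0.05); flanks receive iid per-tip
noise (`flank_mut`, default 2%). Forced toggles and forced CBCs can be
planted on named lineages, and every event is logged so tips replay
exactly from the root — a property the tests assert.

Defaults describe the study conditions being emulated: a few tens of
taxa, V4 lengths of 166 (Type I) and 197 nt (Type II) inside the
observed 163–261 nt range, ~1.8-kb full-length sequences, root state
Type I (the ancestral condition), and mostly-compensated stems. What
the simulator does **not** emulate: realistic SSU covariance structure,
indels other than the single block and none in the flanks, rate
heterogeneity among sites, and base composition — so passing tests
demonstrate algorithmic correctness and recoverability under the stated
generative model, not performance on arbitrary real alignments.

`fixture_mini_cohort()` is the deterministic 12-taxon cohort used
throughout the tests: root Type I, one block gain on the edge to the
`t03..t12` clade, reversals on the terminal branches of `t07` and
`t12`, and one planted CBC on `t12` (echoing the single deviant taxon
of the youngest clade in the motivating system). Both reversal
lineages are nested deeply enough inside the Type II clade (four
independent Type II cherries against two single-tip islands) that the
gain-plus-reversals history is strictly shorter than any parallel-gain
alternative — so recovery does not depend on the resolution rule.
Background substitution is light and uncompensated and no random
toggles occur, making the planted events the complete structural
history.

In the seeded reversal-recovery experiment the background toggle rate
is 0.005 per branch ("low noise": ≈ 0.11 expected extra structural
events per 22-branch replicate), so the planted gain-plus-reversal
remains the dominant history in almost every replicate.

## Numerical conventions and problem sizes

* Coordinates are 1-based with closed intervals throughout, the
  R/Bioconductor convention; dot-bracket is the structure interchange
  format (Vienna files; CT read-only).
* All randomness flows from a single mandatory seed per simulation;
  identical inputs give byte-identical outputs, including folding
  tracebacks.
* Degenerate IUPAC codes collapse to `N`, which never pairs; `T`
  silently becomes `U`.
* Test problem sizes were chosen to keep exhaustive oracles exact and
  the suite fast: folding is enumerated for sequences ≤ 16 nt (300
  cases), parsimony for trees ≤ 8 tips (200 cases), CBC over the full
  4^4 duo table, recovery experiments at 100 seeded replicates, and
  pipeline checks on the 12-taxon fixture.

## Known limitations

* The pair-score model is not a free-energy model: absolute scores are
  dimensionless and per-species structures can differ from
  thermodynamic predictions (base-pair F1 against a thermodynamic
  folder on simulated V4s is typically ~0.6). Printed loop sizes from
  thermodynamic studies reproduce only where structure is strongly
  determined (e.g. the template's 21-nt hairpin).
* Anchored extraction assumes conserved, unindented flanks; heavily
  gapped or truncated flanks defeat it (such sequences are dropped with
  a logged reason, never silently).
* The E23 labelling is heuristic by necessity; the `largest` rule is a
  declared convention, not a homology statement.
* Parsimony reversals are resolution-rule-dependent in the boundary
  cases described above; the package exposes all three rules rather
  than hiding the choice.
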
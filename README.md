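# v4evo

Secondary-structure evolution of the SSU rRNA V4 hypervariable region,
as a tested, reproducible R pipeline.

## The problem

In ciliates such as *Euplotes*, the V4 region of the small-subunit
(SSU) rRNA (163–261 nt) folds into the helices of the eukaryotic E23
expansion. Its largest helix, E23_8, occurs in two discrete
architectures: **Type I**, ending in a single terminal hairpin loop,
and **Type II**, carrying two extra distal sub-helices (E23_11/E23_12)
on a multiloop. Treated as a binary character on a phylogeny, this
structure lets one ask where the Type II elaboration arose, whether
derived lineages reverted to Type I (reverse evolution), and whether
compensatory base changes (CBCs) in paired positions separate cryptic
species. `v4evo` is aimed at molecular systematists who want that
analysis scripted and testable rather than assembled by hand from
alignment viewers, folding servers, and tree editors.

## What it computes

* **Extraction** — V4 located in full-length SSU sequences by two
  conserved flank anchors (ungapped scan, match +1 / mismatch −1,
  mismatch fraction ≤ 0.2), anchors built as the majority-rule
  consensus of any reference alignment.
* **Folding** — base-pair maximisation by dynamic programming with
  scores s(G:C) = 3, s(A:U) = 2, s(G:U) = 1, minimum hairpin 3, no
  pseudoknots; consensus folding on alignment columns adds a covariance
  bonus per extra canonical pair type and an inconsistency penalty per
  non-pairing row. Curation closes 1×1 G:C internal loops and removes
  helices with ≥ 2 non-canonical pairs; isolated lone pairs are
  suppressed before any topological interpretation.
* **Classification** — helix decomposition into stems, E23_8
  designation (largest top-level stem by default), distal walk ending
  in a hairpin (Type I, loop size reported) or a ≥ 2-helix multiloop
  (Type II).
* **CBC analysis** — per pair column: CBC iff both partners differ and
  both taxa still pair (canonically or wobble), hemi-CBC iff exactly
  one side differs; gap/N and non-pairing columns skipped, pairwise
  matrix over any taxon set.
* **Ancestral states** — unit-cost minimum-change (Fitch) parsimony
  with MPR state sets, DELTRAN/ACCTRAN/prefer-ancestral resolution, and
  a report of every Type II → Type I reversal edge with its descendant
  tips.
* **Simulation** — seeded generator of trees, sequences, alignments and
  event logs with planted gains, reversals and CBCs, used by the test
  suite as ground truth.

## Worked example

The packaged 12-taxon cohort carries a planted history: root Type I,
one gain of the two-helix block, two later reversals (`t07`, `t12`),
and one planted CBC on `t12`.

```r
library(v4evo)

fx  <- fixture_mini_cohort()
run <- run_v4_pipeline(fx$sequences, fx$tree, sim_anchor_profile(fx),
                       alignment = fx$v4_alignment)
run
#> <v4_run> 12/12 taxa retained; 4 Type I, 8 Type II; parsimony length 3 (2 reversal(s))

summarize_by_clade(run)
#> # A tibble: 3 × 6
#>   clade     n n_type_i n_type_ii hairpin_min hairpin_max
#>   <chr> <int>    <int>     <int>       <int>       <int>
#> 1 A         2        2         0          21          21
#> 2 B         5        1         4          21          21
#> 3 C         5        1         4          21          21

reversal_report(run$asr)
#> # A tibble: 2 × 5
#>    node from    to     n_tips_below tips_below
#>   <int> <chr>   <chr>         <int> <chr>
#> 1     7 TYPE_II TYPE_I            1 t07
#> 2    12 TYPE_II TYPE_I            1 t12

run$cbc$cbc["t12", c("t09", "t10", "t11")]
#> t09 t10 t11
#>   1   1   1
```

Reading the output: all 12 taxa pass extraction and classification; the
basal clade A retains the ancestral Type I structure with its 21-nt
terminal hairpin; the most parsimonious history needs 3 steps — one
gain of the Type II block and two reversals, exactly the planted edges
above `t07` and `t12`; and `t12`, the lone Type I deviant of its clade,
shows one CBC against every other taxon — the classical cryptic-species
signal. `autoplot(run$asr)` draws the state-painted tree,
`autoplot(run$structures[["t01"]])` an arc diagram of a per-taxon
structure, and `autoplot(run$cbc)` the CBC heatmap; `tidy()` and
`glance()` return the underlying tibbles.

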
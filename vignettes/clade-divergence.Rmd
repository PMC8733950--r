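---
title: "Testing differential divergence between paralogous clades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing differential divergence between paralogous clades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladediv)
```

## The question and the model

A gene duplication creates two paralogous clades that afterwards evolve
independently. If one copy keeps the ancestral function, purifying selection
limits its divergence during the subsequent speciations; the other copy may
drift, neofunctionalize or decay and accumulate changes faster. `cladediv`
turns that asymmetry into a testable contrast: it treats the multiset of
branch lengths *inside* each clade as a sample of per-lineage divergence and
asks whether the two samples differ in location.

Branch lengths are used rather than leaf-to-leaf (pairwise patristic)
distances because a single internal edge contributes to many leaf pairs: an
outlier edge would be counted once in our sample but quadratically often in
a pairwise-distance scheme. Each edge is one observation.

The null hypothesis is "the two clades did not diverge differentially
within the clade", with no direction assumed, so all three tests are
two-sided. The reported statistics follow the convention *first clade minus
second*: a negative t means clade A is the less diverged one.

Three tests are reported side by side rather than combined, because they
guard against different violations: Student's t is the reference under
normality and equal variances; Welch's t drops the equal-variance
assumption (its Welch–Satterthwaite df is never larger than the pooled df);
Mann–Whitney U drops normality altogether. No multiple-testing correction is
applied across the three — they are three views of one comparison, not three
hypotheses. A report consumer should pick the test whose assumptions fit and
read the other two as sensitivity checks.

## What goes into the samples

For a selected clade (an internal node plus its subtree, at least two
leaves) the sample contains the length of every edge strictly inside the
subtree, as a multiset — repeated values are data, not duplicates. The stem
edge, which connects the clade root to the duplication node, is excluded by
default: it measures how far the duplicate itself drifted before the
within-clade speciations began, not divergence during them. Both readings
are computable; `include_stem = TRUE` adds the stem to each sample.

Zero-length edges are legal observations. Negative edge lengths (which
neighbour-joining can produce) are accepted with a warning and enter the
sample as-is: silently altering the user's data would be worse than an
honest warning. Missing branch lengths, by contrast, are a hard parse
error — the tests are meaningless without lengths, and zero-filling would
fabricate data, so no escape hatch is provided.

## Species restriction, representatives, pruning

When leaf labels embed a species identifier, a user regex (first match in
the label, substring semantics — e.g. `taxid.[0-9]+`) maps leaves to
species. The comparison is then restricted to the species present in *both*
clades, for a matched contrast; unmatched leaves are excluded with a warning
by default (an `error` policy is available for strict runs).

If a species contributes several leaves to one clade (in-paralogs,
isoforms, redundant database entries), only its *least diverged* leaf is
kept: the one with the smallest path distance to the clade root. A more
diverged within-species copy is the likelier product of relaxed selection or
sequencing artefacts, and would contaminate the clade-level signal. Distance
is measured to the **clade** root, not the tree root: every leaf of a fixed
clade shares the path above the clade root, so both readings order leaves
identically, and the clade-root reading keeps the choice independent of
whatever sits above the duplication node. Ties are broken by lexicographic
leaf label (C locale), making the selection deterministic and
permutation-invariant.

Each clade is then pruned to its representatives of the common species.
Pruning removes the other leaves, deletes emptied internal nodes, and
suppresses unifurcations by merging the two incident edges into one edge
carrying the summed length; if the old clade root is left with a single
child, the result is re-rooted at the MRCA of the kept leaves. The defining
contract — checked property-style in the test suite against brute-force
path sums — is that the patristic distance between any two kept leaves is
bit-for-bit the sum it was before pruning. The stem length of a pruned
clade is defined as the original stem plus any collapsed path between the
old clade root and the new root, so the stem-inclusion flag stays
well-defined after pruning.

The species-set (Venn/superset) summary is always computed on the *full*,
unpruned clades: it describes clade content, not the pruned comparison. A
clade is called a superset only when the other side has no unique species
and the intersection is nonempty — a "superset" over a disjoint pair would
be vacuous. A superset clade's gene is the more likely essential copy, since
it was retained in every lineage sampled.

## Numerical choices in the tests

- t tail probabilities come from the t distribution via `pt`, i.e. the
  regularized incomplete beta function of base R's math library.
- The Mann–Whitney statistic is U1 (first sample), from midrank sums.
  Exactness switch: tie-free samples with `n1 + n2 ≤ 16` get the exact
  two-sided p — the null probability of a U at least as far from
  `n1·n2/2` as observed, computed from the exact U distribution
  (`dwilcox`); at most `choose(16, 8) = 12870` assignments are involved,
  and the suite cross-checks this path against a literal enumeration of
  all assignments. Ties, whose exact treatment is ill-defined without a
  permutation machinery, or larger samples, fall back to the normal
  approximation with tie-corrected variance and 0.5 continuity correction.
- Degenerate inputs fail per test, not per analysis: constant samples make
  the t tests error (zero pooled variance) while the U test still reports;
  only if all three tests fail does the analysis abort.
- p-values are reported as raw floats with no floor, but the JSON report
  adds a `p_display` string of `"< 1e-15"` below representable precision,
  since a displayed `0` would overstate certainty.

## Clade selection semantics

Clades are designated by a leaf set (their MRCA is the clade root) or an
internal node label. The two clades must be disjoint; nesting or overlap is
an error because the samples would share edges. They are *not* required to
be sisters — trees with intervening nodes between the two paralog groups
are common — but a warning is raised when the clade roots are not siblings,
as the contrast is designed for the two sides of a single duplication node,
which the user must identify. The input tree's rooting is taken as
meaningful; the package never re-roots.

## The simulator and what passing tests do (and do not) show

`simulate_duplicated_tree()` builds one random species topology on `k`
leaves by uniform random joins, instantiates it twice under a common root
(the duplication node), and draws every edge length i.i.d. from a base
distribution — exponential with mean 0.1 substitutions/site by default,
positive and right-skewed like empirical gene-tree branch lengths; a
fixed-length mode exists for deterministic unit checks. All clade A edges
are multiplied by `rate_a` and clade B edges by `rate_b`, so the rate ratio
is the true effect size; optional species dropout in clade B emulates the
loss of a dispensable duplicate in some lineages and yields ground truth
for the superset analysis. Identical specifications (including the seed)
produce byte-identical Newick output.

The suite and the acceptance script use this generator at desk scale:
`k = 20` species (38 branch lengths per clade), 500 replicates for the
null — each test's empirical size at α = 0.05 is required to land in
[0.02, 0.09] — and 200 replicates at a threefold rate ratio, where
Mann–Whitney power must reach 0.90 and the mean Student t must be negative
(the sign convention under a less-diverged first clade). These sizes give
stable rates in seconds; they are the package's own calibration conditions.

What the simulator does *not* emulate: sequence-level evolution (alignment
noise, site-rate heterogeneity, tree-inference error), non-i.i.d. branch
lengths along a lineage, gene birth–death within clades, or asymmetric
topologies between the two paralog groups (the two clades share one species
topology by construction, which is exactly the matched design the
common-species restriction produces on real data). Passing the calibration
therefore shows the *statistics and plumbing* behave correctly on
branch-length data with known truth — it does not certify performance on
trees whose branch lengths are themselves poorly estimated. Garbage
lengths in, garbage inference out.

## Known limitations

- One node pair per run: the user must know the duplication node. Scanning
  all duplication nodes of a tree is out of scope.
- Branch-length samples within a clade are treated as exchangeable
  observations; phylogenetic autocorrelation along paths is ignored, as in
  any edge-as-observation scheme.
- The exact U path requires tie-free data; heavily tied (e.g. heavily
  rounded) branch lengths always take the approximation.
- Species extraction is purely lexical; no taxonomy service is consulted.

## Worked run

```{r example}
tree <- parse_newick(
  "((g1_sp1:0.1,g1_sp2:0.2):0.05,(g2_sp1:0.4,g2_sp2:0.6):0.05);")
cfg <- analysis_config(clade_a = c("g1_sp1", "g1_sp2"),
                       clade_b = c("g2_sp1", "g2_sp2"),
                       species_pattern = "sp[0-9]+")
compare_clades(tree, cfg)
```

```{r power}
power_sweep(sim_spec(k = 10, rate_b = 3, seed = 7), replicates = 50)
```
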
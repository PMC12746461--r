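---
title: "Representative random sampling of chemical space: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representative random sampling of chemical space: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrspace)
```

## The problem

A chemical space is the set of all molecules that can be assembled from a
set of atom types — pairs (element, valence) — within an atom-count
window, under plain valence-bond rules: every molecule is a connected,
loop-free, undirected multigraph whose vertex degrees (counting bond
orders) equal the atom valences.  Such spaces grow far too quickly for
full enumeration, yet most empirical statements about "chemical space"
are made from databases that cover a thin, biased slice of it.  This
package provides the machinery to (a) enumerate all feasible sum
formulas of a space, (b) estimate how many distinct molecular graphs
each formula admits *without* enumerating them, (c) draw approximately
uniform random molecules across the whole space, and (d) score how
representative an existing molecule collection is of its underlying
space.

Elements are opaque labels here.  Only the valence enters the
combinatorics, which is the central symmetry the method exploits: any
relabeling of equally-bonding elements yields the same set of distinct
graphs, so results computed once for a *degree sequence* can be reused
for every stoichiometry that maps onto it.

## Formula enumeration

Formulas are generated by a two-stage nested integer partition.  For a
total atom count, the count is first distributed over the ordered
valence types (compositions, not unordered partitions, because each part
is tied to a specific valence); a composition survives only if its
degree sum is even and the degree multiset is realizable as a connected
loop-free multigraph.  The realizability test is: at least two atoms,
even degree sum $M$, maximum degree at most the sum of the others, and
$M/2 \ge N_a - 1$ bonds.  We validated this predicate against exhaustive
multigraph enumeration on small cases rather than taking it on faith.
Each surviving composition is then refined by partitioning the atoms of
each valence type over the elements of that type.  The result equals the
one-stage partition of all atoms over all atom types (a property the
test suite asserts on every fixture space), but only generates distinct
cases once.

```{r formulas}
sp <- chemical_space(c("C", "H", "F"), c(4, 1, 1), natoms = c(2, 8))
head(formula_table(sp))
```

## Counting molecular graphs per formula

Within one formula, molecules are *protomolecules*: multigraphs whose
vertices carry element-slot labels (placeholders per valence) rather
than concrete elements.  A labeled degree sequence is *pure* if each
valence has a single slot.  Counting proceeds through four tiers, most
accurate first:

1. **exact** — exhaustive enumeration with canonical-form deduplication
   (igraph/BLISS on a colored parallel-edge expansion).  The enumerator
   grows graphs one bond unit at a time, always incident to the
   lowest-index unsaturated vertex, deduplicating partial states per
   level; this is complete because any target graph admits a build order
   obeying the rule and isomorphic partial states have isomorphic
   completion sets.  It is deliberately simple: its role is to be the
   oracle every estimator is tested against.  The default cap is 10
   atoms; known-small universes may raise it explicitly.
2. **base** — the universe graph $U(d)$ has one vertex per protomolecule
   and edges between graphs at minimal edit distance.  It behaves like a
   small-world network, so its average path length $l_G$ tracks
   $\log|U(d)|$.  We measure $l_G$ as the mean pairwise minimal edit
   distance over sampled graph pairs and invert the calibrated relation
   $\log|U(d)| = a_7\, l_G + b_7$.
3. **pure** — for a nonpure sequence whose pure counterpart has a known
   $l_G$, the multiplier
   $N_P(d)=\prod_v \prod_i \binom{\sum_{j\ge i} c_j}{c_i}$ counts the
   element-placement combinations under the assumption that large random
   graphs are asymmetric; it enters through
   $l_G(d) = \left(1 + \frac{\log N_P(d)}{\sum_i d_i}\right) l_G(d_U)$,
   with no additional fitting.
4. **asymptotic** — for large pure sequences, the asymptotic count of
   loop-free multigraphs with given degrees
   ($G = \frac{M!}{(M/2)!\,2^{M/2}\,k_1!\cdots k_n!}\,e^{\text{corr}}$,
   evaluated in log space) is mapped to a path length through the second
   calibrated relation $l_G = a_{10}\log G + b_{10}$ and then treated as
   the pure tier.  Because the relation keeps growing as monovalent
   atoms are added while the true count must fall once the double-bond
   equivalents reach zero, the count is divided by $t!$, where $t$ is
   the number of monovalent atoms in excess of the minimum feasible for
   the sequence's heavy-atom profile.  The baseline of $t$ is a design
   choice (the trend, not the anchor, is established); it is isolated in
   `excess_monovalent()` so alternatives can be swapped.

All logarithms are natural.  The convention is self-consistent because
both relations are refittable from local exact data
(`refit_calibration()`); the shipped defaults
($a_7 = 1.220$, $b_7 = -0.7295$, $a_{10} = 0.7561$, $b_{10} = -14.40$)
are reference fits obtained at database scale (hundreds of thousands of
degree sequences), not desk-scale values.  On the bundled fixture suite
(21 degree sequences, universe sizes 2–122) a local refit recovers a
positive slope with $R^2 \approx 0.9$ and places every sequence within
one order of magnitude — a scaled-down analogue of the ~73%
order-of-magnitude rate reported at database scale, on far easier
problems.  Desk-scale universes barely span two decades, so `strict =
FALSE` is appropriate when refitting on them.

```{r counts}
d <- degree_seq(c(4, 1), c(4, 10))      # four tetravalent, ten monovalent
count_exact(d, cap = 14)                # butane + isobutane skeletons
nonpure_multiplier(degree_seq(c(4, 1, 1), c(1, 2, 2)))  # CH2F2 family
```

### Edit distances

The ground cost between two graphs of one degree sequence is the
minimal, over slot-respecting vertex permutations, L1 transport cost
between their bond-order matrices, halved — i.e. the number of
unit bond edits.  The L1 choice is a documented convention (the metric
underlying the "minimal transport between permuted adjacency matrices"
idea admits several ground costs); it is isolated in `permuted_cost()`.
Below 100 slot-respecting permutations the minimum is exact by brute
force; above, six heuristics run under a per-heuristic call budget
(default 50): random shuffling, pairwise-switch descent, 2-opt over all
transpositions, per-element-class optimization in one and in repeated
scans, and a depth-first branch-and-bound.  Heuristics only ever
overestimate; on fixture pairs where the exact oracle is available they
hit the true minimum in well over 90% of cases.  Pairs are canonically
ordered before searching, making the call symmetric; a seed makes it
deterministic.

## Sampling

Sampling is two-stage: a formula is drawn with probability proportional
to its (estimated) count, then a graph is drawn within the formula by a
degree-preserving Markov chain over connected loop-free multigraphs,
started from a stub-matching realization (biased, which the chain
removes).  The move is a double edge swap on two bond units; proposals
creating loops or disconnecting the graph are rejected.

Two details matter and are easy to get wrong:

* **Multiplicity asymmetry.**  Picking bond *units* makes the raw
  proposal asymmetric in bond orders (choosing an edge of order $m$ can
  happen $m$ ways), so a Metropolis–Hastings factor
  $\frac{(m_{ac}+1)(m_{bd}+1)}{m_{ab}\,m_{cd}}$ restores uniformity over
  vertex-labeled multigraphs.
* **Automorphism correction.**  Uniformity over *labeled* graphs weights
  an isomorphism class by the number of its labelings, i.e. inversely by
  its automorphism-group order $|\mathrm{Aut}(G)|$.  Because the
  uniformity claim is at class level, the default target is
  $\pi(G) \propto |\mathrm{Aut}(G)|$, which makes classes equiprobable.
  $|\mathrm{Aut}|$ is computed exactly (igraph/BLISS) and memoized per
  chain.  For large molecules, where nontrivial automorphisms are rare,
  the correction can be switched off (`aut_correction = FALSE`) and the
  chain targets the labeled-uniform law — the regime in which both laws
  coincide.  Both modes are provided because class-level correction is a
  genuine modeling choice: we verified empirically (universe of the
  butane/isobutane pair) that the corrected chain is uniform over
  classes while the uncorrected one reproduces the $1/|\mathrm{Aut}|$
  weights.

Chain schedule: burn-in $10E$ and thinning $5E$ steps ($E$ = bond
units).  The thinning was chosen by measuring lag-1 autocorrelation of
class indicators on the validation fixtures (≈0.5 at $1E$, ≈0.04 at
$5E$); draws are then close enough to independent for multinomial
envelopes and chi-square tests to apply at their nominal levels.  One
master seed drives everything; per-formula chains are independent.

```{r sampling}
fx_space <- chemical_space(c("C", "H"), c(4, 1), c(2, 5))
smp <- sample_space(fx_space, 5, config = sampler_config(seed = 11))
vapply(smp, function(m) write_smiles(m), character(1))
```

## Validation diagnostics

Two diagnostics reproduce the canonical uniformity tests on enumerable
fixtures:

* `sorted_frequency_curve()` — per-class frequencies normalized to unit
  uniform expectation, sorted ascending, against a Monte-Carlo envelope.
  The envelope is a *global rank envelope*: simulated uniform curves are
  scored by their most extreme pointwise rank and the most extreme
  (1 − level) are dropped, so the whole curve stays inside with
  approximately the nominal probability (pointwise quantile bands would
  undercover jointly).  The band always contains the ideal flat curve:
  being closer to perfect uniformity than multinomial noise is never
  evidence of bias.  Sample keys outside the enumerated universe are a
  hard error — that is a sampler bug, not a statistical fluctuation.
* `stoichiometry_frequency()` — per-formula frequencies normalized by
  the formula's share of the total count; uniform sampling gives values
  near 1 with binomial standard scores.

The bundled fixture generator (`make_fixtures()`) provides the ground
truth: five deterministic spaces with at most 8 atoms and fully
enumerated universes, including a joint set of five stoichiometries
(C4H4, C4H3F, C4H2F2, C4HF3, C6H2 — 162 graphs) that mirrors the scale
of the canonical five-stoichiometry/175-graph uniformity experiment.
With 6000 samples the sorted curve sits inside the 99% envelope, the
chi-square test against uniformity is non-significant at α = 0.01, and
all per-formula normalized frequencies are within a few percent of 1.
C4H3F and C4HF3 deliberately share one labeled degree sequence, so
class identity in these tests is (formula, canonical graph key).

## Database comparison

`compare_database()` groups molecules by stoichiometry (atom types from
element + realized valence, so trivalent and pentavalent nitrogen are
distinct types), sorts all stoichiometries of the reference space by
their estimated size (ties broken by formula key), and accumulates both
the space counts and the database counts over that common support into
CDFs.  The KS statistic is the maximum absolute CDF difference; the KL
divergence $\sum_x P(x)\log(P(x)/Q(x))$ takes the space as $P$ and the
database as $Q$, flooring empty database bins at a configurable
$\varepsilon$ (default $1/(10\cdot\text{total space count})$) and
flagging when the floor was hit, since such terms inflate the metric.
`subsample_curve()` traces mean KS against the sampled fraction — the
lower-bound-on-database-size diagnostic.  Molecules arrive as graph
JSON, SDF V2000, or SMILES (converted to explicit-hydrogen form via
OpenBabel; unparseable records are skipped and counted).

## Scope and limitations

* The generator's universe is *topological*: no stability, energy, 3D
  embedding, charge, radical or isotope information.  A uniform sample
  of graphs is a uniform sample of possible bonding topologies, not of
  stable compounds.
* Estimated tiers carry an irreducible per-formula bias (the small-world
  relation is a correlation, not an identity); aggregate counts over
  many formulas are more trustworthy than any single one, and passing
  fixture tests demonstrates correctness of the machinery at desk
  scale, not accuracy of the asymptotic tier at 30+ atoms.
* Exact enumeration and exact automorphism counting limit the
  class-corrected sampler to desk-scale molecules; the uncorrected
  chain has no such limit.
* Fixture problem sizes (≤ 8–14 atoms, universes ≤ ~200 graphs, 6000
  samples, 40 distance pairs per sequence) were chosen so the whole
  validation suite runs in minutes on one core while keeping every
  statistical test at its nominal level.
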
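---
title: "Methods: ligand-independent 3D residue-pattern similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-independent 3D residue-pattern similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patternsim)
```

## The model

`patternsim` treats a protein structure as a cloud of residue points: each
standard amino acid is reduced to the geometric center of its side-chain
heavy atoms. Everything downstream — grid construction, pattern growth,
descriptors, scoring — sees only these centers and the residue types. This
is a deliberate abstraction: it makes the method independent of ligands,
of sequence order, and of any superposition, at the cost of discarding
backbone orientation and atomic detail.

The unit of comparison is the **3D pattern**: a set of residues anchored
to one *virtual reference coordinate*. Reference coordinates are the
midpoints of all residue pairs whose centers lie within the grid radius
$G_r$ of each other. Anchoring patterns to pair midpoints, rather than to
residues themselves, lets patterns be centered on cavities and interfaces
— the places where binding sites live — without any pocket-detection
heuristic.

From each grid point $g$, the candidate pattern is every residue whose
center distance to $g$ lies in $[N_t, F_t]$; candidates are then pruned
until all pairwise center distances are at most $F_t$. $F_t$ thus plays a
double role — maximum anchor distance and maximum pattern diameter — which
is the only reading that satisfies both threshold definitions
simultaneously.

Each pattern of $n$ residues is summarized by four descriptors, and two
patterns are compared only through them:

* **Dist**: the multiset of $n(n-1)/2$ tokens such as `L5R` (pair of
  one-letter codes around the rounded distance). Captures internal
  geometry plus composition.
* **NbE**: the sum of tabulated per-residue short+medium-range non-bonded
  energies. A scalar composition fingerprint.
* **Sc**: the multiset of eight physicochemical categories (aliphatic,
  aromatic, hydroxyl, acidic, acid amide, basic, sulphur, cyclic).
  Composition at coarse granularity.
* **Tsp**: the perimeter — the tokens of the edges of the shortest closed
  tour through the $n$ centers. A shape signature that is far more
  sensitive to rearrangement than Dist, because a single displaced residue
  can reroute the whole tour.

The GScore of a pattern pair is the weighted mean of the four partial
similarities (token-multiset overlaps for Dist/Tsp/Sc, a magnitude ratio
for NbE), each in $[0, 100]$, with weights summing to 100.

## Parameters

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| $G_r$ (`gr`) | Å | 10 | max center-center distance for a pair to seed a grid point; controls exploration density |
| $N_t$ (`nt`) | Å | 3 | min residue-to-anchor distance; small values admit residues hugging the anchor |
| $F_t$ (`ft`) | Å | 10 | max residue-to-anchor distance *and* max pattern diameter |
| `min_residues` | count | 3 | smallest reportable pattern; a perimeter needs ≥ 3 vertices |
| `weights` | % | 25/25/25/25 | relative contribution of SDist/SNbE/STsp/SSc |
| `threshold` | % | 50 | retention filter, strict (GScore > threshold) |

$G_r = 10$ Å, equal weights and the 50 % filter are the conventional
operating point for binding-site-scale analyses. The $N_t = 3$ Å,
$F_t = 10$ Å and `min_residues = 3` defaults are this package's own
choices (no published defaults exist for them): 3–10 Å from a cavity
midpoint brackets the first and second residue shells of a drug-sized
pocket, and three residues is the smallest set with a non-degenerate
perimeter. For larger sites, raise $F_t$; for patterns of well-separated
residues, raise $N_t$.

## Numerical and procedural choices

Several points the method's verbal description leaves open had to be fixed
one way; these are the package's choices and the reasons.

* **Side-chain center**: unweighted mean of side-chain heavy atoms
  (non-hydrogen, excluding backbone N/CA/C/O/OXT); glycine falls back to
  CA. Heavy-atom means are the field's convention and crystal structures
  rarely carry hydrogens.
* **Structure normalization**: first model only, first-listed altloc
  conformer only (deterministic geometry); waters and non-polymer
  heteroatoms excluded (ligand independence); MSE and similar modified
  residues mapped to their standard parent; all protein chains by default,
  filterable per structure.
* **Inclusive distance bounds** ($d \le G_r$, $d \le F_t$): boundary ties
  must be deterministic, and inclusivity is conventional.
* **Coincident midpoints are kept** as distinct grid points: one pattern
  per grid point keeps the all-vs-all pair count equal to the product of
  the two grid sizes, which is the accounting the method's reported pair
  counts imply. An optional `dedup` flag collapses identical residue sets.
* **Token rounding**: distances round to the nearest integer Å, halves up
  (`7.5 → 8`). A fixed rule is required for reproducible multiset
  intersections.
* **Token canonicalization**: the two letters are placed in lexicographic
  order around the number (`R5L` and `L5R` both become `L5R`). Without
  this, token overlap would depend on arbitrary residue input order,
  breaking the order independence the descriptors are designed for.
* **Multiset, not set, intersections** for Dist/Tsp/Sc: the normalizers
  $n(n-1)/2$ and $n$ only make sense when duplicates are preserved; set
  semantics would over-reward patterns with repeated tokens.
* **SNbE at zero**: the ratio is 0/0 when both energies are 0; it is
  defined as 100 there (identical values) and as 0 when exactly one is 0.
* **Greedy pruning**: when candidates violate the $F_t$ diameter, the
  residue with the most violations is removed first, ties broken by larger
  anchor distance, then by later file order. This is deterministic, exact
  on feasible inputs, and maximal on the small instances we can check
  exhaustively. One consequence worth knowing: *enlarging* $F_t$ can
  occasionally remove a residue from the pattern grown at a given anchor,
  because the wider candidate shell brings in violators that change the
  pruning order. The candidate stage itself is monotone in $F_t$.
* **TSP**: exact Held–Karp dynamic programming up to 10 residues
  (descriptor-scale patterns are usually this small), nearest-neighbour
  plus 2-opt beyond. Tours are closed; the descriptor stores edge tokens
  as a multiset, so tour start and direction never matter.
* **Strict threshold** (`GScore > threshold`), matching the written
  retention rule; scores are carried as exact ratios and rounded to one
  decimal only at reporting time.
* **Energy table**: shipped as an editable two-column text file. The
  packaged values are a synthetic stand-in (scaled with side-chain size
  and polarizability); the published per-residue energies the descriptor
  was defined with are not printed in the literature accessible here.
  Because SNbE is a ratio of sums, patterns of identical composition score
  100 under *any* table, and all packaged validation relies on such
  composition-identity cases rather than on the table's absolute values.

## The synthetic-structure generator

`make_structure()` emits standard-conformant PDB text in which each
residue's side-chain center is *planted exactly*: the residue is realized
with a single CB side-chain atom placed on the requested coordinate (CA
for glycine), plus offset backbone dressing. Decoys (waters, a HETATM
ligand, altloc B conformers, a second model) exercise the parser's
filtering rules. `make_twin_pair()` derives a second structure by seeded
Gaussian coordinate jitter and/or mutations confined to the same
physicochemical category.

What this emulates well: the geometry pipeline (grid, thresholds, pruning,
descriptors, scoring) operates on centers and types only, so planted-center
fixtures exercise it exactly as real structures do, with known ground
truth — zero jitter must give all-100 matched pairs, category-preserving
mutation must leave SSc at 100, and jitter beyond the 1 Å token rounding
must degrade SDist.

What it does not emulate: real rotamer geometry (centers of multi-atom
side chains), crystallographic noise models, chain connectivity and
realistic packing density. Passing tests therefore validate the
*algorithmics* on controlled geometry; absolute pattern counts and scores
on real proteins additionally depend on chain selection, the energy table
and the $N_t$/$F_t$ operating point.

## Problem sizes

The test suite runs on synthetic structures of 3–50 residues (grids up to
about 1200 points), checks TSP optimality by exhaustive enumeration up to
n = 8, pruning maximality up to 8 candidates, and scoring against a
naive quadruple-loop re-implementation on up to 4×4 pattern pairs; the
twin-pair degradation checks use 10 seeds at 2 Å jitter. These sizes make
every brute-force oracle exact while keeping the default suite fast. One
regression test parses two full crystal structures from the Protein Data
Bank and checks their published grid sizes at $G_r = 10$; it requires
network access to fetch them.

## Known limitations

* All-vs-all cost is the product of the two grid sizes; at $G_r = 10$ a
  medium-sized protein already yields thousands of patterns, and a full
  cross comparison of two such proteins reaches tens of millions of pairs.
  The R implementation is written for clarity and is appropriate for
  desk-scale analyses (hundreds of patterns per side); very large runs
  call for aggressive thresholds, chain filters or `dedup`.
* GScore quantifies descriptor overlap, not statistical significance; no
  background distribution or p-value is computed.
* The method never superposes patterns, so it reports *that* two patterns
  look alike, not a residue-to-residue correspondence.
* Cross-size comparisons follow the formulas literally: overlap is
  normalized by the larger cardinality, so a small pattern fully contained
  in a large one scores the size ratio, not 100.
```{r session}
sessionInfo()
```
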
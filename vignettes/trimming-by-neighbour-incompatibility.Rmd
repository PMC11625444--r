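---
title: "Trimming alignments by neighbour incompatibility: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trimming alignments by neighbour incompatibility: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyin)
```

## The underlying model

A single column of an alignment cannot reveal phylogenetic noise: a 50/50
split of two nucleotides may be one clean synapomorphy or pure randomness.
Noise shows up as *discord between* columns. Two characters are
phylogenetically compatible when some tree exists on which both can evolve
homoplasy-free, i.e. each needs only its minimum conceivable number of
changes (distinct states minus one). No tree has to be inferred to decide
this. For two binary characters the four-gamete rule applies: the pair is
incompatible exactly when all four state combinations are present. The
multistate generalization used here is the state-pair graph: one vertex per
observed state of each column, one edge per state combination observed in at
least one taxon. The pair is compatible if and only if that bipartite graph
is acyclic.

`are_incompatible()` implements the cycle test with union-find over at most
ten vertices (four nucleotides plus the gap state, per side); an edge whose
endpoints are already connected closes a cycle. Only taxa observed in both
columns contribute edges. Pairs with fewer than two doubly-observed taxa, or
with a constant column on the shared taxa, are declared compatible — no
cycle can exist, which is also why mostly-gap regions offer the method
little traction.

The trimmer composes three steps (`phyin_mask()`):

1. **Conflict flagging** (`find_conflicted()`): every ordered pair of
   columns at distance ≤ `d` is tested; each incompatible pair flags both
   members. Conflict is strictly pairwise even for `d > 1`.
2. **Block scan** (`select_blocks()`): a window of `b` consecutive sites is
   evaluated at every start position; a window whose proportion of flagged
   sites is ≥ `p` marks the span from its first to its last flagged site.
   Marks from overlapping windows are unioned.
3. **Deletion** (`apply_mask()`).

The procedure is a pure function of the alignment and the parameters; there
is no randomness anywhere in the trimming path.

## Parameters

* `d` (integer ≥ 1, default 2) — how far apart two columns may be and still
  be compared. Larger `d` flags more aggressively but erodes the locality
  that lets the method find boundaries between chaotic and orderly regions.
* `e` (logical, default `TRUE`) — whether internal gaps act as a fifth
  state. Internal gaps record indel events and carry signal comparable to
  substitutions; terminal gaps record sequencing failure and are always
  missing data, never a state. Fifth-state treatment is most defensible when
  loci are trimmed separately: in a concatenated matrix the internal/terminal
  distinction is lost, since a taxon absent from one locus shows a long gap
  run flanked by observed data from neighbouring loci.
* `b` (integer ≥ 1, default 10) — the window length, in sites, over which
  the conflicted proportion is measured. Longer windows are better estimates
  but can miss short chaotic stretches.
* `p` (proportion, default 0.5) — the triggering threshold, compared as
  "greater than or equal". Raising `p` trims less.
* occupancy threshold (default 0.5) — the companion filter deletes sites
  whose gap fraction (`-` and `?` both counted, ambiguity letters not)
  **strictly exceeds** the threshold, so an exactly-half-gapped column
  survives the default. A threshold of 0.18 corresponds to requiring 82%
  site occupancy.

## Numerical and edge-case choices

These choices were genuinely open and are fixed here as package policy:

* **Sliding windows.** Blocks are evaluated at every start position rather
  than as disjoint tiles, making the mask translation-invariant and unable
  to miss a noisy stretch straddling a tile boundary.
* **Short alignments.** An alignment shorter than `b` forms a single window
  of its own length, with the proportion taken over that length; otherwise
  short loci could never be trimmed.
* **Degenerate windows.** At `p = 0` every window triggers, but a span still
  needs at least one flagged site, so a conflict-free alignment is never
  touched. A triggering window whose flags coincide deletes exactly that
  one site.
* **Symbol dialect.** `-` is the only gap glyph. `?` and the IUPAC
  ambiguity letters are missing data in the compatibility machinery
  (partial information treated as absent is the conservative reading), while
  for occupancy `?` counts as a gap and ambiguity letters count as occupied
  base calls. `U` is accepted on input and normalized to `T`. A row that is
  entirely gaps is entirely terminal gap, forced by the definition.
* **Gap–gap pairs.** Under `e = TRUE` the gap state is a full fifth state,
  so a GAP–GAP combination contributes an ordinary edge to the state-pair
  graph.
* **Coordinates.** Internally 0/1-based R indexing; all user-facing reports
  are 1-based inclusive (`write_mask_report()`).

## The verification oracle

`brute_force_compatible()` is deliberately independent of the cycle test:
restricted to the doubly-observed taxa, it enumerates every unrooted binary
topology (3, 15, 105 … up to 10,395 at the 8-taxon cap, via
`phangorn::allTrees`) and asks whether some tree renders both characters
homoplasy-free under Fitch parsimony. The Fitch inner loop is a compact
bitmask implementation, itself cross-checked against
`phangorn::parsimony()` in the unit tests. The suite then drives 10,000
seeded random column pairs (4–6 taxa, nucleotides plus gap, random missing
entries) through both routes and requires complete agreement, alongside
property tests: symmetry, invariance to state relabelling, and the fact that
removing taxa can never create incompatibility.

## What the synthetic generator does and does not emulate

`make_fixture()` produces alignments with a known segmentation: a *clean*
region whose columns are generated by placing one or two substitution
events on edges of a single random tree (`ape::rtopology`), and a *noise*
region of i.i.d. uniform nucleotides. Because every clean column's states
paint clades of the shared tree — a laminar family — each column is convex
(homoplasy-free) on that tree, so clean columns are pairwise compatible *by
construction*, a property the tests verify exhaustively per fixture.
Terminal-gap erosion mimics the fragmented ends of sequence-capture loci.
Internal gaps are injected i.i.d. within noise regions, but as indel events
on tree edges within clean regions: i.i.d. gaps read as a fifth state would
themselves inject conflict into the clean region and destroy the ground
truth the fixture exists to provide.

The defaults (16 taxa, 200 clean + 200 noise sites on both flanks,
terminal-gap rate 0.1, internal-gap rate 0.02) describe a UCE-like locus
with a conserved core and eroded, chaotic flanks. What the generator does
*not* emulate: realistic substitution models (GTR+Γ), rate heterogeneity,
gene-tree discordance, rogue subsequences, or alignment error that is
locally autocorrelated rather than i.i.d. Passing the boundary-detection
suite therefore shows the method separates tree-structured from
structureless regions under idealized conditions; it does not certify
performance on real loci, where noise is rarely uniform and never exactly
i.i.d.

Problem sizes in the test suite (column-pair sweeps at 4–6 taxa, fixtures
of 8–16 taxa and tens to hundreds of sites, 20–100 replicates per property)
were chosen as the smallest scales at which each property is meaningfully
exercised — enumeration oracles grow factorially, and nothing about the
method's behaviour changes beyond these sizes.

## Known limitations

* Nucleotide data only; amino-acid alphabets are not supported.
* The method needs regional contrast in conflict density; alignments that
  are uniformly noisy or uniformly clean give it nothing to segment, and
  mostly-gap regions are poorly trimmed because few taxa overlap (hence the
  companion occupancy filter).
* Compatibility is a yes/no verdict: characters conflicting in one part of
  a tree may still jointly support another part, so flagged sites are not
  proven uninformative — only locally discordant.
* Occupancy is measured over the taxa present in the file at hand; filtering
  isolated per-locus files is less stringent than filtering after all taxa
  are represented in one matrix.
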
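# phyin

Trim noisy regions from nucleotide multiple sequence alignments by
**phylogenetic incompatibility among neighbouring sites** (the PhyIN
criterion), with the companion site-occupancy filter.

## The problem

Phylogenomic loci — ultraconserved elements especially — tend to have a
well-aligned conserved core flanked by fragment-prone, rapidly evolving
regions where homology assessment breaks down. Such chaotic regions degrade
tree inference and are routinely trimmed away. Most trimmers judge columns
one at a time (base frequencies, gappiness) or against the bulk of the
alignment; but phylogenetic noise is only visible as *discord among
characters*. This package flags regions where neighbouring columns cannot
agree on **any** tree, which requires no tree inference and works on a
single locus at a time — so trimming does not silence genuine gene-tree
discord.

## The method

Two characters are *compatible* when some tree exists on which both evolve
without homoplasy (no convergence or reversal, i.e. no more than
`#states − 1` changes each). For binary characters this is the classical
four-gamete test: the pair is incompatible exactly when all four state
combinations occur among the taxa. For multistate characters, build the
bipartite *state-pair graph*: vertices are the observed states of the two
columns, and each state combination observed in some taxon is an edge. The
pair is incompatible **iff that graph contains a cycle** (checked here by
union-find; a brute-force oracle that enumerates every unrooted binary
topology and scores Fitch parsimony verifies the test in the suite).

The trimming procedure, with parameters `d`, `e`, `b`, `p`:

1. For every pair of columns at most `d` apart (default 2), test pairwise
   incompatibility; both members of an incompatible pair are *conflicted*.
2. Slide a window of `b` sites (default 10) over the alignment; whenever the
   proportion of conflicted sites in a window is ≥ `p` (default 0.5), mark
   the sites from the window's first conflicted to its last conflicted site.
3. Delete the marked sites.

Gap semantics matter: *internal* gaps (flanked by observed nucleotides on
the way to each sequence end) represent indel events and are treated as a
fifth character state when `e = TRUE` (the default); *terminal* gaps
(contiguous runs reaching a sequence end) represent failure to sequence and
are always treated as missing data. `?` and IUPAC ambiguity letters are
missing data throughout.

Because the criterion ignores gappiness per se, it should be combined with
the companion occupancy filter, which deletes any site with **more than**
a given gap fraction (default 50%, counting `-` and `?`).

## Worked example

The package ships an 8-taxon, 10-site alignment whose first nine sites form
a conflicted block:

```r
library(phyin)
aln <- phyin_example_alignment()

which(find_conflicted(aln))
#> [1] 1 2 3 7 9

mask <- phyin_mask(aln)
mask
#> site_mask: 9 of 10 sites flagged for deletion
#>   phyin      9

str(trim_report(aln, mask))
#> List of 5
#>  $ n_sites           : int 10
#>  $ n_deleted         : int 9
#>  $ n_phyin           : int 9
#>  $ n_occupancy       : int 0
#>  $ proportion_trimmed: num 0.9
```

Three incompatible neighbour pairs exist within distance 2 (sites 1–2, 2–3
and 7–9), so five sites are conflicted. The 10-site window holds 5/10 ≥ 0.5
conflicted sites, triggering deletion from the first conflicted site (1) to
the last (9); only site 10 survives. `apply_mask(aln, mask)` returns the
one-column alignment, and `run_trim()` does the whole thing file-to-file.

## Command line

```sh
phyin input.fasta -o trimmed.fasta -d 2 -e true -b 10 -p 0.5 \
     --occupancy 0.5 --mask-out mask.tsv
```

(The script installs to `exec/phyin` inside the package directory; progress
goes to standard error, data to files or standard output.)

## Synthetic fixtures

`make_fixture(synth_config(...))` generates seeded alignments with a
tree-consistent core (every column homoplasy-free on one shared random
tree, hence mutually compatible) flanked by i.i.d. random noise, with
terminal-end erosion and internal-gap injection — the structure the method
is designed to segment. Ground-truth region labels come along, so boundary
detection is testable without any external data.

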
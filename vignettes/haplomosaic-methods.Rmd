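---
title: "haplomosaic: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{haplomosaic: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model, the algorithmic and numerical
choices, and the conventions behind `haplomosaic`. The package analyses a
panel of collinear genomes — typically inbred strains genotyped at a common
set of biallelic SNPs on one chromosome — and reconstructs its haplotype
mosaic structure.

## Genotype model

A `genotype_matrix` holds integer calls, strains × markers, with positions
strictly increasing along one chromosome:

* `0` — homozygous major allele (the more frequent allele among homozygous
  calls at that marker; ties break lexicographically to the smaller
  nucleotide, so the coding is reproducible from the data alone),
* `1` — homozygous minor allele,
* `2` — heterozygous,
* `-1` — missing.

Heterozygous and missing calls are treated as *wildcards* by every
combinatorial routine: they are excluded from allele counts, four-gamete
tests and mismatch fractions. Readers exist for a tab-separated table format
and for VCF (via `vcfR`; multi-allelic records are dropped with a warning,
and rows are sorted by position). The table reader instead *rejects*
non-monotone positions, because a hand-edited table with shuffled rows more
likely indicates a corrupted file than an unsorted-but-valid one.

## Compatible intervals

Two markers are *compatible* (four-gamete test) when, among strains with
homozygous calls at both, at most three of the four possible two-site
haplotypes occur; fewer than two informative strains means compatible. An
interval of markers is compatible when all its marker pairs are; such an
interval shows no evidence of historical recombination and admits a single
perfect phylogeny.

`maximal_covering` finds all *maximal* compatible intervals in O(m·scan)
time using a left-extent recurrence: `L[j] = max(L[j-1], 1 + r)` where `r`
is the rightmost marker before `j` incompatible with `j` — valid because
compatibility of an interval is exactly pairwise compatibility, so the set
of valid left endpoints for a right endpoint `j` is a suffix. The minimal
full covering is then chosen greedily left-to-right (always extending to the
farthest-reaching maximal interval). Two facts follow by construction and
are asserted by the test suite:

1. every marker is covered;
2. no marker is covered by more than two chosen intervals (consecutive
   chosen intervals may overlap; non-consecutive ones cannot, or the middle
   interval would not have been maximal).

Intervals carry 0-based marker indices (`start_idx`, `end_idx`), base-pair
bounds, and an alternating even/odd `parity` used by the renderer to tile
overlapping intervals on two rows. BED export converts to half-open 0-based
coordinates.

## Haplotype groups and identity-by-descent

Within one interval, strains are partitioned by single-linkage clustering:
two strains link when their mismatch fraction over pairwise-informative
markers (both calls homozygous) is at most `mismatch_tol` (default 0 =
exact identity up to wildcards). A pair with *zero* informative markers
carries no evidence; such links are applied in a second pass so that a
fully-missing strain joins the group of the lowest-indexed strain it is
uninformative against, but can never *bridge* two evidence-supported groups
into one. Group ids are dense from 0, ordered by each group's smallest
strain index — deterministic given the input.

`compute_ibd` marks an interval IBD-positive for a strain subset when all
selected strains share one group, and merges maximal runs of consecutive
positive intervals into blocks. Because adding a strain can only split
group-sharing, IBD is monotone: a superset's blocks are always contained in
a subset's.

## Mosaic coloring

`default_coloring` assigns a palette index to each (strain, interval) cell
so that equal colors within an interval correspond exactly to equal
haplotype groups, while minimizing the total number of color changes across
interval boundaries. The key structural fact: the number of transitions at
one boundary depends only on *which* groups are matched across it (a group
keeps its color iff it is matched), not on the actual color labels — so each
boundary can be optimized independently, and an exact maximum-weight
bipartite matching per boundary (weights = shared strain counts) attains the
global minimum over all valid colorings. The test suite verifies this
against exhaustive color-permutation search.

The matcher solves each connected component of the positive-weight sharing
graph exactly by depth-first search with a deterministic candidate order
(current groups ascending; previous groups by color, then id; "unmatched"
last), so ties resolve reproducibly toward smaller previous colors. A greedy
fallback (descending weight, same tie order) guards against components with
more than 12 groups on a side; at this package's problem sizes the fallback
is never exercised. Unmatched groups take the smallest palette index unused
in their interval.

`order_recoloring` instead colors each strain by the display rank of the
earliest-ranked displayed strain sharing its group, so the top strain is one
color genome-wide. `sort_strains_at` orders strains by their group ids over
the visible intervals, radiating outward from the interval containing the
anchor position (anchor interval first, then right, left, right, ...),
ties keeping the initial order — a stable radix sort.

## Subspecific origin and heterozygosity HMMs

`call_diagnostic_snps` takes subspecies labels for a reference subset
(`domesticus` / `musculus` / `castaneus`) and flags marker alleles carried
only by references of one subspecies: *fully* informative (weight 1) when
all references of that subspecies carry it, *partially* informative
(`partial_weight`, default 0.5) otherwise.

`subspecies_viterbi` decodes a 3-state HMM per strain over its informative
diagnostic calls. Log-space emissions: `w·log(1-ε)` when the call supports
the state's subspecies, `w·log(ε/2)` when it supports another (ε =
`epsilon`, default 0.05, the rate at which a diagnostic SNP misleads),
0 when uninformative; transitions stay with `log(1-2ρ)` and switch with
`log(ρ)` (ρ = `rho`, default 1e-6 per marker step — at that default a
single contrary SNP can never outweigh two switches, which the tests check
analytically). The initial distribution is uniform: with no prior on the
ancestry at the chromosome start, any informative prefix dominates a 3-way
constant immediately. `heterozygosity_viterbi` is the analogous 2-state
(inbred / heterozygous) decoder with emissions `het_emit` (default 0.5, the
chance a truly heterozygous region yields a het call at a marker) and
`het_err` (default 0.01, het calls in inbred material), staying with
`log(1-ρ)`.

Decoded paths are compressed to segments whose boundaries fall at
inter-marker midpoints; the outer ends close at the outermost informative
markers. Both decoders are validated against exhaustive enumeration of all
state paths on small instances (score equality, so ties between distinct
optimal paths are tolerated); defaults are scale-dependent, and the
small-instance tests pin the switch rate to the instance size for the same
reason a 500-marker chromosome uses ρ = 1e-6.

## Local phylogenies

Per interval, each haplotype group gets a consensus sequence (majority
homozygous call; ties and all-wildcard sites are undefined) and pairwise
distances are the fraction of differing sites among both-defined sites
(pairs with no comparable site get distance 1.0 with a warning). The
neighbor-joining implementation follows the canonical Q-criterion
agglomeration with deterministic first-minimum tie-breaking; negative branch
lengths (possible for non-additive inputs) are clamped to zero with the
excess moved to the sister branch, preserving path lengths. Results are
returned as `ape` `phylo` objects; correctness is cross-checked against
`ape::nj` and against exact recovery of random additive metrics. Leaf
support counts the markers at which a group's consensus differs from all
other groups, normalized by interval length. Newick export is via
`ape::write.tree` with an optional per-leaf TSV sidecar (support, member
strains).

## Rendering

The renderer builds a flat list of primitives (rects, lines, text) and
writes either a hand-generated SVG (stable attribute order, fixed number
formatting, binary-mode output — byte-identical across runs and platforms)
or a PNG via `grDevices`. The genomic-to-pixel map is affine with rounding
and clamping. Each track switches between *detail* mode (one element per
item) and *histogram* mode when items exceed one per pixel; histogram bars
are max-normalized to the track height. Compatible intervals tile on two
rows by parity so overlapping neighbors stay visually separate.

## Simulator

`simulate_panel` generates ground-truthed panels: 8 founder haplotypes by
default (4 *domesticus*, 2 *musculus*, 2 *castaneus*) with independent
random alleles, plus disjoint subspecies-private variants at 10% of markers
each so diagnostic SNPs exist by construction. The first `n_founders`
strains are pure founder copies (the natural labeled reference subset); the
rest are mosaics with Poisson(`switch_rate`, default 2) breakpoints placed
uniformly, founders resampled without immediate repetition. Optional
heterozygous regions are injected into designated "wild" strains. Noise:
symmetric allele flips at `err_rate` (default 0.01) and missingness at
`miss_rate` (default 0.02). After noise, calls are recoded so `0` is the
major allele, with the founder truth flipped consistently.

Scope and limitations: founder alleles are independent across markers (no
within-founder linkage beyond the mosaic structure itself) — sufficient to
exercise every algorithm here, but not a coalescent model; do not use it to
benchmark LD-sensitive methods. Interval lengths under the defaults are
short (1–8 markers at 50 strains), which is the realistic regime for dense
panels: recombination evidence accumulates quickly with panel size.

## Problem sizes and numerics

The package targets panels up to a few hundred strains and tens of
thousands of markers per chromosome; the interval scan is linear in markers
times incompatibility-scan depth, grouping is quadratic in strains per
interval, and the HMMs are linear. All decoding is in log space; no
underflow-prone products are formed. All algorithms are deterministic given
their inputs, and every random routine takes an explicit seed, so whole-
pipeline outputs are byte-reproducible.
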
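# haplomosaic

Comparative haplotype mosaic analysis for panels of collinear genomes.

Laboratory mouse strains (and other inbred panels) are genetic mosaics: each
chromosome is a patchwork of haplotypes inherited from a small set of
ancestral founders, often tracing back to distinct subspecies. Given a
biallelic SNP matrix over such a panel, `haplomosaic` reconstructs and
visualizes that mosaic structure:

- **Compatible intervals** — segments the chromosome into maximal intervals
  of SNPs that are pairwise compatible under the four-gamete test, i.e.
  intervals with no evidence of historical recombination, each admitting a
  single perfect phylogeny. A minimal full covering is selected; by
  construction at most two intervals overlap any marker.
- **Haplotype groups** — within each interval, partitions strains into
  groups with (near-)identical alleles; heterozygous and missing calls act
  as wildcards.
- **Dynamic identity-by-descent** — for any strain subset, finds the merged
  runs of consecutive intervals where all selected strains fall in one
  group.
- **Mosaic colorings** — assigns palette indices per (strain, interval) so
  equal colors mean equal groups, reusing colors across interval boundaries
  via exact maximum-weight bipartite matching, which provably minimizes the
  total number of color transitions. Also: order-based recoloring for a
  chosen display order, and a position-radiating strain sort.
- **Subspecific origin and heterozygosity** — calls diagnostic SNPs from a
  labeled reference subset, then decodes per-strain subspecies segments
  (3-state Viterbi HMM) and heterozygous blocks (2-state HMM).
- **Local phylogenies** — consensus distances between haplotype groups,
  neighbor-joining trees per interval with per-leaf SNP support, Newick
  output.
- **Rendering** — deterministic, scale-adaptive SVG/PNG track images (SNP
  density, interval tiling, colored mosaics) that switch between per-item
  detail and histograms at one item per pixel.
- **Simulator** — a ground-truthed founder-mosaic panel generator used for
  validation throughout.

## Quick start

```r
library(haplomosaic)

# simulate a ground-truthed panel: 30 strains x 200 markers
sim <- simulate_panel(sim_params(n_strains = 30, n_markers = 200, seed = 42))
gm  <- sim$matrix

# 1. compatible intervals (minimal full covering)
iv <- maximal_covering(gm)
iv
#> compatible_intervals: 119 intervals on chr1 covering markers 0 - 199
#>   ordinal parity chrom start_idx end_idx start_pos end_pos n_markers
#> 1       0   even  chr1         0       2      5261   13610         3
#> 2       1    odd  chr1         3       6     16101   55182         4
#> ...

# 2. haplotype groups and a transition-minimizing coloring
asg <- assign_all_haplotypes(gm, iv, mismatch_tol = 0)
mos <- default_coloring(asg)
mos
#> color_mosaic: 30 strains x 119 intervals, 7 distinct colors
count_transitions(mos)
#> [1] 1353

# 3. identity-by-descent between two strains
compute_ibd(asg, c("S001", "S002"))[1:2, ]
#>   chrom start    end start_idx end_idx n_intervals_merged
#> 1  chr1  5261  61980         0       8                  4
#> 2  chr1 82556 108127        11      14                  3

# 4. subspecific origin from diagnostic SNPs
labels <- labeled_reference_subset(sim$truth, 2)   # 2 references/subspecies
diag   <- call_diagnostic_snps(gm, labels)         # 113 diagnostic SNPs here
subspecies_viterbi(gm, "S015", diag)
#>   strain chrom start     end     label mean_emission
#> 1   S015  chr1  5261 1971035 castaneus     0.9566834

# 5. a local phylogeny for one interval
local_tree(gm, iv[17, ], mismatch_tol = 0)
#> haplo_tree: 4 haplotype-group leaves
#> (g0:2.775557562e-17,g1:0.2,(g2:0.2,g3:0.4):0.2);

# 6. render a track image
cfg <- render_config(list(chrom = "chr1", start = 1, end = 2e6), 800,
                     list(list(type = "snp", data = gm$pos),
                          list(type = "intervals", data = iv)))
render_tracks(cfg, "view.svg")
```

Genotype matrices can also be read from a tab-separated table or a VCF with
`read_genotype_matrix(path, format = c("table", "vcf"))`. Calls are coded
`0` = major allele, `1` = minor, `2` = heterozygous, `-1` = missing.

## Command line

Every operation is available as a subcommand of the bundled script
(`inst/scripts/haplomosaic`, or `run_cli()` from R):

```sh
haplomosaic simulate  --out-prefix out --seed 4
haplomosaic intervals --genotypes out/panel.tsv --out out/iv.bed
haplomosaic ibd       --genotypes out/panel.tsv --strains S001,S002 --out out/ibd.bed
haplomosaic color     --genotypes out/panel.tsv --mode default --out out/mosaic.tsv
haplomosaic mosaic    --genotypes out/panel.tsv --labels out/labels.tsv \
                      --strain S020 --out out/subspecies.bed
haplomosaic het       --genotypes out/panel.tsv --strain S010 --out out/het.bed
haplomosaic tree      --genotypes out/panel.tsv --interval chr1:251449-295900 \
                      --out out/tree.nwk
haplomosaic sort      --genotypes out/panel.tsv --position 1000000 \
                      --view 1-2000000 --out out/order.txt
haplomosaic render    --config view.yaml --out out/view.svg
```

Flags override values from an optional YAML `--config` file. Outputs are
written atomically and are byte-identical across reruns with the same seed.
Exit codes: 0 success, 1 usage/validation error, 2 internal error.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "haplomosaic", load_package = "installed")'
```

The suite validates every algorithm against brute-force oracles written
directly from the definitions (interval enumeration, exhaustive Viterbi path
scoring, permutation-minimal transition counts), plus property-based and
end-to-end recovery tests on simulated truth. `test-acceptance.R` holds the
release criteria.

## Documentation

The methods vignette (`vignettes/haplomosaic-methods.Rmd`) documents the
model, parameter defaults, algorithmic choices (including the exact
boundary-matching argument behind the coloring) and the simulator's scope
and limitations.
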
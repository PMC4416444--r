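# ecoassembly

Microbial community composition is shaped by a mixture of ecological
selection, dispersal, and drift, and the mix varies from place to place.
`ecoassembly` is an R package for ecologists who want to quantify that mix:
given a taxa-by-samples abundance table, a rooted phylogeny, and sample
metadata, it estimates — for every sample — what fraction of its
compositional turnover is dominated by **variable selection**, **homogeneous
selection**, **dispersal limitation**, **homogenizing dispersal**, or is
**undominated**, and then models and maps those influences across the
sampled landscape. A built-in evolution-plus-assembly simulator provides
communities with known governing processes, used to validate the inference
rules end to end.

## The statistics

Two null models are applied to each pair of samples within a metacommunity
group.

**Phylogenetic tier (bMNTD / bNTI).** The abundance-weighted between-community
mean nearest taxon distance,

    bMNTD = 0.5 * [ sum_i f_ik * min_j D(i_k, j_m)  +  sum_i f_im * min_j D(i_m, j_k) ],

measures how far each taxon is from its closest relative in the other
community (f = within-sample relative abundance, D = patristic distance).
Shuffling taxon identities across the tips of the phylogeny (999 times by
default) yields a null distribution, and

    bNTI = (bMNTD_obs − mean(bMNTD_null)) / sd(bMNTD_null)

flags selection when |bNTI| > 2: variable selection for bNTI > +2,
homogeneous selection for bNTI < −2.

**Taxonomic tier (RC-bray).** When |bNTI| < 2, the observed Bray–Curtis
dissimilarity is ranked within a null of stochastically re-assembled
community pairs (richness and total abundance conserved; taxa drawn by
occupancy, individuals by pooled relative abundance). The rescaled
percentile RC ∈ [−1, +1] separates dispersal limitation (RC > +0.95),
homogenizing dispersal (RC < −0.95), and undominated (|RC| < 0.95).

Per-sample process fractions are the category frequencies of each sample's
pairwise calls. The spatial stage regresses each fraction on environmental
features plus spatial eigenvectors (PCNM / Moran's eigenvector maps) with a
priority-based collinearity filter and exhaustive AICc model selection, and
interpolates predictions onto a grid.

See `vignette("assembly-processes")` for the full methods account, the
simulator design, and documented limitations.

## Worked example

Everything below is self-contained: the fixture generator evolves a
regional species pool and assembles the seven benchmark communities
(samples `C1_r1`…`C7_r1`; 1–4 in a weak-selection environment, 5–7 under
strong selection, with 2, 3, 5 receiving dispersal from 1).

```r
library(ecoassembly)
fx   <- make_fixture("demo", n_replicates = 1, seed = 11)
comm <- read_community_table(fx[["community"]], orientation = "taxa_rows")
tree <- read_phylogeny(fx[["tree"]])
res  <- run_inference(comm, tree, n_null = 199, seed = 42)
res
#> assembly process inference: 21 pairs, 7 samples (199 nulls, pool = group-union)

subset(res$pairs, select = c(sample_a, sample_b, bNTI, rc_bray, category))[1:6, ]
#>   sample_a sample_b   bNTI rc_bray               category
#> 1    C1_r1    C2_r1 -1.154  -1.000 homogenizing_dispersal
#> 2    C1_r1    C3_r1 -0.461  -0.492            undominated
#> 3    C1_r1    C4_r1 -2.280   1.000  homogeneous_selection
#> 4    C1_r1    C5_r1  0.754  -1.000 homogenizing_dispersal
#> 5    C1_r1    C6_r1  4.335   1.000     variable_selection
#> 6    C1_r1    C7_r1  3.827   1.000     variable_selection
```

The calls read directly: the dispersal-coupled pair C1–C2 is more similar
than its taxonomic null (RC = −1) without a selection signal (|bNTI| < 2) —
homogenizing dispersal; the cross-environment pairs C1–C6 and C1–C7 show
strong phylogenetic divergence (bNTI > +2) — variable selection. Per-sample
fractions aggregate these calls:

```r
cbind(res$fractions[1], round(res$fractions[process_categories()], 3))[c(1, 6, 7), ]
#>   sample_id variable_selection homogeneous_selection dispersal_limitation
#> 1     C1_r1              0.333                 0.167                    0
#> 6     C6_r1              0.833                 0.167                    0
#> 7     C7_r1              0.833                 0.167                    0
#>   homogenizing_dispersal undominated
#> 1                  0.333       0.167
#> 6                  0.000       0.000
#> 7                  0.000       0.000
```

The red-environment samples C6/C7 are dominated by variable selection
(5 of their 6 comparisons cross an environmental boundary), while the focal
sample C1 splits between variable selection (vs the red samples) and
homogenizing dispersal (vs its dispersal-coupled neighbours). The spatial
stage then models and grids any of these fractions:

```r
meta <- read_sample_metadata(fx[["metadata"]])
out  <- map_process_influence(res$fractions, meta, "variable_selection",
                              env_vars = c("env_value", "dist_river"))
out$model       # AICc-selected regression with standardized coefficients
out$grid        # x, y, value, in_hull — ready for filled.contour or ggplot2
```

A command-line front end wrapping the same functions ships in
`inst/cli/ecoassembly.R` with subcommands `infer`, `bnti`, `rcbray`,
`simulate`, `fixture`, and `map`; every run writes a JSON manifest
(parameters, seed, input checksums) beside its outputs.

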
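# gwcparc

Individual whole-brain parcellation from resting-state fMRI by supervoxels
and structured graph learning.

## The problem

Brain network analyses need the brain divided into a manageable number of
spatially contiguous, functionally homogeneous, reproducible parcels, and
functional boundaries differ between people. `gwcparc` builds such a
parcellation for a *single subject* directly from their 4D BOLD volume, in
two stages:

1. **Supervoxels.** SLIC (simple linear iterative clustering) is run
   directly on the voxel time series: local k-means under the unified
   distance

   $$d_{ij} = \frac{\lVert v_i - v_j\rVert^2}{m^2} +
              \frac{\lVert u_i - u_j\rVert^2}{S^2},$$

   where $v_i$ is the (z-scored) time course of voxel $i$, $u_i$ its
   voxel-index coordinates, $m$ the compactness parameter, and $S$ the seed
   grid spacing. Disconnected fragments are merged afterwards so every
   supervoxel is a single 26-connected region.

2. **Graph-without-cut clustering.** From each supervoxel three features
   are extracted (mean time course, 12-bin intensity histogram of the
   temporal-mean image, 10-bin histogram of six-neighbor 3D local binary
   patterns). A sparse affinity graph $S \in \mathbb{R}^{N\times N}$ over
   the $N$ supervoxels, a spectral embedding $Z \in \mathbb{R}^{N\times K}$
   and feature weights $\alpha$ are then learned jointly:

   $$\min_{S,\alpha,Z}
     \sum_{ij}\lVert x_i-x_j\rVert^2 s_{ij}
     + \lambda \sum_m \alpha_m \sum_{ij}\lVert y^{(m)}_i-y^{(m)}_j\rVert^2 s_{ij}
     + \mu \sum_{ij}\lVert z_i-z_j\rVert^2 s_{ij}
     + \beta\lVert S\rVert_F^2 + \beta\gamma\lVert\alpha\rVert_2^2$$

   subject to $s_i^\top \mathbf{1} = 1$, $s_i \ge 0$ (columns on the
   probability simplex with at most $k$ nonzeros),
   $\alpha^\top \mathbf{1} = 1$, $\alpha \ge 0$, and $Z^\top Z = I$. All
   pairwise-distance graphs are normalized by their maximum before entering
   the objective. Because $\sum_{ij}\lVert z_i - z_j\rVert^2 s_{ij} =
   2\,\mathrm{tr}(Z^\top L Z)$ for the Laplacian $L$ of $S$, a large $\mu$
   drives the $K$ smallest Laplacian eigenvalues to zero, i.e. the learned
   graph ends up with **exactly $K$ connected components** — graph
   construction and partitioning happen in one optimization instead of
   cutting a fixed graph afterwards. Labels are read off the components
   (normalized-cut clustering of $S$ is the fallback) and mapped back to
   voxels.

The package also provides the surrounding study apparatus: a synthetic
phantom generator with planted contiguous parcels, the evaluation metrics
(spatial discontiguity index, functional homogeneity, adjacency-matrix Dice
reproducibility), voxel-level normalized-cut and SLIC-as-atlas baselines,
and the random-parcellation nulls (permuted time series, permuted weight
matrices) used to show that a parcellation does not merely reflect spatial
structure.

## Worked example

```r
library(gwcparc)

# 20 x 20 x 12 phantom: 8 contiguous parcels, T = 60, snr = 8
ph  <- make_phantom(seed = 1)
fit <- gwc(ph$bold, ph$mask, K = 8, n_supervoxels = 120, k = 9)
fit
#> Graph-without-cut parcellation
#>   supervoxels: 196  clusters requested: 8  obtained: 8
#>   graph components: 8  iterations: 4  (converged)
#>   feature weights: mean_series=1.000, intensity_histogram=0.000, lbp_histogram=0.000

summary(fit)
#> Graph-without-cut parcellation summary
#>   clusters: requested 8 - obtained 8 - graph components 8
#>   supervoxels: 196 (sizes 10-44)
#>   cluster sizes: 331 - 900 voxels
#>   sparsity k: 9
#>   iterations: 4 (converged)  final objective: 6.21967
#>   feature weights: mean_series=1.000, intensity_histogram=0.000, lbp_histogram=0.000
#>   spatial discontiguity index: 0

mclust::adjustedRandIndex(fit$atlas$labels[ph$mask$data],
                          ph$atlas$labels[ph$mask$data])
#> [1] 1
functional_homogeneity(fit$atlas, ph$bold, ph$mask)$homogeneity
#> [1] 0.984
spatial_discontiguity_index(fit$atlas)
#> [1] 0
```

The printed lines say: the mask was tiled into 196 connected supervoxels;
the learned graph converged in 4 iterations with exactly the 8 requested
connected components; the feature weights loaded on the mean time course
(the histogram features carry no signal in this phantom); and the recovered
atlas is spatially contiguous (discontiguity 0), functionally homogeneous
(mean within-cluster correlation 0.98), and identical to the planted
partition up to label names (adjusted Rand index 1).

Real data go through the same calls: `read_bold()` / `read_mask()` on
NIfTI-1 files, `gwc()` with the defaults (`n_supervoxels = 1000`,
`lambda = 0.1`, `gamma = 1`, `mu = 1e4`, `k = "auto"`), `write_atlas()` for
the result. A command-line wrapper with `simulate`, `parcellate`,
`baseline`, and `evaluate` subcommands is installed under `inst/cli/gwc`
(see `?gwc_cli`).

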
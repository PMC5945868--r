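## Evaluation criteria: spatial contiguity (discontiguity index), functional
## homogeneity (mean within-cluster pairwise correlation), and adjacency
## Dice reproducibility between two atlases.

#' Spatial discontiguity index of an atlas
#'
#' Within each cluster, 26-connected components are labeled; the index is the
#' total component count minus the number of clusters. 0 means every cluster
#' is a single contiguous region.
#'
#' @param atlas a [brain_atlas()]
#' @return nonnegative integer
#' @export
spatial_discontiguity_index <- function(atlas) {
  comp <- grid_components(atlas$labels)
  idx <- atlas$labels > 0
  total <- length(unique(comp[idx]))
  total - atlas$K
}

#' Functional homogeneity of an atlas on a BOLD volume
#'
#' For each cluster with at least two voxels, the mean Pearson correlation
#' over ordered distinct voxel pairs is computed; the homogeneity is the
#' unweighted mean over those clusters. Singleton clusters are omitted (their
#' count is reported). The per-cluster mean is computed with the identity
#' `sum_{i != j} r_ij = (||sum_i z_i||^2 - sum_i ||z_i||^2) / (T - 1)` on
#' z-scored series, which is O(n T) per cluster. Constant (zero-variance)
#' series correlate 0 with everything.
#'
#' @param atlas a [brain_atlas()]
#' @param volume a [bold_volume()] on the same grid
#' @param mask a [brain_mask()]
#' @return list with `homogeneity` (scalar in `[-1, 1]`), `per_cluster`
#'   (named vector a(k) over non-singleton clusters), `n_singletons_omitted`
#' @export
functional_homogeneity <- function(atlas, volume, mask) {
  if (!all(dim(atlas$labels) == dim(mask$data))) {
    stop("atlas and mask grids differ")
  }
  Z <- .zscore_cols(.series_matrix(volume, mask))
  lab <- atlas$labels[mask_index(mask)]
  keep <- lab > 0
  Z <- Z[, keep, drop = FALSE]
  lab <- lab[keep]
  Tm1 <- nrow(Z) - 1
  nk <- tabulate(lab, atlas$K)
  sums <- rowsum(t(Z), lab)                 # per-cluster sum of z-series
  sum_norm2 <- rowSums(sums^2)
  self_norm2 <- rowsum(colSums(Z^2), lab)[, 1]
  eligible <- which(nk >= 2)
  if (length(eligible) == 0) {
    stop("all clusters are singletons; homogeneity undefined")
  }
  a_k <- (sum_norm2[as.character(eligible)] -
            self_norm2[as.character(eligible)]) /
    (Tm1 * nk[eligible] * (nk[eligible] - 1))
  names(a_k) <- eligible
  list(homogeneity = mean(a_k), per_cluster = a_k,
       n_singletons_omitted = sum(nk == 1))
}

#' Adjacency-matrix Dice coefficient between two atlases
#'
#' Both atlases induce an N0 x N0 same-cluster adjacency matrix (diagonal
#' included); the Dice coefficient is `2|A and B| / (|A| + |B|)` where |.|
#' counts ones. It is computed through the contingency-table identity
#' `2 sum_uv n_uv^2 / (sum_u n_u.^2 + sum_v n_.v^2)` without materializing
#' the adjacency matrices.
#'
#' @param atlasA,atlasB two [brain_atlas()]s over the same mask
#' @return scalar in `[0, 1]`
#' @export
dice_coefficient <- function(atlasA, atlasB) {
  inA <- atlasA$labels > 0
  inB <- atlasB$labels > 0
  if (!all(dim(atlasA$labels) == dim(atlasB$labels)) || !identical(inA, inB)) {
    stop("atlases are defined on different masks")
  }
  a <- atlasA$labels[inA]
  b <- atlasB$labels[inB]
  n <- table(a, b)
  2 * sum(n^2) / (sum(rowSums(n)^2) + sum(colSums(n)^2))
}

#' Cross-subject functional homogeneity of an atlas
#'
#' Evaluates [functional_homogeneity()] of one atlas against each held-out
#' subject's data and averages, the circularity-free evaluation: the atlas
#' is trained on one subject and scored on the others.
#'
#' @param atlas a [brain_atlas()]
#' @param volumes_other list of `list(bold = , mask = )` pairs on the same grid
#' @return mean homogeneity across held-out volumes
#' @export
cross_subject_homogeneity <- function(atlas, volumes_other) {
  if (length(volumes_other) == 0) stop("empty held-out list")
  vals <- vapply(volumes_other, function(v) {
    functional_homogeneity(atlas, v$bold, v$mask)$homogeneity
  }, numeric(1))
  mean(vals)
}

#' Enumerate or sample subject pairs for reproducibility averaging
#'
#' With n subjects there are `n(n-1)/2` unordered pairs; Dice reproducibility
#' is averaged over all of them or over a seeded random sample.
#'
#' @param n number of subjects
#' @param n_pairs number of pairs to sample (NULL = all pairs)
#' @param seed RNG seed for sampling
#' @return 2-column integer matrix, one pair per row
#' @export
subject_pairs <- function(n, n_pairs = NULL, seed = 1) {
  stopifnot(n >= 2)
  all_pairs <- t(utils::combn(n, 2))
  if (is.null(n_pairs) || n_pairs >= nrow(all_pairs)) return(all_pairs)
  set.seed(seed)
  all_pairs[sample.int(nrow(all_pairs), n_pairs), , drop = FALSE]
}
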
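## Competing voxel-level parcellations: normalized cut on two weight schemes
## (spatially constrained correlation; Gaussian of functional and spatial
## distance), SLIC-as-atlas, and the random variants of all approaches.

#' Spatially constrained correlation weights
#'
#' `w_ij = corr(v_i, v_j)` when the voxel-index distance `||u_i - u_j|| <= 3`
#' and 0 otherwise. Negative correlations are retained. The result is sparse.
#'
#' @param volume a [bold_volume()]
#' @param mask a [brain_mask()]
#' @return symmetric sparse `Matrix` (N0 x N0) with zero diagonal
#' @export
weights_constrained_corr <- function(volume, mask) {
  dims <- dim(mask$data)
  Z <- .zscore_cols(.series_matrix(volume, mask))
  Tm1 <- nrow(Z) - 1
  idx <- mask_index(mask)
  vid <- integer(prod(dims))
  vid[idx] <- seq_along(idx)
  ai <- arrayInd(idx, dims)
  ## half set of integer offsets with 0 < ||d|| <= 3
  g <- as.matrix(expand.grid(dx = -3:3, dy = -3:3, dz = -3:3))
  g <- g[rowSums(g^2) > 0 & rowSums(g^2) <= 9, , drop = FALSE]
  g <- g[g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
           (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0), , drop = FALSE]
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (r in seq_len(nrow(g))) {
    nb <- ai + rep(g[r, ], each = nrow(ai))
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nl <- (nb[ok, 3] - 1L) * dims[1] * dims[2] + (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    inm <- vid[nl] > 0
    i <- which(ok)[inm]
    j <- vid[nl][inm]
    w <- colSums(Z[, i, drop = FALSE] * Z[, j, drop = FALSE]) / Tm1
    ii <- c(ii, i); jj <- c(jj, j); xx <- c(xx, w)
  }
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(xx, xx),
                            dims = c(length(idx), length(idx)))
  Matrix::diag(W) <- 0
  W
}

#' Gaussian functional-spatial weights
#'
#' `w_ij = exp(-||v_i - v_j||^2 / sigma_v^2 - ||u_i - u_j||^2 / sigma_u^2)`
#' with `sigma_v`, `sigma_u` the medians of the pairwise functional and
#' spatial distances over in-mask voxels (computed on a seeded random
#' subsample of at most `max_pairs` voxel pairs when the pair count is
#' larger). No spatial constraint: the matrix is dense and all weights lie
#' in (0, 1].
#'
#' @param volume a [bold_volume()]
#' @param mask a [brain_mask()]
#' @param max_pairs pair-subsample cap for the medians
#' @param seed seed for the pair subsample
#' @return dense symmetric matrix (N0 x N0) with zero diagonal
#' @export
weights_gaussian <- function(volume, mask, max_pairs = 1e6, seed = 1) {
  if (mask$N0 < 2) stop("need at least two in-mask voxels")
  V <- .series_matrix(volume, mask)
  U <- voxel_coords(mask)
  n <- ncol(V)
  sqv <- colSums(V^2)
  Dv2 <- pmax(outer(sqv, sqv, "+") - 2 * crossprod(V), 0)
  squ <- colSums(U^2)
  Du2 <- pmax(outer(squ, squ, "+") - 2 * crossprod(U), 0)
  npairs <- n * (n - 1) / 2
  if (npairs > max_pairs) {
    set.seed(seed)
    i <- sample.int(n, max_pairs, replace = TRUE)
    j <- sample.int(n, max_pairs, replace = TRUE)
    keep <- i != j
    pick <- cbind(i[keep], j[keep])
  } else {
    pick <- which(upper.tri(Dv2), arr.ind = TRUE)
  }
  sigma_v <- stats::median(sqrt(Dv2[pick]))
  sigma_u <- stats::median(sqrt(Du2[pick]))
  if (sigma_v == 0) {
    warning("all time series identical; functional term set to 1")
    fv <- matrix(0, n, n)
  } else {
    fv <- Dv2 / sigma_v^2
  }
  W <- exp(-fv - Du2 / sigma_u^2)
  diag(W) <- 0
  W
}

#' Normalized-cut spectral clustering of a weight matrix
#'
#' Negative weights are clipped at zero, the symmetric normalized Laplacian
#' is formed, the K eigenvectors of its smallest eigenvalues embed the
#' nodes, rows are unit-normalized, and k-means with a fixed seed
#' discretizes the embedding. A disconnected graph with at most K components
#' is partitioned per component with cluster counts allocated proportionally
#' to component size (at least one each).
#'
#' @param W square symmetric weight matrix (dense or sparse)
#' @param K number of clusters
#' @param seed seed for the k-means discretization
#' @return integer labels 1..K
#' @export
ncut_labels <- function(W, K, seed = 1) {
  W <- as.matrix(W)
  W <- pmax(W, 0)
  diag(W) <- 0
  n <- nrow(W)
  if (K <= 1) return(rep(1L, n))
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1 && comp$no <= K) {
    alloc <- .allocate_clusters(comp$csize, K)
    lab <- integer(n)
    offset <- 0L
    for (c in seq_len(comp$no)) {
      members <- which(comp$membership == c)
      kc <- alloc[c]
      sub <- if (kc == 1) rep(1L, length(members)) else {
        ncut_labels(W[members, members, drop = FALSE], kc, seed)
      }
      lab[members] <- sub + offset
      offset <- offset + kc
    }
    return(lab)
  }
  d <- rowSums(W)
  d[d == 0] <- .Machine$double.eps
  dm12 <- 1 / sqrt(d)
  Lsym <- diag(n) - (dm12 * W) * rep(dm12, each = n)
  Lsym <- (Lsym + t(Lsym)) / 2
  e <- eigen(Lsym, symmetric = TRUE)
  U <- e$vectors[, n:(n - K + 1), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  set.seed(seed)
  km <- stats::kmeans(U, centers = K, nstart = 10, iter.max = 100)
  as.integer(km$cluster)
}

## Largest-remainder allocation of K clusters to components, >= 1 each.
.allocate_clusters <- function(sizes, K) {
  n <- length(sizes)
  alloc <- rep(1L, n)
  extra <- K - n
  if (extra > 0) {
    quota <- sizes / sum(sizes) * extra
    alloc <- alloc + floor(quota)
    rem <- extra - sum(floor(quota))
    if (rem > 0) {
      ord <- order(quota - floor(quota), decreasing = TRUE)
      alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
    }
  }
  alloc
}

#' Normalized-cut voxel-level parcellation
#'
#' @param W weight matrix over in-mask voxels (from
#'   [weights_constrained_corr()] or [weights_gaussian()])
#' @param mask the [brain_mask()] the weights were computed on
#' @param K number of clusters
#' @param seed discretization seed
#' @return a [brain_atlas()]
#' @export
ncut_parcellate <- function(W, mask, K, seed = 1) {
  lab <- ncut_labels(W, K, seed)
  out <- array(0L, dim(mask$data))
  out[mask_index(mask)] <- lab
  brain_atlas(.densify_labels(out), mask$affine)
}

#' SLIC-as-atlas parcellation
#'
#' Runs SLIC with `K` target supervoxels and treats the supervoxels as the
#' clusters of the atlas.
#'
#' @param volume a [bold_volume()]
#' @param mask a [brain_mask()]
#' @param K number of clusters (target supervoxel count)
#' @param m SLIC compactness parameter
#' @param max_iter SLIC iterations
#' @return a [brain_atlas()]
#' @export
slic_parcellate <- function(volume, mask, K, m = 10, max_iter = 10) {
  sv <- run_slic(volume, mask, n_supervoxels = K, m = m, max_iter = max_iter)
  supervoxels_as_atlas(sv, mask$affine)
}

#' Random-parcellation null of an approach
#'
#' Applies the named approach to randomized input: the normalized-cut null
#' permutes the weight matrix ([permute_weight_matrix()]); the SLIC and
#' graph-learning nulls permute the voxel time series within the mask
#' ([permute_time_series()]). All other parameters are identical to the
#' non-random approach, so differences in evaluation metrics isolate the
#' approach's reliance on spatial structure.
#'
#' @param approach one of `"gwc"`, `"slic"`, `"ncut"`
#' @param volume a [bold_volume()] (for `"gwc"` and `"slic"`)
#' @param mask a [brain_mask()]
#' @param K cluster count
#' @param seed permutation seed
#' @param W weight matrix (for `"ncut"`)
#' @param m SLIC compactness (for `"slic"`)
#' @param ... further arguments passed to [gwc()] or [ncut_parcellate()]
#' @return a [brain_atlas()]
#' @export
random_variant <- function(approach = c("gwc", "slic", "ncut"),
                           volume = NULL, mask = NULL, K, seed = 1,
                           W = NULL, m = 10, ...) {
  approach <- match.arg(approach)
  switch(approach,
    gwc = {
      rb <- permute_time_series(volume, mask, seed)
      gwc(rb, mask, K, ...)$atlas
    },
    slic = {
      rb <- permute_time_series(volume, mask, seed)
      slic_parcellate(rb, mask, K, m = m, ...)
    },
    ncut = {
      Wr <- permute_weight_matrix(W, seed)
      ncut_parcellate(Wr, mask, K, seed = seed, ...)
    })
}
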
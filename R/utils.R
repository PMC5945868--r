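`%||%` <- function(a, b) if (is.null(a)) b else a

## In-mask voxels are enumerated in R's native array order (first index fastest),
## which gives every voxel a stable linear index used by all matrix-indexed
## structures (time-series matrices, weight matrices, supervoxel labels).

#' Linear indices of in-mask voxels
#' @param mask a `brain_mask`
#' @return integer vector of linear (1-based) array indices, x fastest
#' @keywords internal
mask_index <- function(mask) which(mask$data)

#' Voxel-index coordinates of in-mask voxels
#'
#' All spatial distances in the package are computed in 0-based voxel-index
#' units; world coordinates are obtained only through the affine.
#'
#' @param mask a `brain_mask`
#' @return 3 x N0 matrix of 0-based (x, y, z) coordinates
#' @keywords internal
voxel_coords <- function(mask) {
  t(arrayInd(mask_index(mask), dim(mask$data))) - 1
}

## The 26 neighbor offsets of a voxel, and the 13 "positive" half used when
## building undirected edge lists (each unordered pair visited once).
.offsets26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

.offsets26_half <- function() {
  o <- .offsets26()
  keep <- o[, 3] > 0 | (o[, 3] == 0 & o[, 2] > 0) |
    (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0)
  o[keep, , drop = FALSE]
}

## Edge list (pairs of linear grid indices) between 26-adjacent voxels that
## carry the same positive label. `labels3d` is an integer array with 0
## marking background.
.same_label_edges <- function(labels3d) {
  dims <- dim(labels3d)
  idx <- which(labels3d > 0)
  ai <- arrayInd(idx, dims)
  offs <- .offsets26_half()
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- ai + rep(offs[r, ], each = nrow(ai))
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nl <- (nb[ok, 3] - 1L) * dims[1] * dims[2] + (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    same <- labels3d[nl] == labels3d[idx[ok]] & labels3d[nl] > 0
    from <- c(from, idx[ok][same]); to <- c(to, nl[same])
  }
  cbind(from, to)
}

#' Label 26-connected components within each region of a labeled 3D array
#'
#' Voxels belong to the same component iff they carry the same positive label
#' and are connected through a 26-adjacency path inside that label.
#'
#' @param labels3d integer 3D array, 0 = background
#' @return integer 3D array of component ids (1..n_components), 0 outside
#' @keywords internal
grid_components <- function(labels3d) {
  dims <- dim(labels3d)
  idx <- which(labels3d > 0)
  if (length(idx) == 0) return(array(0L, dims))
  vid <- integer(prod(dims))
  vid[idx] <- seq_along(idx)
  ed <- .same_label_edges(labels3d)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(ed) > 0) {
    g <- igraph::add_edges(g, rbind(vid[ed[, 1]], vid[ed[, 2]]))
  }
  comp <- igraph::components(g)$membership
  out <- array(0L, dims)
  out[idx] <- as.integer(comp)
  out
}

## Column-wise z-scoring of a T x n series matrix (sample sd); constant
## series map to all-zero columns so that they correlate 0 with everything.
.zscore_cols <- function(V) {
  mu <- colMeans(V)
  V <- sweep(V, 2, mu)
  s <- sqrt(colSums(V^2) / (nrow(V) - 1))
  s[s == 0] <- Inf
  sweep(V, 2, s, "/")
}

## T x N0 matrix of in-mask voxel time courses, in mask order.
.series_matrix <- function(bold, mask) {
  dims <- dim(bold$data)
  v <- matrix(bold$data, prod(dims[1:3]), dims[4])
  t(v[mask_index(mask), , drop = FALSE])
}

## Relabel positive integers to a dense 1..K range preserving order of first
## numeric value (sorted unique labels map to 1..K).
.densify_labels <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  out <- lab
  out[lab > 0] <- match(lab[lab > 0], u)
  storage.mode(out) <- "integer"
  out
}
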
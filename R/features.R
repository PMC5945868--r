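## Per-supervoxel features and the graphs built from them. Three features
## enter the graph learning: the mean (z-scored) time course, a 12-bin
## intensity histogram of the temporal-mean image, and a 10-bin histogram of
## six-neighbor 3D local binary pattern (LBP) codes. The histogram and LBP
## features are computed on the temporal-mean 3D image; "mean intensity" is
## read as the supervoxel's mean z-scored time course so that the functional
## signal the parcellation targets is retained.

#' Mean time-course feature (T x N)
#'
#' Column n is the mean of the z-scored time courses of the voxels in
#' supervoxel n.
#'
#' @param volume a [bold_volume()]
#' @param mask a [brain_mask()]
#' @param sv a `supervoxel_map` built on the same mask
#' @return T x N matrix
#' @export
mean_intensity_feature <- function(volume, mask, sv) {
  V <- .zscore_cols(.series_matrix(volume, mask))
  t(rowsum(t(V), sv$labels) / sv$sizes)
}

#' Temporal-mean 3D image of a BOLD volume
#' @param volume a [bold_volume()]
#' @return 3D array of voxelwise temporal means
#' @export
temporal_mean_image <- function(volume) {
  apply(volume$data, 1:3, mean)
}

#' Per-supervoxel intensity histogram feature (n_bins x N)
#'
#' Member-voxel intensities are binned into `n_bins` equal-width bins
#' spanning the global in-mask intensity range; each column is normalized to
#' sum to one. A constant image degenerates to one-hot columns (all mass in
#' the bin containing the shared value).
#'
#' @param volume3d 3D scalar image (typically [temporal_mean_image()])
#' @param mask a [brain_mask()]
#' @param sv a `supervoxel_map`
#' @param n_bins number of bins
#' @return n_bins x N column-stochastic matrix
#' @export
intensity_histogram_feature <- function(volume3d, mask, sv, n_bins = 12) {
  x <- volume3d[mask_index(mask)]
  rng <- range(x)
  if (rng[1] == rng[2]) {
    bin <- rep(1L, length(x))
  } else {
    br <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin <- findInterval(x, br, rightmost.closed = TRUE)
  }
  H <- matrix(0, n_bins, sv$N)
  tab <- table(factor(bin, levels = seq_len(n_bins)), factor(sv$labels, levels = seq_len(sv$N)))
  H[] <- as.numeric(tab)
  sweep(H, 2, colSums(H), "/")
}

## ---- six-neighbor 3D LBP -------------------------------------------------

## Bit order of the 6 face neighbors: -x, +x, -y, +y, -z, +z (bits 1..6).
.lbp_dirs <- function() {
  rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
}

## The 24 proper rotations of the cube as permutations of the 6 face
## directions: enumerate signed permutation matrices with determinant +1.
.lbp_rotation_perms <- function() {
  dirs <- .lbp_dirs()
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  out <- list()
  for (p in perms3) {
    P <- diag(3)[p, , drop = FALSE]
    for (r in seq_len(nrow(signs))) {
      R <- diag(signs[r, ]) %*% P
      if (abs(det(R) - 1) > 1e-9) next
      rotated <- dirs %*% t(R)
      perm <- match(
        apply(rotated, 1, paste, collapse = ","),
        apply(dirs, 1, paste, collapse = ",")
      )
      out[[length(out) + 1]] <- perm
    }
  }
  unique(out)
}

.lbp_cache <- new.env(parent = emptyenv())

#' Grouping of the 64 six-neighbor LBP patterns under cube rotations
#'
#' All `2^6` binary patterns over the six face neighbors are grouped into
#' equivalence classes under the 24 proper rotations of the cube; classes are
#' ordered by their minimal pattern integer. Exactly 10 classes exist
#' (Burnside's lemma on the octahedral rotation action).
#'
#' @return integer vector of length 64: group id (1..10) of patterns 0..63
#' @export
lbp_group_table <- function() {
  if (!is.null(.lbp_cache$table)) return(.lbp_cache$table)
  perms <- .lbp_rotation_perms()
  bits <- t(sapply(0:63, function(p) as.integer(intToBits(p)[1:6])))
  canon <- integer(64)
  for (p in 0:63) {
    orbit <- vapply(perms, function(pr) {
      sum(bits[p + 1, pr] * 2^(0:5))
    }, numeric(1))
    canon[p + 1] <- min(orbit)
  }
  classes <- sort(unique(canon))
  .lbp_cache$table <- match(canon, classes)
  .lbp_cache$table
}

#' Six-neighbor 3D LBP codes, grouped under cube rotations
#'
#' Each in-mask voxel's six face neighbors are thresholded against the
#' center (neighbor >= center encodes 1; out-of-mask or out-of-grid
#' neighbors encode 0), yielding a 6-bit pattern that is mapped to its
#' rotation-equivalence class.
#'
#' @param volume3d 3D scalar image
#' @param mask a [brain_mask()]
#' @return integer 3D array of group ids (1..10) in-mask, 0 outside
#' @export
lbp3d_codes <- function(volume3d, mask) {
  dims <- dim(volume3d)
  idx <- mask_index(mask)
  ai <- arrayInd(idx, dims)
  dirs <- .lbp_dirs()
  pattern <- integer(length(idx))
  ctr <- volume3d[idx]
  for (b in 1:6) {
    nb <- ai + rep(dirs[b, ], each = nrow(ai))
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nl <- (pmax(nb[, 3], 1) - 1L) * dims[1] * dims[2] +
      (pmax(nb[, 2], 1) - 1L) * dims[1] + pmax(nb[, 1], 1)
    val <- rep(-Inf, length(idx))
    inm <- ok & mask$data[nl]
    val[inm] <- volume3d[nl[inm]]
    pattern <- pattern + bitwShiftL(as.integer(val >= ctr), b - 1L)
  }
  tab <- lbp_group_table()
  out <- array(0L, dims)
  out[idx] <- tab[pattern + 1L]
  out
}

#' Per-supervoxel LBP histogram feature (10 x N)
#'
#' @param codes output of [lbp3d_codes()]
#' @param mask a [brain_mask()]
#' @param sv a `supervoxel_map`
#' @return 10 x N column-stochastic matrix
#' @export
lbp_histogram_feature <- function(codes, mask, sv) {
  cd <- codes[mask_index(mask)]
  n_groups <- max(lbp_group_table())
  tab <- table(factor(cd, levels = seq_len(n_groups)),
               factor(sv$labels, levels = seq_len(sv$N)))
  H <- matrix(as.numeric(tab), n_groups, sv$N)
  sweep(H, 2, colSums(H), "/")
}

#' Extract the full feature set of a supervoxel map
#'
#' @param volume a [bold_volume()]
#' @param mask a [brain_mask()]
#' @param sv a `supervoxel_map`
#' @param n_bins intensity histogram bins
#' @return object of class `feature_set`: list with `Y` (named list of
#'   feature matrices, each d_m x N), `d` (dimensions), `names`
#' @export
supervoxel_features <- function(volume, mask, sv, n_bins = 12) {
  mimg <- temporal_mean_image(volume)
  Y <- list(
    mean_series = mean_intensity_feature(volume, mask, sv),
    intensity_histogram = intensity_histogram_feature(mimg, mask, sv, n_bins),
    lbp_histogram = lbp_histogram_feature(lbp3d_codes(mimg, mask), mask, sv)
  )
  structure(list(Y = Y, d = vapply(Y, nrow, integer(1)), names = names(Y)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("Feature set: ", length(x$Y), " features over ",
      ncol(x$Y[[1]]), " supervoxels\n", sep = "")
  for (nm in names(x$Y)) cat("  ", nm, ": d = ", nrow(x$Y[[nm]]), "\n", sep = "")
  invisible(x)
}

## ---- graphs --------------------------------------------------------------

#' Pairwise Euclidean distance graph of a point set
#'
#' @param points d x N matrix (one column per supervoxel)
#' @return N x N symmetric matrix of (unsquared) Euclidean distances with
#'   zero diagonal and attribute `normalized = FALSE`
#' @export
distance_graph <- function(points) {
  if (ncol(points) < 2) stop("need at least two points")
  G <- as.matrix(stats::dist(t(points)))
  dimnames(G) <- NULL
  attr(G, "normalized") <- FALSE
  G
}

#' Normalize a graph by its maximum entry
#'
#' Every entry is divided by the maximum value in the graph, putting graphs
#' built from differently scaled quantities on a common scale. An all-zero
#' graph is returned unchanged. Idempotent.
#'
#' @param G matrix from [distance_graph()]
#' @return matrix with maximum entry 1 (unless all-zero), attribute
#'   `normalized = TRUE`
#' @export
normalize_graph <- function(G) {
  mx <- max(G)
  if (mx > 0) G <- G / mx
  attr(G, "normalized") <- TRUE
  G
}

#' Spatial adjacency graph of supervoxels, and neighbor-count estimate
#'
#' `S0[i, j] = 1` iff some voxel of supervoxel i and some voxel of supervoxel
#' j are 26-adjacent (i != j). The sparsity parameter `k_est` is the mean
#' column sum of S0 rounded to an integer (round half to even), used as the
#' default number of nonzero affinities per supervoxel in the graph learning.
#'
#' @param sv a `supervoxel_map`
#' @return list with `S0` (N x N binary symmetric matrix, zero diagonal) and
#'   `k_est`
#' @export
spatial_adjacency <- function(sv) {
  N <- sv$N
  if (N < 2) stop("graph too small: need at least 2 supervoxels")
  dims <- dim(sv$labels3d)
  idx <- which(sv$labels3d > 0)
  ai <- arrayInd(idx, dims)
  offs <- .offsets26_half()
  S0 <- matrix(0, N, N)
  for (r in seq_len(nrow(offs))) {
    nb <- ai + rep(offs[r, ], each = nrow(ai))
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nl <- (nb[ok, 3] - 1L) * dims[1] * dims[2] + (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    a <- sv$labels3d[idx[ok]]
    b <- sv$labels3d[nl]
    diff <- b > 0 & b != a
    if (any(diff)) {
      S0[cbind(a[diff], b[diff])] <- 1
      S0[cbind(b[diff], a[diff])] <- 1
    }
  }
  list(S0 = S0, k_est = as.integer(round(mean(colSums(S0)))))
}
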
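## Phantom generator and randomization procedures. Phantoms plant spatially
## contiguous parcels whose voxels share a latent time course plus i.i.d.
## Gaussian noise, so every pipeline stage is testable without real data.

#' Generate a synthetic BOLD phantom with planted contiguous parcels
#'
#' The in-mask grid is partitioned into `K_true` spatially contiguous parcels
#' by nearest-seed growth from `K_true` random in-mask seed voxels (Euclidean
#' distance in voxel-index coordinates, ties broken toward the lower parcel
#' id). Each parcel carries an independent standard-Gaussian latent time
#' course of length `T`; each voxel observes its parcel's latent series plus
#' i.i.d. Gaussian noise of standard deviation `1/snr`.
#'
#' @param shape integer 3-vector of grid dimensions
#' @param K_true number of planted parcels
#' @param T_len number of time points
#' @param snr ratio of latent-signal s.d. to noise s.d.; `Inf` for noiseless
#' @param mask_kind `"box"` (full grid) or `"ellipsoid"` (inscribed)
#' @param seed RNG seed
#' @param smooth optional moving-average window (in time points) applied to
#'   the latent courses; 0 disables smoothing
#' @return list with elements `bold` ([bold_volume()]), `mask`
#'   ([brain_mask()]), `atlas` (ground-truth [brain_atlas()]), and `latent`
#'   (T x K_true latent course matrix)
#' @export
make_phantom <- function(shape = c(20, 20, 12), K_true = 8, T_len = 60,
                         snr = 8, mask_kind = c("box", "ellipsoid"),
                         seed = 1, smooth = 0) {
  mask_kind <- match.arg(mask_kind)
  stopifnot(length(shape) == 3, K_true >= 1, T_len >= 2, snr > 0)
  set.seed(seed)
  m <- array(TRUE, shape)
  if (mask_kind == "ellipsoid") {
    ctr <- (shape - 1) / 2
    rad <- shape / 2
    ai <- arrayInd(seq_len(prod(shape)), shape) - 1
    m <- array(colSums((t(ai) - ctr)^2 / rad^2) <= 1, shape)
  }
  mask <- brain_mask(m)
  if (K_true > mask$N0) stop("K_true exceeds the in-mask voxel count")
  coords <- voxel_coords(mask)            # 3 x N0
  seeds <- sample.int(mask$N0, K_true)
  ## nearest-seed growth; which.min breaks ties toward the lower parcel id
  d2 <- matrix(0, K_true, mask$N0)
  for (k in seq_len(K_true)) {
    d2[k, ] <- colSums((coords - coords[, seeds[k]])^2)
  }
  parcel <- apply(d2, 2, which.min)
  labels <- array(0L, shape)
  labels[mask_index(mask)] <- as.integer(parcel)
  atlas <- brain_atlas(labels)

  latent <- matrix(stats::rnorm(T_len * K_true), T_len, K_true)
  if (smooth > 0) {
    w <- rep(1 / (2 * smooth + 1), 2 * smooth + 1)
    latent <- apply(latent, 2, function(x) {
      y <- stats::filter(x, w, sides = 2)
      y[is.na(y)] <- x[is.na(y)]
      as.numeric(y)
    })
  }
  noise_sd <- if (is.finite(snr)) 1 / snr else 0
  series <- latent[, parcel, drop = FALSE] +
    matrix(stats::rnorm(T_len * mask$N0, sd = noise_sd), T_len, mask$N0)
  dat <- array(0, c(shape, T_len))
  flat <- matrix(dat, prod(shape), T_len)
  flat[mask_index(mask), ] <- t(series)
  bold <- bold_volume(array(flat, c(shape, T_len)))
  list(bold = bold, mask = mask, atlas = atlas, latent = latent)
}

#' Randomly permute in-mask voxel time series
#'
#' The multiset of in-mask time courses is preserved; their spatial
#' assignment is a uniform random permutation. Out-of-mask voxels are
#' untouched. This destroys spatial structure while preserving each series'
#' autocorrelation, and is the null input for the random SLIC and random
#' graph-learning parcellations.
#'
#' @param volume a [bold_volume()]
#' @param mask a [brain_mask()]
#' @param seed RNG seed
#' @return a [bold_volume()] with permuted in-mask series
#' @export
permute_time_series <- function(volume, mask, seed = 1) {
  set.seed(seed)
  idx <- mask_index(mask)
  perm <- sample.int(length(idx))
  d <- dim(volume$data)
  flat <- matrix(volume$data, prod(d[1:3]), d[4])
  flat[idx, ] <- flat[idx[perm], , drop = FALSE]
  bold_volume(array(flat, d), volume$affine)
}

#' Randomly permute a symmetric weight matrix
#'
#' Off-diagonal entries of the upper triangle are uniformly permuted, the
#' result is symmetrized, and the diagonal is preserved; the multiset of
#' upper-triangle values is conserved. This is the null input for the random
#' normalized-cut parcellation.
#'
#' @param W square symmetric matrix (dense or `Matrix` sparse)
#' @param seed RNG seed
#' @return matrix of the same shape
#' @export
permute_weight_matrix <- function(W, seed = 1) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  set.seed(seed)
  up <- upper.tri(W)
  vals <- W[up]
  W[up] <- vals[sample.int(length(vals))]
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}
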
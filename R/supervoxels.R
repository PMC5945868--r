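## SLIC supervoxels computed directly on the BOLD time series: local k-means
## in a unified functional + spatial metric, followed by connectivity
## enforcement so that every supervoxel is a single 26-connected region.

#' Unified SLIC distance between two voxels
#'
#' `||v_i - v_j||^2 / m^2 + ||u_i - u_j||^2 / S^2`: the squared functional
#' distance between time courses normalized by the compactness parameter `m`,
#' plus the squared spatial distance (voxel-index units) normalized by the
#' seed grid spacing `S`.
#'
#' @param v_i,v_j time courses (equal length)
#' @param u_i,u_j voxel-index coordinates (length 3)
#' @param m compactness normalizer for the functional distance
#' @param spacing spatial normalizer S (average supervoxel side length)
#' @return nonnegative scalar
#' @export
unified_distance <- function(v_i, v_j, u_i, u_j, m = 10, spacing = 1) {
  if (length(v_i) != length(v_j)) {
    stop("time courses differ in length: ", length(v_i), " vs ", length(v_j))
  }
  sum((v_i - v_j)^2) / m^2 + sum((u_i - u_j)^2) / spacing^2
}

## Distance from every voxel (columns of V/coords) to its assigned centroid.
.assigned_distance <- function(V, coords, cser, ccoord, lab, m, spacing) {
  colSums((V - cser[, lab, drop = FALSE])^2) / m^2 +
    colSums((coords - ccoord[, lab, drop = FALSE])^2) / spacing^2
}

#' SLIC supervoxels on resting-state fMRI time series
#'
#' Seeds are initialized on a regular 3D grid with spacing
#' `round((N0 / n_supervoxels)^(1/3))` restricted to the mask (seeds falling
#' outside are moved to the nearest in-mask voxel). Each iteration assigns
#' every voxel within a +/- S window of a seed to the seed minimizing the
#' [unified_distance()], then recomputes seed centroids and mean series.
#' Voxel time courses are z-scored before distance computation, which makes
#' the functional distance an affine function of Pearson correlation. After
#' `max_iter` iterations, disconnected fragments are merged into the
#' 26-adjacent supervoxel sharing the longest boundary, so every supervoxel
#' is 26-connected. The realized supervoxel count N may differ slightly from
#' `n_supervoxels`.
#'
#' @param volume a [bold_volume()]
#' @param mask a [brain_mask()]
#' @param n_supervoxels target supervoxel count
#' @param m compactness parameter of the unified distance
#' @param max_iter assignment/update iterations
#' @return object of class `supervoxel_map` with fields `labels3d` (integer
#'   array), `labels` (per in-mask voxel), `N`, `centroids` (3 x N, 0-based
#'   voxel coordinates), `mean_series` (T x N mean z-scored courses), `sizes`,
#'   `spacing`, and `objective` (per-iteration data frame with the SLIC
#'   objective before and after each assignment step)
#' @export
run_slic <- function(volume, mask, n_supervoxels = 1000, m = 10,
                     max_iter = 10) {
  stopifnot(n_supervoxels >= 1, m > 0)
  if (n_supervoxels > mask$N0) {
    stop("n_supervoxels (", n_supervoxels, ") exceeds N0 (", mask$N0, ")")
  }
  dims <- dim(mask$data)
  V <- .zscore_cols(.series_matrix(volume, mask))   # T x N0
  coords <- voxel_coords(mask)                      # 3 x N0, 0-based
  N0 <- mask$N0
  spacing <- (N0 / n_supervoxels)^(1 / 3)
  step <- max(1L, as.integer(round(spacing)))

  ## voxel-id lookup: grid linear index -> in-mask column, 0 if out of mask
  vid <- integer(prod(dims))
  vid[mask_index(mask)] <- seq_len(N0)

  ## regular seed grid, snapped into the mask
  ax <- lapply(dims, function(d) seq(floor(step / 2), d - 1, by = step))
  cand <- as.matrix(expand.grid(ax))                # 0-based grid coords
  lin <- (cand[, 3]) * dims[1] * dims[2] + (cand[, 2]) * dims[1] + cand[, 1] + 1
  seed_vox <- vid[lin]
  if (any(seed_vox == 0)) {
    out <- which(seed_vox == 0)
    for (s in out) {
      d2 <- colSums((coords - cand[s, ])^2)
      seed_vox[s] <- which.min(d2)
    }
  }
  seed_vox <- unique(seed_vox)
  N <- length(seed_vox)
  ccoord <- coords[, seed_vox, drop = FALSE]
  cser <- V[, seed_vox, drop = FALSE]

  lab <- integer(N0)
  obj_hist <- data.frame(iteration = integer(0), before = numeric(0),
                         after = numeric(0))
  for (it in seq_len(max_iter)) {
    before <- if (it > 1) {
      sum(.assigned_distance(V, coords, cser, ccoord, lab, m, spacing))
    } else NA_real_
    best_d <- rep(Inf, N0)
    best_l <- integer(N0)
    for (c in seq_len(N)) {
      lo <- pmax(ceiling(ccoord[, c] - spacing), 0)
      hi <- pmin(floor(ccoord[, c] + spacing), dims - 1)
      if (any(lo > hi)) next
      box <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
      blin <- box[, 3] * dims[1] * dims[2] + box[, 2] * dims[1] + box[, 1] + 1
      w <- vid[blin]
      w <- w[w > 0]
      if (length(w) == 0) next
      d <- colSums((V[, w, drop = FALSE] - cser[, c])^2) / m^2 +
        colSums((coords[, w, drop = FALSE] - ccoord[, c])^2) / spacing^2
      upd <- d < best_d[w]
      best_d[w[upd]] <- d[upd]
      best_l[w[upd]] <- c
    }
    ## voxels outside every window: full search against all centroids
    left <- which(best_l == 0L)
    if (length(left) > 0) {
      fd <- (outer(colSums(V[, left, drop = FALSE]^2), colSums(cser^2), "+") -
               2 * crossprod(V[, left, drop = FALSE], cser)) / m^2
      sd2 <- (outer(colSums(coords[, left, drop = FALSE]^2),
                    colSums(ccoord^2), "+") -
                2 * crossprod(coords[, left, drop = FALSE], ccoord)) / spacing^2
      tot <- fd + sd2
      best_l[left] <- max.col(-tot, ties.method = "first")
      best_d[left] <- tot[cbind(seq_along(left), best_l[left])]
    }
    lab <- best_l
    obj_hist <- rbind(obj_hist, data.frame(iteration = it, before = before,
                                           after = sum(best_d)))
    ## centroid / mean-series update
    sz <- tabulate(lab, N)
    keep <- sz > 0
    ccoord <- t(rowsum(t(coords), lab)[as.character(which(keep)), , drop = FALSE] /
                  sz[keep])
    cser <- t(rowsum(t(V), lab)[as.character(which(keep)), , drop = FALSE] /
                sz[keep])
    if (!all(keep)) {
      lab <- match(lab, which(keep))
      N <- sum(keep)
    }
  }

  labels3d <- array(0L, dims)
  labels3d[mask_index(mask)] <- lab
  labels3d <- .enforce_connectivity(labels3d)
  lab <- labels3d[mask_index(mask)]
  N <- max(lab)
  sz <- tabulate(lab, N)
  ccoord <- t(rowsum(t(coords), lab) / sz)
  cser <- t(rowsum(t(V), lab) / sz)

  structure(list(labels3d = labels3d, labels = lab, N = N,
                 centroids = ccoord, mean_series = cser, sizes = sz,
                 spacing = spacing, m = m, objective = obj_hist,
                 mask = mask),
            class = "supervoxel_map")
}

## Keep the largest 26-connected component of every label; merge each other
## fragment into the 26-adjacent label sharing the longest boundary
## (tie: smaller label). Iterates until all labels are single components.
.enforce_connectivity <- function(labels3d) {
  dims <- dim(labels3d)
  offs <- .offsets26()
  for (pass in 1:20) {
    comp <- grid_components(labels3d)
    idx <- which(labels3d > 0)
    key <- paste(labels3d[idx], comp[idx])
    tab <- table(key)
    ## components per label
    lab_of_key <- as.integer(sub(" .*", "", names(tab)))
    multi <- lab_of_key[duplicated(lab_of_key)]
    if (length(multi) == 0) break
    ## component sizes; the largest component of each label is kept
    sizes <- as.integer(tab)
    names(sizes) <- names(tab)
    for (lv in unique(multi)) {
      ks <- names(sizes)[lab_of_key == lv]
      keep <- ks[which.max(sizes[ks])]
      for (kk in setdiff(ks, keep)) {
        cid <- as.integer(sub(".* ", "", kk))
        frag <- which(labels3d == lv & comp == cid)
        ai <- arrayInd(frag, dims)
        nb_lab <- integer(0)
        for (r in seq_len(nrow(offs))) {
          nb <- ai + rep(offs[r, ], each = nrow(ai))
          ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
          if (!any(ok)) next
          nl <- (nb[ok, 3] - 1L) * dims[1] * dims[2] +
            (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
          nv <- labels3d[nl]
          nb_lab <- c(nb_lab, nv[nv > 0 & nv != lv])
        }
        if (length(nb_lab) == 0) next   # isolated label island; keep as is
        cnt <- table(nb_lab)
        tgt <- as.integer(names(cnt)[cnt == max(cnt)])
        labels3d[frag] <- min(tgt)
      }
    }
  }
  .densify_labels(labels3d)
}

#' @export
print.supervoxel_map <- function(x, ...) {
  cat("Supervoxel map: N = ", x$N, " supervoxels over ",
      sum(x$sizes), " voxels (sizes ", min(x$sizes), "-", max(x$sizes),
      ", spacing S = ", round(x$spacing, 2), ")\n", sep = "")
  invisible(x)
}

#' Convert a supervoxel map to an atlas (supervoxels as clusters)
#' @param sv a `supervoxel_map`
#' @param affine 4x4 transform for the atlas
#' @return a [brain_atlas()]
#' @export
supervoxels_as_atlas <- function(sv, affine = diag(4)) {
  brain_atlas(sv$labels3d, affine)
}
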
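## Volumetric containers and NIfTI-1 I/O. Grids are voxel-index addressed
## (0-based in all distance computations); world mm coordinates exist only
## through the 4x4 affine carried alongside each array.

#' Construct a 4D BOLD volume
#'
#' @param data 4D numeric array (nx, ny, nz, T)
#' @param affine 4x4 voxel-index-to-world transform
#' @return object of class `bold_volume` with fields `data`, `affine`, `T`
#' @export
bold_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 4) {
    stop("BOLD volume must be 4D; found rank ", length(dim(data)))
  }
  if (dim(data)[4] < 2) stop("T >= 2 required; found T = ", dim(data)[4])
  structure(list(data = data, affine = affine, T = dim(data)[4]),
            class = "bold_volume")
}

#' Construct a binary brain mask
#'
#' Nonzero voxels are in-mask. The mask grid must be congruent with the
#' volume it is paired with.
#'
#' @param data 3D array; nonzero values mark in-mask voxels
#' @param affine 4x4 transform
#' @return object of class `brain_mask` with fields `data` (logical array),
#'   `affine`, `N0` (in-mask voxel count)
#' @export
brain_mask <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3) {
    stop("mask must be 3D; found rank ", length(dim(data)))
  }
  m <- array(data != 0, dim(data))
  n0 <- sum(m)
  if (n0 < 1) stop("empty mask: no in-mask voxels")
  structure(list(data = m, affine = affine, N0 = n0), class = "brain_mask")
}

#' Construct a brain atlas (voxel-level parcellation)
#'
#' Labels are nonnegative integers, 0 outside the mask and 1..K inside.
#'
#' @param labels 3D integer array of cluster labels
#' @param affine 4x4 transform
#' @return object of class `brain_atlas` with fields `labels`, `affine`, `K`
#' @export
brain_atlas <- function(labels, affine = diag(4)) {
  if (length(dim(labels)) != 3) {
    stop("atlas labels must be 3D; found rank ", length(dim(labels)))
  }
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("atlas labels must be nonnegative integers")
  }
  storage.mode(labels) <- "integer"
  k <- length(unique(labels[labels > 0]))
  structure(list(labels = labels, affine = affine, K = k),
            class = "brain_atlas")
}

.read_affine <- function(img) {
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4, 4))
  aff
}

.write_nifti <- function(arr, affine, path, datatype = "auto") {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::`sform<-`(img, structure(affine, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(affine, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a 4D BOLD volume from a NIfTI-1 file
#'
#' @param path path to a .nii or .nii.gz file
#' @return a [bold_volume()]
#' @export
read_bold <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) {
    stop("expected a 4D BOLD image; found rank ", length(d), " in ", path)
  }
  bold_volume(array(as.numeric(img), d), .read_affine(img))
}

#' Read a 3D brain mask from a NIfTI-1 file
#'
#' @param path path to a .nii or .nii.gz file
#' @param volume optional [bold_volume()] whose grid the mask must match
#' @return a [brain_mask()]
#' @export
read_mask <- function(path, volume = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) stop("expected a 3D mask; found rank ", length(d))
  if (!is.null(volume) && !all(d == dim(volume$data)[1:3])) {
    stop("mask grid ", paste(d, collapse = "x"),
         " does not match volume grid ",
         paste(dim(volume$data)[1:3], collapse = "x"))
  }
  m <- brain_mask(array(as.numeric(img), d), .read_affine(img))
  if (!is.null(volume)) {
    v <- .series_matrix(volume, m)
    if (!all(is.finite(v))) stop("non-finite values inside the mask")
  }
  m
}

#' Read an atlas from a NIfTI-1 file
#'
#' @param path path to a .nii or .nii.gz file
#' @return a [brain_atlas()]
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) stop("expected a 3D atlas; found rank ", length(d))
  brain_atlas(array(as.integer(img), d), .read_affine(img))
}

#' Write an atlas as an integer NIfTI-1 file
#'
#' Label values are densified to 1..K before writing (a warning is issued if
#' gaps were present) so that downstream metrics can assume contiguous label
#' ranges. Round trips are bit exact.
#'
#' @param atlas a [brain_atlas()]
#' @param path output path (.nii or .nii.gz)
#' @return the path, invisibly
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "brain_atlas"))
  lab <- atlas$labels
  u <- sort(unique(lab[lab > 0]))
  if (length(u) > 0 && !identical(u, seq_along(u))) {
    warning("atlas labels had gaps; relabeled to 1..", length(u))
    lab <- .densify_labels(lab)
  }
  .write_nifti(lab, atlas$affine, path, datatype = "int32")
}

#' Write a BOLD volume as NIfTI-1
#' @param volume a [bold_volume()]
#' @param path output path
#' @export
write_bold <- function(volume, path) {
  .write_nifti(volume$data, volume$affine, path, datatype = "double")
}

#' Write a brain mask as NIfTI-1
#' @param mask a [brain_mask()]
#' @param path output path
#' @export
write_mask <- function(mask, path) {
  .write_nifti(array(as.integer(mask$data), dim(mask$data)),
               mask$affine, path, datatype = "int32")
}

#' @export
print.bold_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("BOLD volume: ", paste(d[1:3], collapse = " x "),
      " grid, T = ", d[4], " time points\n", sep = "")
  invisible(x)
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("Brain mask: ", paste(dim(x$data), collapse = " x "),
      " grid, N0 = ", x$N0, " in-mask voxels\n", sep = "")
  invisible(x)
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat("Brain atlas: ", paste(dim(x$labels), collapse = " x "),
      " grid, ", x$K, " clusters over ", sum(x$labels > 0),
      " voxels\n", sep = "")
  invisible(x)
}
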
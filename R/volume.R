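#' CT volume container
#'
#' A minimal container for a HU-calibrated CT volume in the package's
#' canonical anatomical orientation: axis 1 runs left to right (x), axis 2
#' posterior to anterior (y), axis 3 inferior to superior (z). Voxel
#' \code{[i, j, k]} (1-based) occupies the half-open box
#' \code{[(i-1)*dx, i*dx) x [(j-1)*dy, j*dy) x [(k-1)*dz, k*dz)} in
#' volume-local millimetre coordinates (origin at the corner of the first
#' voxel), so its centre is at \code{((i-1/2)*dx, (j-1/2)*dy, (k-1/2)*dz)}.
#' Voxels are stored as floating-point HU; no integer quantisation is
#' applied anywhere in the pipeline.
#'
#' @param data 3-D numeric array of HU values.
#' @param spacing numeric length-3, millimetres per voxel along (x, y, z).
#' @param origin numeric length-3, scanner-space position of the volume
#'   corner in mm (informational; all package geometry is volume-local).
#' @return an object of class \code{ct_volume}.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  check_that(is.array(data) && length(dim(data)) == 3L,
             "ct_volume: `data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  check_that(length(spacing) == 3L && all(is.finite(spacing)) && all(spacing > 0),
             "ct_volume: `spacing` must be 3 positive finite numbers")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

# Centre coordinates (mm) of voxels along one axis.
voxel_centers <- function(n, dx) (seq_len(n) - 0.5) * dx

#' Write a CT volume to NIfTI
#'
#' The canonical orientation maps directly onto NIfTI's RAS+ convention,
#' so the stored affine is a pure diagonal scaling by the voxel spacing.
#' The (informational) origin is not persisted; all package geometry is
#' volume-local.
#'
#' @param volume a [ct_volume()].
#' @param path output path; \code{.nii} or \code{.nii.gz}.
#' @return \code{path}, invisibly.
#' @export
write_ct_volume <- function(volume, path) {
  check_that(inherits(volume, "ct_volume"), "write_ct_volume: not a ct_volume")
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a CT volume from NIfTI, normalising to the canonical orientation
#'
#' The file's affine is inspected: each voxel axis must point along a
#' scanner axis to within 5 degrees (oblique acquisitions are rejected),
#' and the data array is permuted/flipped so that the returned array is in
#' the canonical left-right / posterior-anterior / inferior-superior
#' order.
#'
#' @param path a NIfTI file.
#' @return a [ct_volume()].
#' @export
read_ct_volume <- function(path) {
  check_that(file.exists(path), paste0("read_ct_volume: no such file: ", path))
  img <- RNifti::readNifti(path)
  check_that(length(dim(img)) == 3L, "read_ct_volume: expected a 3-D volume")
  affine <- RNifti::xform(img)
  rot <- affine[1:3, 1:3]
  spacing_in <- sqrt(colSums(rot^2))
  check_that(all(spacing_in > 0), "read_ct_volume: degenerate affine")
  dirs <- sweep(rot, 2, spacing_in, "/")
  perm <- integer(3); flip <- logical(3)
  for (ax in 1:3) {
    target <- max.col(t(abs(dirs)))[ax]  # scanner axis this voxel axis points along
    cosang <- abs(dirs[target, ax])
    check_that(cosang >= cos(5 * pi / 180),
               sprintf("read_ct_volume: voxel axis %d is oblique (> 5 deg from a scanner axis)", ax))
    perm[target] <- ax
    flip[target] <- dirs[target, ax] < 0
  }
  check_that(all(perm > 0) && !anyDuplicated(perm),
             "read_ct_volume: affine does not define three distinct axes")
  arr <- aperm(as.array(img), perm)
  for (ax in 1:3) {
    if (flip[ax]) {
      idx <- rev(seq_len(dim(arr)[ax]))
      arr <- switch(ax, arr[idx, , , drop = FALSE],
                    arr[, idx, , drop = FALSE], arr[, , idx, drop = FALSE])
    }
  }
  ct_volume(arr, spacing = spacing_in[perm], origin = affine[1:3, 4])
}
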
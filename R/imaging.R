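#' Window settings for display mapping
#'
#' Defaults are the bone-window settings used for AAC reading: width
#' 2500 HU, level (centre) 200 HU.
#'
#' @param width window width in HU (> 0).
#' @param level window level / centre in HU.
#' @return an object of class \code{window_settings}.
#' @export
window_settings <- function(width = 2500, level = 200) {
  check_that(is.numeric(width) && width > 0, "window_settings: width must be > 0")
  structure(list(width = as.numeric(width), level = as.numeric(level)),
            class = "window_settings")
}

#' Sagittal slab maximum intensity projection
#'
#' Projects a slab of the volume along x onto the sagittal (z, y) plane:
#' each output pixel is the maximum HU over the slab columns. The slab is
#' specified in millimetres and converted to voxel columns by half-open
#' rounding \code{[floor(lo/dx), ceil(hi/dx))}, so a 20 mm slab at 1 mm
#' spacing covers exactly 20 columns. A slab partly outside the volume is
#' clipped with a warning; a slab fully outside is an error.
#'
#' @param volume a [ct_volume()].
#' @param center_x slab centre along x, in mm.
#' @param thickness slab thickness in mm (default 20).
#' @return an object of class \code{sagittal_mip}: a list with
#'   \code{image} (matrix, rows = z increasing inferior to superior,
#'   cols = y increasing posterior to anterior), \code{thickness},
#'   \code{center_x} and the y/z spacings.
#' @export
sagittal_mip <- function(volume, center_x, thickness = 20) {
  check_that(inherits(volume, "ct_volume"), "sagittal_mip: not a ct_volume")
  check_that(thickness > 0, "sagittal_mip: thickness must be > 0")
  dx <- volume$spacing[1]; nx <- dim(volume$data)[1]
  lo <- center_x - thickness / 2
  hi <- center_x + thickness / 2
  check_that(hi > 0 && lo < nx * dx, "sagittal_mip: slab lies fully outside the volume")
  i_lo <- floor(lo / dx)      # 0-based half-open column range
  i_hi <- ceiling(hi / dx)
  if (i_lo < 0 || i_hi > nx) {
    warning("sagittal_mip: slab clipped to volume bounds", call. = FALSE)
    i_lo <- max(i_lo, 0L); i_hi <- min(i_hi, nx)
  }
  cols <- seq.int(i_lo + 1L, i_hi)
  slab <- volume$data[cols, , , drop = FALSE]
  img <- apply(slab, c(3, 2), max)  # rows = z, cols = y
  structure(list(image = img, thickness = thickness, center_x = center_x,
                 spacing_y = volume$spacing[2], spacing_z = volume$spacing[3]),
            class = "sagittal_mip")
}

#' Map HU values to 8-bit display intensities
#'
#' The standard linear window/level mapping:
#' \code{display = round(255 * clip((HU - (level - width/2)) / width, 0, 1))},
#' with rounding half away from zero so exported images are bit-identical
#' across platforms. Monotone non-decreasing in HU; depends only on HU
#' values, never on voxel spacing.
#'
#' @param image numeric matrix or array of HU values (or a
#'   \code{sagittal_mip}, whose image slot is used).
#' @param w a [window_settings()].
#' @return integer array of the same shape, values in 0..255.
#' @export
apply_window <- function(image, w = window_settings()) {
  check_that(inherits(w, "window_settings"), "apply_window: w must be window_settings")
  if (inherits(image, "sagittal_mip")) image <- image$image
  lo <- w$level - w$width / 2
  frac <- pmin(pmax((image - lo) / w$width, 0), 1)
  out <- round_half_away(255 * frac)
  storage.mode(out) <- "integer"
  out
}

#' Export a windowed MIP as PNG
#'
#' Radiological display orientation: superior at the top (z decreasing
#' down the rows), anterior to the right.
#'
#' @param mip a [sagittal_mip()].
#' @param path output PNG path.
#' @param w a [window_settings()].
#' @return \code{path}, invisibly.
#' @export
write_mip_png <- function(mip, path, w = window_settings()) {
  check_that(inherits(mip, "sagittal_mip"), "write_mip_png: not a sagittal_mip")
  disp <- apply_window(mip$image, w)
  png::writePNG(disp[rev(seq_len(nrow(disp))), , drop = FALSE] / 255, path)
  invisible(path)
}
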
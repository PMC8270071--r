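#' Detect calcified voxels by HU band
#'
#' Thresholds the volume with the calcium detection band used for aortic
#' plaque selection: minimum 450 HU, maximum 3070 HU. Both bounds are
#' inclusive.
#'
#' @param volume a [ct_volume()].
#' @param min_hu,max_hu detection band in HU; \code{min_hu < max_hu}.
#' @return an object of class \code{calc_mask}: logical array aligned to
#'   the volume plus the band used.
#' @export
detect_calcification <- function(volume, min_hu = 450, max_hu = 3070) {
  check_that(inherits(volume, "ct_volume"), "detect_calcification: not a ct_volume")
  check_that(min_hu < max_hu, "detect_calcification: min_hu must be < max_hu")
  mask <- volume$data >= min_hu & volume$data <= max_hu
  structure(list(mask = mask, min_hu = as.numeric(min_hu),
                 max_hu = as.numeric(max_hu), spacing = volume$spacing),
            class = "calc_mask")
}

#' @export
print.calc_mask <- function(x, ...) {
  cat(sprintf("<calc_mask> band [%g, %g] HU, %d of %d voxels masked\n",
              x$min_hu, x$max_hu, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Write a calcification mask as a 0/1 NIfTI volume
#' @param mask a [detect_calcification()] result.
#' @param path output NIfTI path.
#' @export
write_calc_mask <- function(mask, path) {
  check_that(inherits(mask, "calc_mask"), "write_calc_mask: not a calc_mask")
  write_ct_volume(ct_volume(array(as.double(mask$mask), dim(mask$mask)),
                            mask$spacing), path)
}

# Indices and centre coordinates of masked voxels that lie in the wall
# band of the scored segment. Shared between wall coverage and Agatston
# scoring; `slab_halfwidth = Inf` disables the midline restriction and
# `wall = NULL` keeps both walls.
wall_band_voxels <- function(mask, geom, wall = NULL, slab_halfwidth = Inf) {
  d <- dim(mask$mask)
  sp <- mask$spacing
  check_that(geom$z_ima >= 0 && geom$z_bif <= d[3] * sp[3],
             "wall coverage: geometry z range lies outside the volume")
  idx <- which(mask$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(idx[, , drop = FALSE])
  cx <- (idx[, 1] - 0.5) * sp[1]
  cy <- (idx[, 2] - 0.5) * sp[2]
  cz <- (idx[, 3] - 0.5) * sp[3]
  keep <- cz >= geom$z_ima & cz <= geom$z_bif
  idx <- idx[keep, , drop = FALSE]
  cx <- cx[keep]; cy <- cy[keep]; cz <- cz[keep]
  if (nrow(idx) == 0L) return(idx)
  cl <- centerline_at(geom, cz)
  dxo <- cx - cl$x; dyo <- cy - cl$y
  r <- sqrt(dxo^2 + dyo^2)
  tol <- max(sp[1], sp[2])  # one maximal in-plane spacing
  keep <- abs(dxo) <= slab_halfwidth &
    r >= geom$lumen_radius - tol &
    r <= geom$lumen_radius + geom$wall_thickness + tol
  if (!is.null(wall)) {
    keep <- keep & if (wall == "anterior") dyo > 0 else dyo <= 0
  }
  idx[keep, , drop = FALSE]
}

#' Per-wall calcified coverage of the scored segment
#'
#' Measures the calcified fraction of the longitudinal length of one
#' aortic wall: the quantity the severity rubric discretises. A masked
#' voxel contributes if its centre lies (a) within \code{[z_ima, z_bif]},
#' (b) within \code{slab_halfwidth} of the centreline along x (mirroring
#' the 20 mm midline MIP slab used for visual reading), (c) radially
#' within the wall band \code{[lumen_radius - tol, lumen_radius +
#' wall_thickness + tol]} with tol one maximal in-plane spacing, and
#' (d) on the requested wall (anterior: y above the centreline). Each
#' contributing voxel covers its half-open z extent; the extents are
#' unioned, clipped to the segment, and divided by the segment length.
#'
#' @param mask a [detect_calcification()] result.
#' @param geom an [aorta_geometry()].
#' @param wall \code{"anterior"} or \code{"posterior"}.
#' @param slab_halfwidth lateral half-width of the midline slab in mm
#'   (default 10, i.e. a 20 mm slab).
#' @return an object of class \code{wall_coverage}: the wall, the
#'   disjoint covered intervals (mm) and the fraction in [0, 1].
#' @export
wall_coverage <- function(mask, geom, wall, slab_halfwidth = 10) {
  check_that(inherits(mask, "calc_mask"), "wall_coverage: not a calc_mask")
  check_that(inherits(geom, "aorta_geometry"), "wall_coverage: not an aorta_geometry")
  check_that(wall %in% c("anterior", "posterior"),
             "wall_coverage: wall must be 'anterior' or 'posterior'")
  dz <- mask$spacing[3]
  idx <- wall_band_voxels(mask, geom, wall = wall, slab_halfwidth = slab_halfwidth)
  if (nrow(idx) == 0L) {
    ivs <- merge_intervals(numeric(0), numeric(0))
  } else {
    k <- sort(unique(idx[, 3]))
    ivs <- clip_intervals(merge_intervals((k - 1) * dz, k * dz),
                          geom$z_ima, geom$z_bif)
  }
  frac <- interval_union_length(ivs) / (geom$z_bif - geom$z_ima)
  structure(list(wall = wall, intervals = ivs,
                 fraction = min(max(frac, 0), 1)),
            class = "wall_coverage")
}

#' @export
print.wall_coverage <- function(x, ...) {
  cat(sprintf("<wall_coverage> %s wall: fraction %.4f over %d interval(s)\n",
              x$wall, x$fraction, nrow(x$intervals)))
  invisible(x)
}

#' Write wall coverage (both walls) as JSON
#' @param coverages list with elements \code{anterior} and
#'   \code{posterior}, each a [wall_coverage()].
#' @param path JSON file path.
#' @export
write_coverage <- function(coverages, path) {
  to_obj <- function(cv) {
    list(wall = cv$wall,
         intervals = unname(apply(cv$intervals, 1, as.list, simplify = FALSE)),
         fraction = cv$fraction)
  }
  jsonlite::write_json(lapply(coverages, to_obj), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
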
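#' Aorta segment geometry
#'
#' Describes the scored aortic segment in the volume's millimetre frame:
#' centreline samples (x, y) as a function of z, the lumen radius, wall
#' thickness, and the two longitudinal landmarks bounding the segment —
#' the origin of the inferior mesenteric artery (IMA) above and the
#' bifurcation into the common iliac arteries below. Geometry is always
#' supplied (from phantom generation or a JSON file); the package does no
#' anatomical landmark detection.
#'
#' @param centerline data.frame with numeric columns \code{z}, \code{x},
#'   \code{y} (mm), sorted by z, covering at least \code{[z_ima, z_bif]}.
#' @param lumen_radius lumen radius in mm.
#' @param wall_thickness wall thickness in mm.
#' @param z_ima,z_bif longitudinal landmarks in mm, \code{z_ima < z_bif}.
#' @return an object of class \code{aorta_geometry}.
#' @export
aorta_geometry <- function(centerline, lumen_radius, wall_thickness, z_ima, z_bif) {
  check_that(is.data.frame(centerline) && all(c("z", "x", "y") %in% names(centerline)),
             "aorta_geometry: centerline needs columns z, x, y")
  check_that(nrow(centerline) >= 2L, "aorta_geometry: need >= 2 centerline samples")
  check_that(!is.unsorted(centerline$z, strictly = TRUE),
             "aorta_geometry: centerline z must be strictly increasing")
  check_that(is.numeric(z_ima) && is.numeric(z_bif) && z_ima < z_bif,
             "aorta_geometry: z_ima must be < z_bif")
  check_that(min(centerline$z) <= z_ima && max(centerline$z) >= z_bif,
             "aorta_geometry: centerline must cover [z_ima, z_bif]")
  check_that(lumen_radius > 0, "aorta_geometry: lumen_radius must be > 0")
  check_that(wall_thickness > 0, "aorta_geometry: wall_thickness must be > 0")
  structure(list(centerline = centerline[, c("z", "x", "y")],
                 lumen_radius = as.numeric(lumen_radius),
                 wall_thickness = as.numeric(wall_thickness),
                 z_ima = as.numeric(z_ima), z_bif = as.numeric(z_bif)),
            class = "aorta_geometry")
}

#' @export
print.aorta_geometry <- function(x, ...) {
  cat(sprintf("<aorta_geometry> segment z = [%.1f, %.1f] mm (length %.1f mm)\n",
              x$z_ima, x$z_bif, x$z_bif - x$z_ima))
  cat(sprintf("  lumen radius %.1f mm, wall thickness %.1f mm, %d centerline samples\n",
              x$lumen_radius, x$wall_thickness, nrow(x$centerline)))
  invisible(x)
}

# Linear interpolation of the centerline at arbitrary z (clamped outside
# the sampled range).
centerline_at <- function(geom, z) {
  cl <- geom$centerline
  list(x = stats::approx(cl$z, cl$x, xout = z, rule = 2)$y,
       y = stats::approx(cl$z, cl$y, xout = z, rule = 2)$y)
}

#' Write / read aorta geometry as JSON
#' @param geom an [aorta_geometry()].
#' @param path JSON file path.
#' @return \code{read_geometry} returns an [aorta_geometry()];
#'   \code{write_geometry} returns \code{path} invisibly.
#' @export
write_geometry <- function(geom, path) {
  check_that(inherits(geom, "aorta_geometry"), "write_geometry: not an aorta_geometry")
  obj <- list(centerline = geom$centerline,
              lumen_radius = geom$lumen_radius,
              wall_thickness = geom$wall_thickness,
              z_ima = geom$z_ima, z_bif = geom$z_bif)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  check_that(file.exists(path), paste0("read_geometry: no such file: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("centerline", "lumen_radius", "wall_thickness", "z_ima", "z_bif")
  missing <- setdiff(required, names(obj))
  check_that(length(missing) == 0,
             paste0("read_geometry: missing key(s): ", paste(missing, collapse = ", ")))
  aorta_geometry(as.data.frame(obj$centerline), obj$lumen_radius,
                 obj$wall_thickness, obj$z_ima, obj$z_bif)
}
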
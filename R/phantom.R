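#' Plaque specification for the synthetic phantom
#'
#' A calcified wall plaque is an angular sector of the aortic wall shell,
#' on one wall, spanning a longitudinal interval. The intensity must be at
#' or above the 450 HU calcium detection floor, otherwise the plaque would
#' be invisible to the pipeline it is meant to exercise.
#'
#' @param wall \code{"anterior"} or \code{"posterior"}.
#' @param z_interval numeric length-2, longitudinal extent in mm
#'   (half-open \code{[start, end)}), inside the scored segment.
#' @param angular_halfwidth half-width in degrees of the sector around the
#'   wall's cardinal direction (anterior = +y, posterior = -y); in
#'   (0, 90].
#' @param intensity plaque HU (default 700, >= 450).
#' @return an object of class \code{plaque_spec}.
#' @export
plaque_spec <- function(wall, z_interval, angular_halfwidth = 45, intensity = 700) {
  check_that(wall %in% c("anterior", "posterior"),
             "plaque_spec: wall must be 'anterior' or 'posterior'")
  z_interval <- as.numeric(z_interval)
  check_that(length(z_interval) == 2L && z_interval[1] < z_interval[2],
             "plaque_spec: z_interval must satisfy start < end")
  check_that(angular_halfwidth > 0 && angular_halfwidth <= 90,
             "plaque_spec: angular_halfwidth must be in (0, 90]")
  check_that(intensity >= 450,
             "plaque_spec: intensity must be >= 450 HU (the detection floor)")
  structure(list(wall = wall, z_interval = z_interval,
                 angular_halfwidth = as.numeric(angular_halfwidth),
                 intensity = as.numeric(intensity)),
            class = "plaque_spec")
}

#' Phantom specification
#'
#' Defines a synthetic contrast-enhanced lower abdominal aorta: a straight
#' (optionally bowed) tube of contrast-opacified lumen at ~300 HU inside a
#' soft-tissue wall shell, embedded in a uniform soft-tissue background,
#' with calcified plaques in the wall and additive Gaussian HU noise. The
#' lumen default of 300 HU is deliberately below the 450 HU detection
#' floor so contrast never masquerades as calcium.
#'
#' @param shape integer length-3, voxels per axis (x, y, z).
#' @param spacing numeric length-3, mm per voxel.
#' @param z_ima,z_bif segment landmarks in mm, \code{z_ima < z_bif}.
#' @param plaques list of [plaque_spec()] objects.
#' @param lumen_hu,wall_hu,background_hu tissue intensities (HU).
#' @param noise_sigma Gaussian noise standard deviation (HU).
#' @param lumen_radius,wall_thickness tube geometry (mm).
#' @param bow_amplitude amplitude (mm) of an optional sinusoidal lateral
#'   bow of the centreline along x; 0 (the default) gives a straight
#'   tube. Intended for robustness tests only.
#' @param seed integer seed for the noise field.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(64, 64, 80), spacing = c(1.5, 1.5, 1),
                         z_ima = 10, z_bif = 70, plaques = list(),
                         lumen_hu = 300, wall_hu = 50, background_hu = 40,
                         noise_sigma = 10, lumen_radius = 9, wall_thickness = 2,
                         bow_amplitude = 0, seed = 1L) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  check_that(length(shape) == 3L && all(shape > 0), "phantom_spec: shape must be 3 positive integers")
  check_that(length(spacing) == 3L && all(spacing > 0), "phantom_spec: spacing must be 3 positive numbers")
  check_that(z_ima < z_bif, "phantom_spec: z_ima must be < z_bif")
  check_that(z_ima >= 0 && z_bif <= shape[3] * spacing[3],
             "phantom_spec: segment [z_ima, z_bif] must lie inside the volume")
  check_that(lumen_hu < 450, "phantom_spec: lumen_hu must be < 450 HU (the detection floor)")
  check_that(noise_sigma >= 0, "phantom_spec: noise_sigma must be >= 0")
  check_that(lumen_radius > 0 && wall_thickness > 0,
             "phantom_spec: lumen_radius and wall_thickness must be > 0")
  for (p in plaques) {
    check_that(inherits(p, "plaque_spec"), "phantom_spec: plaques must be plaque_spec objects")
    check_that(p$z_interval[1] >= z_ima && p$z_interval[2] <= z_bif,
               "phantom_spec: plaque z_interval must lie inside [z_ima, z_bif]")
  }
  structure(list(shape = shape, spacing = spacing, z_ima = as.numeric(z_ima),
                 z_bif = as.numeric(z_bif), plaques = plaques,
                 lumen_hu = as.numeric(lumen_hu), wall_hu = as.numeric(wall_hu),
                 background_hu = as.numeric(background_hu),
                 noise_sigma = as.numeric(noise_sigma),
                 lumen_radius = as.numeric(lumen_radius),
                 wall_thickness = as.numeric(wall_thickness),
                 bow_amplitude = as.numeric(bow_amplitude),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Ground truth for a phantom
#'
#' Per-wall union of the plaque longitudinal intervals, the analytic
#' calcified fraction (union length over segment length), the rubric
#' sub-scores and total, and the rasterised plaque voxel count.
#' @keywords internal
make_ground_truth <- function(spec, plaque_voxels) {
  L <- spec$z_bif - spec$z_ima
  per_wall <- function(wall) {
    ps <- Filter(function(p) p$wall == wall, spec$plaques)
    ivs <- merge_intervals(vapply(ps, function(p) p$z_interval[1], numeric(1)),
                           vapply(ps, function(p) p$z_interval[2], numeric(1)))
    frac <- interval_union_length(ivs) / L
    list(intervals = ivs, fraction = frac, score = wall_subscore(frac))
  }
  ant <- per_wall("anterior"); post <- per_wall("posterior")
  structure(list(anterior_intervals = ant$intervals,
                 posterior_intervals = post$intervals,
                 anterior_fraction = ant$fraction,
                 posterior_fraction = post$fraction,
                 anterior_score = ant$score, posterior_score = post$score,
                 total_score = ant$score + post$score,
                 plaque_voxels = as.integer(plaque_voxels)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> anterior %.4f (score %d), posterior %.4f (score %d), total %d\n",
              x$anterior_fraction, x$anterior_score,
              x$posterior_fraction, x$posterior_score, x$total_score))
  invisible(x)
}

#' Generate a synthetic aorta phantom
#'
#' Rasterises the tube, wall shell and plaques onto the voxel grid (a
#' voxel belongs to a structure if its centre does), then adds Gaussian
#' noise drawn from the spec's seed. Ground-truth fractions are computed
#' analytically from the plaque intervals, never from voxels, so they can
#' serve as an independent reference for the measurement pipeline.
#' Identical specs (including the seed) produce bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements \code{volume} ([ct_volume()]),
#'   \code{geometry} ([aorta_geometry()]) and \code{truth}
#'   (ground truth, see [make_ground_truth()]).
#' @export
generate_phantom <- function(spec) {
  check_that(inherits(spec, "phantom_spec"), "generate_phantom: not a phantom_spec")
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  dx <- spec$spacing[1]; dy <- spec$spacing[2]; dz <- spec$spacing[3]
  xs <- voxel_centers(nx, dx); ys <- voxel_centers(ny, dy); zs <- voxel_centers(nz, dz)
  cx0 <- nx * dx / 2; cy0 <- ny * dy / 2
  zspan <- nz * dz
  cxz <- cx0 + spec$bow_amplitude * sin(pi * zs / zspan)  # centreline x per z

  # Per-voxel offsets from the centreline, as nx*ny*nz arrays.
  dxo <- outer(xs, cxz, "-")                                    # nx x nz
  dxa <- aperm(array(dxo, c(nx, nz, ny)), c(1, 3, 2))           # nx x ny x nz
  dya <- array(rep(ys - cy0, each = nx), c(nx, ny, nz))
  r2 <- dxa^2 + dya^2

  R <- spec$lumen_radius; W <- spec$wall_thickness
  vol <- array(spec$background_hu, c(nx, ny, nz))
  in_wall <- r2 > R^2 & r2 <= (R + W)^2
  vol[in_wall] <- spec$wall_hu
  vol[r2 <= R^2] <- spec$lumen_hu

  zin_seg <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
  plaque_union <- array(FALSE, c(nx, ny, nz))
  for (p in spec$plaques) {
    sgn <- if (p$wall == "anterior") 1 else -1
    # angular offset from the wall's cardinal direction (+/- y)
    r <- sqrt(r2)
    cosang <- sgn * dya / pmax(r, .Machine$double.eps)
    ang_ok <- cosang >= cos(p$angular_halfwidth * pi / 180)
    zin <- zin_seg >= p$z_interval[1] & zin_seg < p$z_interval[2]
    m <- in_wall & ang_ok & zin
    vol[m] <- p$intensity
    plaque_union <- plaque_union | m
  }

  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed,
                       stats::rnorm(length(vol), 0, spec$noise_sigma))
    vol <- vol + array(noise, dim(vol))
  }

  cl <- data.frame(z = zs, x = cxz, y = cy0)
  geom <- aorta_geometry(cl, lumen_radius = R, wall_thickness = W,
                         z_ima = spec$z_ima, z_bif = spec$z_bif)
  list(volume = ct_volume(vol, spec$spacing),
       geometry = geom,
       truth = make_ground_truth(spec, sum(plaque_union)))
}

#' Write / read phantom ground truth as JSON
#'
#' The round trip is lossless: numbers are serialised at full precision.
#'
#' @param gt a ground truth object from [generate_phantom()].
#' @param path JSON file path.
#' @return \code{read_ground_truth} returns the ground truth object;
#'   \code{write_ground_truth} returns \code{path} invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  check_that(inherits(gt, "ground_truth"), "write_ground_truth: not a ground_truth")
  iv_list <- function(m) unname(apply(m, 1, function(r) as.list(r), simplify = FALSE))
  obj <- list(anterior_intervals = iv_list(gt$anterior_intervals),
              posterior_intervals = iv_list(gt$posterior_intervals),
              anterior_fraction = gt$anterior_fraction,
              posterior_fraction = gt$posterior_fraction,
              anterior_score = gt$anterior_score,
              posterior_score = gt$posterior_score,
              total_score = gt$total_score,
              plaque_voxels = gt$plaque_voxels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  check_that(file.exists(path), paste0("read_ground_truth: no such file: ", path))
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("read_ground_truth: malformed JSON: ",
                                           conditionMessage(e), call. = FALSE))
  required <- c("anterior_intervals", "posterior_intervals",
                "anterior_fraction", "posterior_fraction",
                "anterior_score", "posterior_score", "total_score", "plaque_voxels")
  for (key in required) {
    if (is.null(obj[[key]])) {
      stop("read_ground_truth: missing required key: ", key, call. = FALSE)
    }
  }
  iv_mat <- function(lst) {
    if (length(lst) == 0L) {
      return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
    }
    m <- do.call(rbind, lapply(lst, function(r) as.numeric(unlist(r))))
    dimnames(m) <- list(NULL, c("start", "end"))
    m
  }
  structure(list(anterior_intervals = iv_mat(obj$anterior_intervals),
                 posterior_intervals = iv_mat(obj$posterior_intervals),
                 anterior_fraction = as.numeric(obj$anterior_fraction),
                 posterior_fraction = as.numeric(obj$posterior_fraction),
                 anterior_score = as.integer(obj$anterior_score),
                 posterior_score = as.integer(obj$posterior_score),
                 total_score = as.integer(obj$total_score),
                 plaque_voxels = as.integer(obj$plaque_voxels)),
            class = "ground_truth")
}

#' Sample a random phantom specification
#'
#' The default study-condition sampler: per wall it draws a target
#' calcified fraction either exactly 0 (probability 0.2) or uniformly
#' from the rubric-safe regions at least 0.05 away from the 1/3 and 2/3
#' score boundaries (and at least 0.05 above 0), splits the target length
#' over one or two disjoint plaques, and snaps all plaque intervals to
#' the voxel grid so the analytic fraction is exactly recoverable from a
#' noise-free rasterisation. Plaque intensities are drawn in
#' [600, 900] HU and angular half-widths in [30, 60] degrees. Noise sigma
#' stays at the spec default of 10 HU.
#'
#' @param seed integer seed; the whole spec is a deterministic function
#'   of it.
#' @param ... further arguments passed to [phantom_spec()] (e.g. shape).
#' @return a [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, ...) {
  base <- phantom_spec(seed = as.integer(seed), ...)
  dz <- base$spacing[3]
  L <- base$z_bif - base$z_ima
  nbins <- floor(L / dz + 1e-9)
  # Safe fraction regions, shrunk so grid-snapping (<= dz/2 shift) cannot
  # bring a fraction within 0.05 of a rubric boundary.
  eps <- 0.05 + 0.6 * dz / L
  regions <- rbind(c(eps, 1 / 3 - eps), c(1 / 3 + eps, 2 / 3 - eps),
                   c(2 / 3 + eps, 0.95))
  spec <- with_seed(seed, {
    plaques <- list()
    for (wall in c("anterior", "posterior")) {
      if (stats::runif(1) < 0.2) next  # disease-free wall
      widths <- regions[, 2] - regions[, 1]
      reg <- sample.int(nrow(regions), 1, prob = widths)
      target <- stats::runif(1, regions[reg, 1], regions[reg, 2])
      lbins <- max(1L, round(target * nbins))
      two <- lbins >= 4L && stats::runif(1) < 0.5 && lbins + 1L < nbins
      if (two) {
        l1 <- lbins %/% 2L; l2 <- lbins - l1
        s1 <- sample.int(nbins - l1 - l2 - 1L, 1) - 1L
        s2_opts <- seq.int(s1 + l1 + 1L, nbins - l2)
        s2 <- s2_opts[sample.int(length(s2_opts), 1)]
        pieces <- list(c(s1, s1 + l1), c(s2, s2 + l2))
      } else {
        s1 <- sample.int(nbins - lbins + 1L, 1) - 1L
        pieces <- list(c(s1, s1 + lbins))
      }
      for (pc in pieces) {
        plaques[[length(plaques) + 1L]] <- plaque_spec(
          wall = wall,
          z_interval = base$z_ima + pc * dz,
          angular_halfwidth = stats::runif(1, 30, 60),
          intensity = stats::runif(1, 600, 900))
      }
    }
    phantom_spec(shape = base$shape, spacing = base$spacing,
                 z_ima = base$z_ima, z_bif = base$z_bif, plaques = plaques,
                 lumen_hu = base$lumen_hu, wall_hu = base$wall_hu,
                 background_hu = base$background_hu,
                 noise_sigma = base$noise_sigma,
                 lumen_radius = base$lumen_radius,
                 wall_thickness = base$wall_thickness,
                 bow_amplitude = base$bow_amplitude, seed = base$seed)
  })
  spec
}

#' Write / read a phantom spec as JSON
#' @param spec a [phantom_spec()].
#' @param path JSON file path.
#' @return \code{read_phantom_spec} returns a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  check_that(inherits(spec, "phantom_spec"), "write_phantom_spec: not a phantom_spec")
  obj <- unclass(spec)
  obj$plaques <- lapply(spec$plaques, unclass)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  check_that(file.exists(path), paste0("read_phantom_spec: no such file: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  plaques <- list()
  if (!is.null(obj$plaques) && length(obj$plaques)) {
    pl <- obj$plaques
    if (is.data.frame(pl)) pl <- split(pl, seq_len(nrow(pl)))
    plaques <- lapply(pl, function(p)
      plaque_spec(p$wall, unlist(p$z_interval), p$angular_halfwidth, p$intensity))
    names(plaques) <- NULL
  }
  args <- obj[setdiff(names(obj), "plaques")]
  args$plaques <- plaques
  do.call(phantom_spec, args)
}
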
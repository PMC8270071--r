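#' Pipeline run configuration
#'
#' Collects every tunable constant of the pipeline, defaulting to the
#' published protocol values: calcium detection band 450-3070 HU, bone
#' window 2500/200 HU, 20 mm midline sagittal slab.
#'
#' @param min_hu,max_hu calcium detection band (HU).
#' @param window_width,window_level display window (HU).
#' @param slab_thickness MIP slab thickness (mm); the coverage
#'   half-width is derived as half of it unless given explicitly.
#' @param slab_halfwidth lateral half-width for wall coverage (mm).
#' @param min_detectable_fraction rubric floor, see [wall_subscore()].
#' @param min_area_mm2 Agatston minimum lesion area (mm^2).
#' @param icc_model default ICC model for agreement statistics.
#' @param seed integer seed governing all randomness in a run.
#' @param out_dir output directory for batch runs.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(min_hu = 450, max_hu = 3070,
                       window_width = 2500, window_level = 200,
                       slab_thickness = 20, slab_halfwidth = slab_thickness / 2,
                       min_detectable_fraction = 0, min_area_mm2 = 1,
                       icc_model = "two_way_random_absolute_single",
                       seed = 1L, out_dir = ".") {
  check_that(is.numeric(min_hu) && is.numeric(max_hu) && min_hu < max_hu,
             "run_config: min_hu must be < max_hu (fields min_hu, max_hu)")
  check_that(window_width > 0, "run_config: window_width must be > 0")
  check_that(slab_thickness > 0, "run_config: slab_thickness must be > 0")
  check_that(slab_halfwidth > 0, "run_config: slab_halfwidth must be > 0")
  check_that(min_detectable_fraction >= 0 && min_detectable_fraction < 1,
             "run_config: min_detectable_fraction must lie in [0, 1)")
  check_that(min_area_mm2 >= 0, "run_config: min_area_mm2 must be >= 0")
  check_that(icc_model %in% c("two_way_random_absolute_single",
                              "two_way_random_absolute_average",
                              "two_way_consistency_single"),
             "run_config: unknown icc_model")
  structure(list(min_hu = as.numeric(min_hu), max_hu = as.numeric(max_hu),
                 window_width = as.numeric(window_width),
                 window_level = as.numeric(window_level),
                 slab_thickness = as.numeric(slab_thickness),
                 slab_halfwidth = as.numeric(slab_halfwidth),
                 min_detectable_fraction = as.numeric(min_detectable_fraction),
                 min_area_mm2 = as.numeric(min_area_mm2),
                 icc_model = icc_model, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Load / save a run configuration
#'
#' YAML or JSON; unspecified fields take the protocol defaults, unknown
#' keys are an error (no silent ignore).
#'
#' @param path config file (\code{.yaml}, \code{.yml} or \code{.json}).
#' @param config a [run_config()].
#' @return \code{load_config} returns a [run_config()].
#' @export
load_config <- function(path) {
  check_that(file.exists(path), paste0("load_config: no such file: ", path))
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(obj)) obj <- list()  # empty file: all defaults
  known <- names(formals(run_config))
  unknown <- setdiff(names(obj), known)
  check_that(length(unknown) == 0,
             paste0("load_config: unknown key(s): ", paste(unknown, collapse = ", ")))
  do.call(run_config, obj)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  check_that(inherits(config, "run_config"), "save_config: not a run_config")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(unclass(config), path)
  }
  invisible(path)
}
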
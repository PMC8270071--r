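#' Run the scoring pipeline over a batch of patients
#'
#' For each patient: load the volume and geometry, detect calcification,
#' measure the two wall coverage fractions, apply the severity rubric and
#' compute the Agatston-style calcium score. Per-patient failures are
#' caught, logged and reported in the \code{error} column; the batch
#' continues. Output is deterministic given the inputs and config, and
#' the CSV is written with a fixed dialect (comma-separated, UTF-8,
#' header row, integer scores, fractions with six decimals) so reruns
#' are byte-identical.
#'
#' @param volume_paths character vector of NIfTI volume paths.
#' @param geometry_paths character vector of geometry JSON paths, same
#'   length.
#' @param patient_ids optional ids (defaults to volume file stems).
#' @param config a [run_config()].
#' @param csv_path,json_path optional output paths; when NULL, derived
#'   from \code{config$out_dir} as \code{scores.csv} / \code{report.json}.
#' @param log_file optional path receiving the structured log.
#' @return invisibly, the per-patient results data.frame: patient_id,
#'   anterior, posterior, total, anterior_fraction, posterior_fraction,
#'   agatston, volume_score, lesion_count, error.
#' @export
run_pipeline <- function(volume_paths, geometry_paths, patient_ids = NULL,
                         config = run_config(), csv_path = NULL,
                         json_path = NULL, log_file = NULL) {
  check_that(length(volume_paths) == length(geometry_paths),
             "run_pipeline: volume and geometry path lists must have equal length")
  n <- length(volume_paths)
  patient_ids <- patient_ids %||% sub("\\.nii(\\.gz)?$", "", basename(volume_paths))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- patient_ids[i]
    rows[[i]] <- tryCatch({
      aac_log("INFO", "scoring patient ", id, file = log_file)
      vol <- read_ct_volume(volume_paths[i])
      geom <- read_geometry(geometry_paths[i])
      mask <- detect_calcification(vol, config$min_hu, config$max_hu)
      ant <- wall_coverage(mask, geom, "anterior", config$slab_halfwidth)
      post <- wall_coverage(mask, geom, "posterior", config$slab_halfwidth)
      sc <- total_score(ant$fraction, post$fraction,
                        config$min_detectable_fraction)
      ag <- agatston_score(vol, mask, geom, config$min_area_mm2)
      data.frame(patient_id = id, anterior = sc$anterior,
                 posterior = sc$posterior, total = sc$total,
                 anterior_fraction = ant$fraction,
                 posterior_fraction = post$fraction,
                 agatston = ag$agatston, volume_score = ag$volume_score,
                 lesion_count = ag$lesion_count, error = "")
    }, error = function(e) {
      aac_log("ERROR", "patient ", id, " failed: ", conditionMessage(e),
              file = log_file)
      data.frame(patient_id = id, anterior = NA_integer_,
                 posterior = NA_integer_, total = NA_integer_,
                 anterior_fraction = NA_real_, posterior_fraction = NA_real_,
                 agatston = NA_real_, volume_score = NA_real_,
                 lesion_count = NA_integer_, error = conditionMessage(e))
    })
  }
  res <- do.call(rbind, rows)
  if (is.null(csv_path)) csv_path <- file.path(config$out_dir, "scores.csv")
  if (is.null(json_path)) json_path <- file.path(config$out_dir, "report.json")
  write_score_csv(res, csv_path)
  jsonlite::write_json(list(config = unclass(config), results = res),
                       json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(res)
}

# Fixed-dialect CSV: integer scores, six-decimal fractions.
write_score_csv <- function(res, path) {
  out <- res
  for (col in c("anterior_fraction", "posterior_fraction")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", sprintf("%.6f", out[[col]]))
  }
  for (col in c("agatston", "volume_score")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", sprintf("%.6f", out[[col]]))
  }
  con <- file(path, open = "wb")  # binary mode: LF line endings everywhere
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
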
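#' Wall sub-score from a calcified fraction
#'
#' The per-wall severity rubric: 0 if no calcification at all (fraction
#' exactly zero); 1 if less than one-third of the longitudinal length is
#' calcified; 2 if between one-third and two-thirds (inclusive at both
#' boundaries); 3 if more than two-thirds. The optional
#' \code{min_detectable_fraction} treats tiny fractions (at or below the
#' floor) as no disease — a robustness knob for noisy real data, off
#' (zero) by default.
#'
#' @param fraction calcified fraction in [0, 1]; vectorised.
#' @param min_detectable_fraction fractions at or below this count as 0
#'   (default 0, i.e. any nonzero fraction scores at least 1).
#' @return integer sub-score(s) in 0..3.
#' @export
wall_subscore <- function(fraction, min_detectable_fraction = 0) {
  check_that(is.numeric(fraction) && all(is.finite(fraction)),
             "wall_subscore: fraction must be finite numeric")
  check_that(all(fraction >= 0 & fraction <= 1),
             "wall_subscore: fraction must lie in [0, 1]")
  score <- integer(length(fraction))
  f <- fraction
  f[f <= min_detectable_fraction] <- 0
  score[f > 0] <- 1L
  score[f >= 1 / 3] <- 2L
  score[f > 2 / 3] <- 3L
  score
}

#' Total disease severity score from the two wall fractions
#'
#' Applies the wall rubric to the anterior and posterior calcified
#' fractions and sums the sub-scores into the 0-6 disease severity
#' score; 6 indicates severe disease on both walls.
#'
#' @param anterior_fraction,posterior_fraction calcified fractions in
#'   [0, 1].
#' @param min_detectable_fraction passed to [wall_subscore()].
#' @return an object of class \code{atheroma_score} with integer fields
#'   \code{anterior} (0-3), \code{posterior} (0-3) and \code{total}
#'   (0-6).
#' @export
total_score <- function(anterior_fraction, posterior_fraction,
                        min_detectable_fraction = 0) {
  a <- wall_subscore(anterior_fraction, min_detectable_fraction)
  p <- wall_subscore(posterior_fraction, min_detectable_fraction)
  structure(list(anterior = a, posterior = p, total = a + p),
            class = "atheroma_score")
}

#' @export
print.atheroma_score <- function(x, ...) {
  cat(sprintf("<atheroma_score> anterior %d + posterior %d = total %d (of 6)\n",
              x$anterior, x$posterior, x$total))
  invisible(x)
}

#' Score a CT volume end to end
#'
#' Pipeline composition: detect calcification in the HU band, measure the
#' anterior and posterior wall coverage fractions over the scored
#' segment, and apply the rubric.
#'
#' @param volume a [ct_volume()].
#' @param geom an [aorta_geometry()].
#' @param config a [run_config()]; controls the detection band, slab
#'   half-width and rubric floor.
#' @return an \code{atheroma_score} with the two measured fractions
#'   attached as \code{anterior_fraction} / \code{posterior_fraction}.
#' @export
score_volume <- function(volume, geom, config = run_config()) {
  mask <- detect_calcification(volume, config$min_hu, config$max_hu)
  ant <- wall_coverage(mask, geom, "anterior", config$slab_halfwidth)
  post <- wall_coverage(mask, geom, "posterior", config$slab_halfwidth)
  sc <- total_score(ant$fraction, post$fraction, config$min_detectable_fraction)
  sc$anterior_fraction <- ant$fraction
  sc$posterior_fraction <- post$fraction
  sc
}
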
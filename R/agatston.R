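# Connected-component labelling of integer grid coordinates.
# `coords`: n x d matrix of voxel indices; two cells are connected when
# every coordinate differs by at most 1 (8-connectivity in 2-D,
# 26-connectivity in 3-D). Returns an integer membership vector.
label_components <- function(coords) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  d <- ncol(coords)
  dims <- apply(coords, 2, max) + 1L
  key <- as.numeric(coords[, 1])
  mult <- 1
  for (ax in seq_len(d)[-1]) {
    mult <- mult * dims[ax - 1]
    key <- key + as.numeric(coords[, ax]) * mult
  }
  offs <- as.matrix(expand.grid(rep(list(-1:1), d)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nk <- key
    mult <- 1
    for (ax in seq_len(d)) {
      if (ax > 1) mult <- mult * dims[ax - 1]
      nk <- nk + offs[r, ax] * mult
    }
    hit <- match(nk, key)
    ok <- which(!is.na(hit))
    if (length(ok)) edges <- rbind(edges, cbind(ok, hit[ok]))
  }
  g <- igraph::graph_from_edgelist(if (is.null(edges)) matrix(integer(0), ncol = 2) else edges,
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

#' Agatston-style calcium score over the aortic segment
#'
#' Reference calcium burden score over the same IMA-to-bifurcation
#' segment that the severity rubric grades, for correlating the two
#' measures. Per axial slice, 8-connected lesions of the detection mask
#' (restricted to the aortic wall band, both walls, no midline slab
#' restriction) are weighted by peak density — weight 1, 2, 3 or 4 for
#' peak HU in [130, 200), [200, 300), [300, 400) and >= 400 — and
#' contribute lesion area (mm^2) times the weight; slice contributions
#' are scaled by slice spacing / 3 mm so non-3 mm acquisitions remain
#' comparable, then summed. Lesions below \code{min_area_mm2} are
#' discarded. Unlike workstation implementations that can bleed into
#' confluent calcification beyond the landmarks, scoring here is clipped
#' strictly to \code{[z_ima, z_bif]}.
#'
#' With the 450 HU detection floor every retained lesion necessarily has
#' weight 4; this is asserted.
#'
#' @param volume a [ct_volume()] (source of peak HU values).
#' @param mask a [detect_calcification()] result on the same volume.
#' @param geom an [aorta_geometry()].
#' @param min_area_mm2 minimum lesion area per slice in mm^2 (default 1).
#' @return an object of class \code{calcium_score_result}:
#'   \code{agatston} (unitless), \code{volume_score} (mm^3 of retained
#'   plaque) and \code{lesion_count} (3-D 26-connected lesions).
#' @export
agatston_score <- function(volume, mask, geom, min_area_mm2 = 1.0) {
  check_that(inherits(volume, "ct_volume"), "agatston_score: not a ct_volume")
  check_that(inherits(mask, "calc_mask"), "agatston_score: not a calc_mask")
  check_that(identical(dim(volume$data), dim(mask$mask)),
             "agatston_score: volume and mask dimensions differ")
  sp <- volume$spacing
  check_that(all(is.finite(sp)) && all(sp > 0), "agatston_score: spacing missing or invalid")
  idx <- wall_band_voxels(mask, geom, wall = NULL, slab_halfwidth = Inf)
  if (nrow(idx) == 0L) {
    return(structure(list(agatston = 0, volume_score = 0, lesion_count = 0L),
                     class = "calcium_score_result"))
  }
  area_vox <- sp[1] * sp[2]
  agatston <- 0
  retained <- NULL
  for (k in sort(unique(idx[, 3]))) {
    sl <- idx[idx[, 3] == k, 1:2, drop = FALSE]
    memb <- label_components(sl)
    slice_sum <- 0
    for (comp in unique(memb)) {
      vox <- sl[memb == comp, , drop = FALSE]
      area <- nrow(vox) * area_vox
      if (area < min_area_mm2) next
      peak <- max(volume$data[cbind(vox, k)])
      w <- if (peak >= 400) 4 else if (peak >= 300) 3 else if (peak >= 200) 2 else 1
      stopifnot(w == 4L || mask$min_hu < 400)  # 450 HU floor forces weight 4
      slice_sum <- slice_sum + area * w
      retained <- rbind(retained, cbind(vox, k))
    }
    agatston <- agatston + slice_sum * sp[3] / 3
  }
  if (is.null(retained)) {
    return(structure(list(agatston = 0, volume_score = 0, lesion_count = 0L),
                     class = "calcium_score_result"))
  }
  lesion_count <- max(label_components(retained))
  structure(list(agatston = agatston,
                 volume_score = nrow(retained) * area_vox * sp[3],
                 lesion_count = as.integer(lesion_count)),
            class = "calcium_score_result")
}

#' @export
print.calcium_score_result <- function(x, ...) {
  cat(sprintf("<calcium_score_result> Agatston %.1f, volume %.1f mm^3, %d lesion(s)\n",
              x$agatston, x$volume_score, x$lesion_count))
  invisible(x)
}
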
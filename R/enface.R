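#' Segmentation probability volume for one GA feature
#'
#' Container for the raw output of a per-feature OCT segmentation model over
#' one eye: either a raster of per-A-scan probabilities (rows = b-scans,
#' columns = A-scans) or a list of per-b-scan pixel masks (rows = depth,
#' columns = A-scans) that still need column-wise reduction.
#'
#' @param data numeric matrix `n_bscans x n_ascans` of probabilities in
#'   `[0, 1]`, or a list of per-b-scan probability matrices (one per b-scan,
#'   rows = depth pixels, columns = A-scans).
#' @param feature one of `"RPE_LOSS"`, `"PDR"`, `"HT"` (hypertransmission).
#' @param field_mm physical extent of the scanned field in mm, `c(width,
#'   height)`; width spans the A-scan axis, height the b-scan axis.
#' @param laterality `"OD"` (right) or `"OS"` (left).
#' @param fovea_xy_mm annotated foveal centre `c(x, y)` in mm, measured from
#'   the top-left corner of the field (x along A-scans, y along b-scans).
#' @param min_bscans minimum b-scan count accepted; volumes from clinical
#'   acquisitions are expected to carry at least 25 b-scans over the 6 mm
#'   field, but toy volumes may relax this.
#' @return an object of class `seg_volume`.
#' @export
seg_volume <- function(data, feature = c("RPE_LOSS", "PDR", "HT"),
                       field_mm = c(6, 6), laterality = c("OD", "OS"),
                       fovea_xy_mm = NULL, min_bscans = 25) {
  feature <- match.arg(feature)
  laterality <- match.arg(laterality)
  field_mm <- rep_len(as.numeric(field_mm), 2L)
  if (is.list(data)) {
    if (length(data) < min_bscans)
      stop("volume has ", length(data), " b-scans; at least ", min_bscans,
           " required", call. = FALSE)
    nc <- unique(vapply(data, ncol, integer(1)))
    if (length(nc) != 1L)
      stop("per-b-scan masks must share the A-scan count", call. = FALSE)
    rng <- range(vapply(data, range, numeric(2)))
  } else {
    data <- as.matrix(data)
    if (nrow(data) < min_bscans)
      stop("volume has ", nrow(data), " b-scans; at least ", min_bscans,
           " required", call. = FALSE)
    rng <- range(data)
  }
  if (rng[1] < 0 || rng[2] > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(data = data, feature = feature, field_mm = field_mm,
                 laterality = laterality, fovea_xy_mm = fovea_xy_mm),
            class = "seg_volume")
}

#' En-face feature probability map
#'
#' A 2-D per-A-scan probability grid over the macular field, the common
#' currency of the pipeline. Rows follow the b-scan axis (first row is the
#' superior edge of the field), columns the A-scan axis.
#'
#' @param grid numeric matrix of probabilities in `[0, 1]`.
#' @param feature feature name; `"RORA"` is allowed here because RORA maps
#'   are derived at this level (see [derive_rora()]).
#' @inheritParams seg_volume
#' @return an object of class `enface_map` carrying `grid`, `feature`,
#'   `spacing_mm` (per-cell `c(row, col)` spacing), `field_mm`,
#'   `fovea_xy_mm` and `laterality`.
#' @export
enface_map <- function(grid, feature = c("RPE_LOSS", "PDR", "HT", "RORA"),
                       field_mm = c(6, 6), laterality = c("OD", "OS"),
                       fovea_xy_mm = NULL) {
  feature <- match.arg(feature)
  laterality <- match.arg(laterality)
  grid <- as.matrix(grid)
  field_mm <- rep_len(as.numeric(field_mm), 2L)
  if (min(grid) < 0 || max(grid) > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!is.null(fovea_xy_mm)) {
    if (fovea_xy_mm[1] < 0 || fovea_xy_mm[1] > field_mm[1] ||
        fovea_xy_mm[2] < 0 || fovea_xy_mm[2] > field_mm[2])
      stop("fovea annotation lies outside the scanned field", call. = FALSE)
  }
  structure(list(grid = grid, feature = feature,
                 spacing_mm = c(field_mm[2] / nrow(grid),
                                field_mm[1] / ncol(grid)),
                 field_mm = field_mm, fovea_xy_mm = fovea_xy_mm,
                 laterality = laterality),
            class = "enface_map")
}

#' @export
print.enface_map <- function(x, ...) {
  cat(sprintf("<enface_map> %s, %d x %d cells over %.1f x %.1f mm (%s)\n",
              x$feature, nrow(x$grid), ncol(x$grid),
              x$field_mm[1], x$field_mm[2], x$laterality))
  if (!is.null(x$fovea_xy_mm))
    cat(sprintf("  fovea at (%.2f, %.2f) mm\n",
                x$fovea_xy_mm[1], x$fovea_xy_mm[2]))
  invisible(x)
}

#' Reduce one A-scan pixel column to presence
#'
#' Collapses the depth axis of a single A-scan to a scalar feature
#' probability (the column maximum, i.e. presence anywhere along depth) and
#' its binarisation at a threshold. The `>=` convention is used, so a value
#' exactly at the threshold counts as present.
#'
#' @param column numeric vector of per-pixel probabilities in `[0, 1]`.
#' @param threshold binarisation threshold in `(0, 1)`.
#' @param reduce `"max"` (presence detection, default) or `"mean"` (for
#'   sensitivity analyses).
#' @return list with elements `probability` and `binary`.
#' @export
reduce_column <- function(column, threshold = 0.5, reduce = c("max", "mean")) {
  reduce <- match.arg(reduce)
  if (length(column) == 0L) stop("empty A-scan column", call. = FALSE)
  p <- if (reduce == "max") max(column) else mean(column)
  list(probability = p, binary = p >= threshold)
}

#' Project a segmentation volume onto the en-face plane
#'
#' One grid cell per (b-scan, A-scan). If the volume holds per-b-scan pixel
#' masks, every A-scan column is reduced with [reduce_column()]; if the
#' volume is already at per-A-scan resolution, values pass through
#' unchanged. Field geometry, laterality and the foveal annotation are
#' carried onto the map.
#'
#' @param volume a [seg_volume()].
#' @param reduce column reduction passed to [reduce_column()].
#' @return an [enface_map()].
#' @export
build_enface <- function(volume, reduce = c("max", "mean")) {
  reduce <- match.arg(reduce)
  stopifnot(inherits(volume, "seg_volume"))
  if (is.list(volume$data)) {
    grid <- t(vapply(volume$data, function(bscan) {
      apply(bscan, 2L, function(col) reduce_column(col, reduce = reduce)$probability)
    }, numeric(ncol(volume$data[[1]]))))
  } else {
    grid <- volume$data
  }
  enface_map(grid, feature = volume$feature, field_mm = volume$field_mm,
             laterality = volume$laterality, fovea_xy_mm = volume$fovea_xy_mm)
}

#' Derive RORA as per-A-scan co-occurrence
#'
#' RORA (RPE and outer retinal atrophy) is defined as retinal area where
#' RPE-loss, photoreceptor degeneration and hypertransmission are all
#' present. On probability maps the cell-wise minimum is used: it is the
#' fuzzy AND whose thresholding commutes with the binary intersection, so
#' binarising the derived map at any threshold t equals the AND of the three
#' constituent maps binarised at t.
#'
#' @param rpe,pdr,ht [enface_map()]s of identical geometry and laterality.
#' @return an [enface_map()] with `feature = "RORA"`.
#' @export
derive_rora <- function(rpe, pdr, ht) {
  maps <- list(rpe, pdr, ht)
  stopifnot(all(vapply(maps, inherits, logical(1), "enface_map")))
  dims <- vapply(maps, function(m) dim(m$grid), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("constituent maps differ in grid geometry", call. = FALSE)
  lat <- unique(vapply(maps, `[[`, character(1), "laterality"))
  if (length(lat) != 1L)
    stop("constituent maps differ in laterality", call. = FALSE)
  enface_map(pmin(rpe$grid, pdr$grid, ht$grid), feature = "RORA",
             field_mm = rpe$field_mm, laterality = rpe$laterality,
             fovea_xy_mm = rpe$fovea_xy_mm)
}

#' Thresholded lesion area in mm-squared
#'
#' Counts cells at or above the probability threshold and multiplies by the
#' per-cell area. Cells carrying `NA` (unscanned fill in standardised grids)
#' never count.
#'
#' @param map an [enface_map()] or [standard_grid()].
#' @param threshold probability threshold in `(0, 1)`; the default 0.5 stands
#'   in for model-specific optimised thresholds, which are acquisition
#'   dependent.
#' @return lesion area in mm^2.
#' @export
lesion_area <- function(map, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  if (inherits(map, "enface_map")) {
    cell_mm2 <- prod(map$spacing_mm)
    g <- map$grid
  } else if (inherits(map, "standard_grid")) {
    cell_mm2 <- prod(2 * map$extent_mm / dim(map$grid))
    g <- map$grid
  } else stop("unsupported map type", call. = FALSE)
  sum(g >= threshold, na.rm = TRUE) * cell_mm2
}
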
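#' ETDRS subfield names used throughout the package
#'
#' Region 1 is the central foveal disc (1 mm diameter), regions 2-5 the
#' parafoveal (inner) ring quadrants out to 3 mm diameter, regions 6-9 the
#' perifoveal (outer) ring quadrants out to 6 mm diameter. After laterality
#' normalisation +x is nasal for every eye, so the quadrant names are
#' anatomically consistent across eyes.
#'
#' @format character vector of length 9.
#' @export
etdrs_region_names <- c("foveal",
                        "inner_superior", "inner_nasal",
                        "inner_inferior", "inner_temporal",
                        "outer_superior", "outer_nasal",
                        "outer_inferior", "outer_temporal")

#' Fovea-centred standardised probability grid
#'
#' A fixed-resolution, laterality-normalised resampling of an en-face map
#' used to compare eyes: the fovea sits exactly on the central cell, +x is
#' nasal, +y is superior. Constructed by [standardize_map()]; this
#' constructor is exposed for tests and synthetic work.
#'
#' @param grid numeric matrix (square) of probabilities; `NA` marks cells
#'   outside the scanned field when `fill = NA` was requested.
#' @param extent_mm half-width of the grid from the fovea, in mm.
#' @param fill the fill policy used for unscanned cells (recorded, not
#'   applied here).
#' @return object of class `standard_grid`.
#' @export
standard_grid <- function(grid, extent_mm = 3, fill = 0) {
  grid <- as.matrix(grid)
  if (nrow(grid) != ncol(grid))
    stop("standard grids are square", call. = FALSE)
  if (nrow(grid) %% 2L == 0L)
    stop("resolution must be odd so the fovea falls on a cell centre",
         call. = FALSE)
  structure(list(grid = grid, extent_mm = extent_mm, fill = fill),
            class = "standard_grid")
}

#' @export
print.standard_grid <- function(x, ...) {
  cat(sprintf("<standard_grid> %d x %d cells, +/- %.1f mm from fovea\n",
              nrow(x$grid), ncol(x$grid), x$extent_mm))
  invisible(x)
}

# Cell-centre coordinates of an R x R standard grid: x (nasal) along columns,
# y (superior) along rows with row 1 at the superior edge.
std_grid_coords <- function(resolution, extent_mm) {
  step <- 2 * extent_mm / resolution
  centres <- -extent_mm + (seq_len(resolution) - 0.5) * step
  list(x = centres, y = rev(centres), step = step)
}

#' Resample an en-face map onto the fovea-centred standard grid
#'
#' Bilinear interpolation of the source grid onto a lattice centred on the
#' annotated fovea. Left (OS) eyes are mirrored horizontally before
#' resampling so that +x is nasal for every eye; target cells whose source
#' location falls outside the scanned field receive `fill`.
#'
#' @param map an [enface_map()] with fovea annotation and laterality.
#' @param resolution odd cell count per side of the output grid.
#' @param extent_mm half-width of the output grid from the fovea (3 mm spans
#'   the full 6 mm ETDRS circle).
#' @param fill value for cells outside the scanned field (0 by default;
#'   `NA` to mark them missing and exclude them from region summaries).
#' @return a [standard_grid()].
#' @export
standardize_map <- function(map, resolution = 49, extent_mm = 3, fill = 0) {
  stopifnot(inherits(map, "enface_map"))
  if (is.null(map$fovea_xy_mm))
    stop("en-face map carries no fovea annotation", call. = FALSE)
  if (is.null(map$laterality))
    stop("en-face map carries no laterality", call. = FALSE)
  g <- map$grid
  fov <- map$fovea_xy_mm
  if (map$laterality == "OS") {          # mirror so +x is nasal
    g <- g[, rev(seq_len(ncol(g))), drop = FALSE]
    fov[1] <- map$field_mm[1] - fov[1]
  }
  sp <- map$spacing_mm                   # (row, col) mm per cell
  src_x <- (seq_len(ncol(g)) - 0.5) * sp[2]
  src_y <- (seq_len(nrow(g)) - 0.5) * sp[1]
  cc <- std_grid_coords(resolution, extent_mm)
  # target cell (i, j) offset from fovea: dx = cc$x[j] nasal, dy = cc$y[i]
  # superior; source y runs top-down so superior offsets subtract.
  xp <- outer(rep(1, resolution), fov[1] + cc$x)
  yp <- outer(fov[2] - cc$y, rep(1, resolution))
  tol <- 1e-9 * max(map$field_mm)    # guards exact-boundary cells against fp
  inside <- xp >= src_x[1] - tol & xp <= src_x[length(src_x)] + tol &
            yp >= src_y[1] - tol & yp <= src_y[length(src_y)] + tol
  out <- matrix(fill, resolution, resolution)
  if (any(inside)) {
    xq <- pmin(pmax(xp[inside], src_x[1]), src_x[length(src_x)])
    yq <- pmin(pmax(yp[inside], src_y[1]), src_y[length(src_y)])
    out[inside] <- pracma::interp2(src_x, src_y, g, xq, yq,
                                   method = "linear")
  }
  standard_grid(out, extent_mm = extent_mm, fill = fill)
}

#' Assign standard-grid cells to ETDRS subfields
#'
#' Labels every cell of an `R x R` fovea-centred grid by the subfield its
#' centre falls in: 0 outside the 6 mm circle, 1 foveal (r < 0.5 mm), 2-5
#' parafoveal and 6-9 perifoveal quadrants. Quadrants are split at the 45
#' degree diagonals with half-open angle intervals and half-open radius bins
#' `[0.5, 1.5)` and `[1.5, 3)` so every cell gets exactly one label.
#'
#' @param resolution cells per side.
#' @param extent_mm half-width of the grid in mm (must be >= 3 so the 6 mm
#'   circle fits).
#' @param radii_mm the three ETDRS radii (foveal, inner, outer).
#' @return object of class `etdrs_labels`: integer label matrix plus the
#'   geometry used.
#' @export
etdrs_labels <- function(resolution = 49, extent_mm = 3,
                         radii_mm = c(0.5, 1.5, 3)) {
  stopifnot(extent_mm >= radii_mm[3])
  cc <- std_grid_coords(resolution, extent_mm)
  x <- matrix(cc$x, resolution, resolution, byrow = TRUE)
  y <- matrix(cc$y, resolution, resolution)
  r <- sqrt(x^2 + y^2)
  ang <- (atan2(y, x) * 180 / pi) %% 360
  quad <- integer(length(ang))                       # 0 sup, 1 nas, 2 inf, 3 tmp
  quad[ang >= 45 & ang < 135] <- 0L                  # superior
  quad[ang >= 135 & ang < 225] <- 3L                 # temporal (-x)
  quad[ang >= 225 & ang < 315] <- 2L                 # inferior
  quad[ang < 45 | ang >= 315] <- 1L                  # nasal (+x)
  lab <- matrix(0L, resolution, resolution)
  lab[r < radii_mm[1]] <- 1L
  inner <- r >= radii_mm[1] & r < radii_mm[2]
  outer <- r >= radii_mm[2] & r < radii_mm[3]
  lab[inner] <- 2L + quad[inner]
  lab[outer] <- 6L + quad[outer]
  structure(list(labels = lab, resolution = resolution,
                 extent_mm = extent_mm, radii_mm = radii_mm,
                 region_names = etdrs_region_names),
            class = "etdrs_labels")
}

#' Discretised subfield areas
#'
#' Cell-count area of each ETDRS subfield under a given discretisation;
#' converges to the analytic ring-quadrant areas (foveal pi/4 ~ 0.785 mm^2)
#' as resolution grows.
#'
#' @param labels an [etdrs_labels()].
#' @return named numeric vector of areas in mm^2 (9 subfields).
#' @export
etdrs_region_areas <- function(labels) {
  stopifnot(inherits(labels, "etdrs_labels"))
  cell <- (2 * labels$extent_mm / labels$resolution)^2
  counts <- tabulate(labels$labels[labels$labels > 0L], nbins = 9L)
  stats::setNames(counts * cell, labels$region_names)
}

#' Mean feature probability per ETDRS subfield
#'
#' @param grid a [standard_grid()].
#' @param labels an [etdrs_labels()] of matching resolution.
#' @return named numeric vector of 9 means; a region whose cells are all
#'   fill-`NA` is reported as `NA`.
#' @export
region_means <- function(grid, labels) {
  stopifnot(inherits(grid, "standard_grid"), inherits(labels, "etdrs_labels"))
  if (nrow(grid$grid) != labels$resolution)
    stop("grid and labels differ in resolution", call. = FALSE)
  out <- vapply(1:9, function(k) {
    v <- grid$grid[labels$labels == k]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  stats::setNames(out, labels$region_names)
}

#' Does RORA involve the fovea?
#'
#' TRUE if any cell of the central foveal subfield reaches the probability
#' threshold; FALSE marks a foveal-sparing eye.
#'
#' @param grid a [standard_grid()] of RORA probabilities.
#' @param labels an [etdrs_labels()] of matching resolution.
#' @param threshold probability threshold.
#' @return logical scalar.
#' @export
foveal_involvement <- function(grid, labels, threshold = 0.5) {
  stopifnot(inherits(grid, "standard_grid"), inherits(labels, "etdrs_labels"))
  v <- grid$grid[labels$labels == 1L]
  any(v >= threshold, na.rm = TRUE)
}
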
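#' Per-cell importance table of a fitted model
#'
#' Maps the normalised percentage importances of a [fit_structfunc()] result
#' back to (feature, grid cell) via the deterministic column order.
#'
#' @param fit a `structfunc_fit`.
#' @return data frame with columns `feature`, `row`, `col`,
#'   `importance_pct`; the percentages total 100 (up to numerical
#'   tolerance).
#' @export
importance_by_cell <- function(fit) {
  stopifnot(inherits(fit, "structfunc_fit"))
  info <- fit$column_info
  expected <- sprintf("%s_r%02d_c%02d", info$feature, info$row, info$col)
  if (!identical(expected, names(fit$importance)))
    stop("column order mismatch between importances and column info",
         call. = FALSE)
  data.frame(info, importance_pct = unname(fit$importance),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate importance per ETDRS subfield and feature
#'
#' Sums per-cell percentage importances over the cells of each ETDRS
#' subfield, per feature, yielding the 9 regions x 4 features percentage
#' matrix. Importance falling on cells outside the 6 mm circle is reported
#' as an explicit `outside` remainder so that matrix + remainder = 100.
#'
#' @param x a `structfunc_fit` or a per-cell importance data frame as
#'   returned by [importance_by_cell()].
#' @param labels an [etdrs_labels()] whose resolution matches the cell grid.
#' @return object of class `region_importance`: `matrix` (9 x 4), `outside`
#'   remainder, `row_sums`, `col_sums`, `total`.
#' @export
aggregate_by_region <- function(x, labels) {
  if (inherits(x, "structfunc_fit")) x <- importance_by_cell(x)
  stopifnot(inherits(labels, "etdrs_labels"),
            all(c("feature", "row", "col", "importance_pct") %in% colnames(x)))
  if (max(x$row) > labels$resolution || max(x$col) > labels$resolution)
    stop("labels resolution does not cover the cell grid", call. = FALSE)
  feats <- c("RPE_LOSS", "PDR", "HT", "RORA")
  lab <- labels$labels[cbind(x$row, x$col)]
  m <- matrix(0, 9, length(feats),
              dimnames = list(labels$region_names, feats))
  for (k in 1:9) for (f in feats) {
    sel <- lab == k & x$feature == f
    m[k, f] <- sum(x$importance_pct[sel])
  }
  outside <- sum(x$importance_pct[lab == 0L])
  region_importance(m, outside = outside)
}

#' Construct a region x feature importance table
#'
#' @param matrix 9 x 4 numeric matrix of percentage contributions (rows =
#'   ETDRS subfields in the order of [etdrs_region_names], columns =
#'   features).
#' @param outside percentage mass on cells outside the 6 mm circle.
#' @return object of class `region_importance`.
#' @export
region_importance <- function(matrix, outside = 0) {
  stopifnot(nrow(matrix) == 9)
  if (is.null(rownames(matrix))) rownames(matrix) <- etdrs_region_names
  structure(list(matrix = matrix, outside = outside,
                 row_sums = rowSums(matrix), col_sums = colSums(matrix),
                 total = sum(matrix) + outside),
            class = "region_importance")
}

#' @export
print.region_importance <- function(x, digits = 1, ...) {
  m <- rbind(x$matrix, Sum = x$col_sums)
  m <- cbind(m, Sum = c(x$row_sums, sum(x$col_sums)))
  cat("Importance (% contribution) by ETDRS region and feature:\n")
  print(round(m, digits))
  if (x$outside > 1e-9)
    cat(sprintf("Outside 6 mm circle: %.*f%%\n", digits, x$outside))
  invisible(x)
}

#' Foveal versus non-foveal share of model importance
#'
#' @param x a `region_importance`, or the foveal percentage itself.
#' @return list with `foveal_share` (the foveal row sum) and
#'   `nonfoveal_share` (its complement to 100).
#' @export
foveal_shares <- function(x) {
  fov <- if (inherits(x, "region_importance")) unname(x$row_sums["foveal"])
         else as.numeric(x)
  list(foveal_share = fov, nonfoveal_share = 100 - fov)
}

# Spread a printed region x feature percentage table back onto grid cells
# (one representative cell per subfield) so the aggregation path can be
# exercised against published tables.
region_matrix_to_cells <- function(m, labels) {
  feats <- colnames(m)
  cells <- do.call(rbind, lapply(1:9, function(k) {
    idx <- which(labels$labels == k, arr.ind = TRUE)[1, , drop = FALSE]
    do.call(rbind, lapply(feats, function(f)
      data.frame(feature = f, row = idx[1], col = idx[2],
                 importance_pct = m[k, f], stringsAsFactors = FALSE)))
  }))
  rownames(cells) <- NULL
  cells
}

#' Render per-feature importance heatmaps
#'
#' One en-face panel per feature on the standard grid, shared colour scale,
#' fovea marked at the centre, optional ETDRS ring overlay. Importances are
#' the replicate-averaged percentage contributions of
#' [importance_by_cell()].
#'
#' @param x a `structfunc_fit`.
#' @param features which features to draw.
#' @param etdrs_rings draw the 1 / 3 / 6 mm circles.
#' @param palette colour ramp function.
#' @param ... ignored.
#' @return invisibly, the list of per-feature importance matrices drawn.
#' @export
plot.structfunc_fit <- function(x, features = c("RPE_LOSS", "PDR", "HT", "RORA"),
                                etdrs_rings = TRUE,
                                palette = grDevices::hcl.colors, ...) {
  cells <- importance_by_cell(x)
  b <- x$block_dim
  ext <- x$extent_mm
  mats <- lapply(features, function(f) {
    m <- matrix(0, b, b)
    sel <- cells$feature == f
    m[cbind(cells$row[sel], cells$col[sel])] <- cells$importance_pct[sel]
    m
  })
  names(mats) <- features
  zlim <- range(0, unlist(mats))
  if (diff(zlim) == 0) zlim <- c(0, 1)
  cols <- palette(64, "viridis")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(features)),
                       mar = c(2, 2, 2, 1))
  on.exit(graphics::par(old))
  cc <- std_grid_coords(b, ext)
  for (f in features) {
    # image() draws rows along x; transpose and flip so row 1 is superior
    graphics::image(cc$x, sort(cc$y), t(mats[[f]][b:1, , drop = FALSE]),
                    zlim = zlim, col = cols, asp = 1, xlab = "", ylab = "",
                    main = f, useRaster = TRUE)
    graphics::points(0, 0, pch = 3, col = "white")
    if (etdrs_rings) {
      th <- seq(0, 2 * pi, length.out = 181)
      for (r in c(0.5, 1.5, 3))
        graphics::lines(r * cos(th), r * sin(th), col = "white", lty = 3)
    }
  }
  invisible(mats)
}

#' Reference region x feature importance tables
#'
#' Loads the region-by-feature percentage-importance tables reported for a
#' large clinical GA cohort (standard VA and low-luminance VA models),
#' shipped as plain CSV. They serve as worked examples for the aggregation
#' arithmetic: re-summing the nine subfield rows reproduces the printed
#' feature column totals and the foveal/non-foveal split. Note that a few
#' printed marginal sums differ from cell-wise addition by 0.1 due to
#' rounding of the published cells; the printed marginals are kept alongside
#' the cells.
#'
#' @param which `"va"` or `"llva"`.
#' @return list with `matrix` (9 x 4 percentages), `printed_row_sums`,
#'   `printed_col_sums`.
#' @export
reference_importance <- function(which = c("va", "llva")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_region_importance.csv"),
                      package = "gasf", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  feats <- c("RPE_LOSS", "PDR", "HT", "RORA")
  rows <- d$region != "column_sum"
  m <- as.matrix(d[rows, feats])
  rownames(m) <- d$region[rows]
  list(matrix = m,
       printed_row_sums = stats::setNames(d$printed_sum[rows], d$region[rows]),
       printed_col_sums = stats::setNames(
         unlist(d[!rows, feats]), feats))
}
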
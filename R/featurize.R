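#' Assemble the voxel-level feature table
#'
#' Standardises every eye's four feature maps (three raw plus derived RORA)
#' onto the fovea-centred grid, optionally block-averages them by a factor
#' `k`, and flattens them into one row per eye with a deterministic column
#' order: feature-major (RPE_LOSS, PDR, HT, RORA), then row-major cell
#' order. Eyes missing the requested outcome are dropped with a message.
#'
#' @param cohort a `ga_cohort` from [simulate_ga_cohort()], or any list with
#'   `eyes` (per-eye `maps` of the four [enface_map()]s) and `outcomes`.
#' @param outcome which outcome column to carry: `"va"`, `"llva"` or
#'   `"lld"`.
#' @param downsample_k block-mean downsampling factor; must divide the
#'   standard-grid resolution (`k = 1` keeps raw cells).
#' @param resolution standard-grid resolution before downsampling.
#' @param fill fill value for unscanned cells, passed to
#'   [standardize_map()].
#' @return a data frame of class `feature_table`: columns `patient_id`,
#'   `eye_id`, `outcome`, then the predictor columns in deterministic
#'   order. Attributes: `column_info` (feature/row/col per predictor),
#'   `block_dim` (cells per side after downsampling), `outcome_name`,
#'   `extent_mm`.
#' @export
build_feature_table <- function(cohort, outcome = c("va", "llva", "lld"),
                                downsample_k = 1, resolution = 49,
                                fill = 0) {
  outcome <- match.arg(outcome)
  k <- as.integer(downsample_k)
  if (resolution %% k != 0L)
    stop("downsample_k must divide the resolution", call. = FALSE)
  b <- resolution %/% k
  feats <- c("RPE_LOSS", "PDR", "HT", "RORA")
  out_col <- paste0(outcome, "_letters")
  oc <- cohort$outcomes
  if (is.null(oc[[out_col]]))
    stop("outcome column '", out_col, "' is missing from the cohort",
         call. = FALSE)

  rows <- lapply(cohort$eyes, function(e) {
    unlist(lapply(feats, function(f) {
      sg <- standardize_map(e$maps[[f]], resolution = resolution, fill = fill)
      block_mean(sg$grid, k)
    }), use.names = FALSE)
  })
  mat <- do.call(rbind, rows)

  info <- expand.grid(col = seq_len(b), row = seq_len(b),
                      feature = feats, stringsAsFactors = FALSE)[, c(3, 2, 1)]
  # row-major within feature: row varies slower than col
  info <- info[order(match(info$feature, feats), info$row, info$col), ]
  cn <- sprintf("%s_r%02d_c%02d", info$feature, info$row, info$col)
  colnames(mat) <- cn

  eye_ids <- vapply(cohort$eyes, `[[`, character(1), "eye_id")
  m <- match(eye_ids, oc$eye_id)
  y <- oc[[out_col]][m]
  keep <- !is.na(y)
  if (any(!keep))
    message(sum(!keep), " eye(s) dropped for missing ", outcome)

  tab <- data.frame(patient_id = oc$patient_id[m][keep],
                    eye_id = eye_ids[keep],
                    outcome = y[keep],
                    mat[keep, , drop = FALSE],
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  structure(tab, column_info = info, block_dim = b,
            outcome_name = outcome, extent_mm = 3,
            class = c("feature_table", "data.frame"))
}

# Block mean of a square matrix by factor k; the matrix is flattened in
# row-major cell order (row varies slower) to match the column order.
block_mean <- function(g, k) {
  if (k == 1L) return(as.vector(t(g)))
  b <- nrow(g) %/% k
  out <- matrix(0, b, b)
  for (i in seq_len(b)) for (j in seq_len(b)) {
    out[i, j] <- mean(g[((i - 1) * k + 1):(i * k),
                        ((j - 1) * k + 1):(j * k)], na.rm = TRUE)
  }
  as.vector(t(out))
}

predictor_columns <- function(table) {
  setdiff(colnames(table), c("patient_id", "eye_id", "outcome"))
}
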
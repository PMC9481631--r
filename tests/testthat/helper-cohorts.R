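# Shared fixtures, all generated in code under fixed seeds.

# Small cohort on a 25 x 25 raster; cached across test files.
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_ga_cohort(synth_config(n_patients = 20,
                                                grid = c(25, 25),
                                                rng_seed = 404))
    cache
  }
})

# A feature-table shaped data frame with controllable signal, bypassing the
# image stages; used to test the bootstrap machinery in isolation.
make_toy_table <- function(n_patients = 100, eyes_per_patient = 2,
                           block_dim = 3, seed = 1,
                           outcome_fun = NULL, noise_sd = 0) {
  set.seed(seed)
  feats <- c("RPE_LOSS", "PDR", "HT", "RORA")
  b <- block_dim
  info <- expand.grid(col = seq_len(b), row = seq_len(b),
                      feature = feats, stringsAsFactors = FALSE)[, c(3, 2, 1)]
  info <- info[order(match(info$feature, feats), info$row, info$col), ]
  cn <- sprintf("%s_r%02d_c%02d", info$feature, info$row, info$col)
  n <- n_patients * eyes_per_patient
  x <- matrix(runif(n * length(cn)), n, length(cn), dimnames = list(NULL, cn))
  if (is.null(outcome_fun)) outcome_fun <- function(x) 80 - 40 * x[, 1]
  y <- outcome_fun(x) + rnorm(n, 0, noise_sd)
  tab <- data.frame(
    patient_id = rep(sprintf("P%03d", seq_len(n_patients)),
                     each = eyes_per_patient),
    eye_id = sprintf("E%04d", seq_len(n)),
    outcome = y, x, check.names = FALSE, stringsAsFactors = FALSE)
  structure(tab, column_info = info, block_dim = b, outcome_name = "va",
            extent_mm = 3, class = c("feature_table", "data.frame"))
}

# Random probability map helper.
random_enface <- function(nr = 9, nc = 9, feature = "RPE_LOSS",
                          laterality = "OD", fovea = c(3, 3), seed = 1) {
  set.seed(seed)
  enface_map(matrix(runif(nr * nc), nr, nc), feature = feature,
             field_mm = c(6, 6), laterality = laterality,
             fovea_xy_mm = fovea)
}
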
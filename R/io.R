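#' Write / read an en-face map as a CSV grid with a JSON sidecar
#'
#' The grid goes to `<prefix>.csv` (plain numeric matrix, no header) and the
#' metadata (feature, field, fovea, laterality) to `<prefix>.json`; the pair
#' round-trips exactly at full double precision.
#'
#' @param map an [enface_map()].
#' @param prefix file path without extension.
#' @return the prefix, invisibly.
#' @export
write_enface <- function(map, prefix) {
  stopifnot(inherits(map, "enface_map"))
  utils::write.table(format(map$grid, digits = 17, trim = TRUE, scientific = TRUE),
                     paste0(prefix, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(feature = map$feature, field_mm = map$field_mm,
               fovea_xy_mm = map$fovea_xy_mm, laterality = map$laterality)
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_enface
#' @export
read_enface <- function(prefix) {
  g <- as.matrix(utils::read.table(paste0(prefix, ".csv"), sep = ","))
  dimnames(g) <- NULL
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  enface_map(g, feature = meta$feature, field_mm = meta$field_mm,
             laterality = meta$laterality,
             fovea_xy_mm = if (length(meta$fovea_xy_mm)) meta$fovea_xy_mm)
}

#' Write a synthetic cohort to disk
#'
#' Emits one CSV grid + JSON sidecar per eye per feature (the three raw
#' features and derived RORA), `cohort.csv` with the per-eye outcome table,
#' and `truth.json` with the generating parameters.
#'
#' @param cohort a `ga_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (e in cohort$eyes)
    for (f in names(e$maps))
      write_enface(e$maps[[f]], file.path(dir, paste0(e$eye_id, "_", f)))
  utils::write.csv(cohort$outcomes, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth[c("beta_va", "beta_lld",
                                      "noise_sd_letters")],
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `cohort.csv` and the per-eye map files.
#' @return a `ga_cohort`-shaped list (without generator truth unless
#'   `truth.json` is present).
#' @export
read_cohort <- function(dir) {
  oc <- utils::read.csv(file.path(dir, "cohort.csv"),
                        stringsAsFactors = FALSE)
  feats <- c("RPE_LOSS", "PDR", "HT", "RORA")
  eyes <- lapply(seq_len(nrow(oc)), function(i) {
    maps <- lapply(feats, function(f)
      read_enface(file.path(dir, paste0(oc$eye_id[i], "_", f))))
    names(maps) <- feats
    list(maps = maps,
         fovea_xy_mm = c(oc$fovea_x_mm[i], oc$fovea_y_mm[i]),
         laterality = oc$eye_side[i], patient_id = oc$patient_id[i],
         eye_id = oc$eye_id[i])
  })
  names(eyes) <- oc$eye_id
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  structure(list(eyes = eyes, outcomes = oc, truth = truth),
            class = "ga_cohort")
}

#' Thresholded areas for every eye and feature
#'
#' @param cohort a `ga_cohort`.
#' @param threshold probability threshold.
#' @return data frame `eye_id` x feature columns, areas in mm^2.
#' @export
cohort_areas <- function(cohort, threshold = 0.5) {
  feats <- c("RPE_LOSS", "PDR", "HT", "RORA")
  a <- t(vapply(cohort$eyes, function(e)
    vapply(feats, function(f) lesion_area(e$maps[[f]], threshold),
           numeric(1)), numeric(4)))
  data.frame(eye_id = names(cohort$eyes), a, row.names = NULL,
             stringsAsFactors = FALSE)
}
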
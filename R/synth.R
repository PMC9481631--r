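#' Configuration of the synthetic GA cohort simulator
#'
#' Collects the knobs of the lesion and outcome generator. The defaults are
#' calibrated once so that, at cohort scale, the median thresholded lesion
#' areas approach clinically typical values for GA (about 7.8 mm^2 RPE-loss,
#' 14.4 mm^2 photoreceptor degeneration, 9.2 mm^2 hypertransmission, with
#' derived RORA around 6 mm^2), roughly 15% of eyes are foveal-sparing, and
#' the structure-function law is strong enough to be recoverable through the
#' random-forest stage at realistic noise.
#'
#' @param n_patients number of patients; each contributes one or two eyes.
#' @param frac_bilateral probability that a patient contributes both eyes
#'   (0.46 reproduces roughly 1.46 eyes per patient).
#' @param grid raster size `c(rows, cols)` = (b-scans, A-scans).
#' @param field_mm physical field width/height in mm.
#' @param n_seeds_range inclusive integer range for the lesion seed count.
#' @param target_median_areas_mm2 named calibration targets for the cohort
#'   median thresholded areas (RORA entry is a derived reference, not a
#'   direct target).
#' @param beta_va structure-function law for standard visual acuity:
#'   `va = intercept - foveal_rora_coef * mean foveal RORA probability -
#'   extrafoveal_rora_area_coef * extrafoveal RORA area (mm^2) + noise`,
#'   clamped to \[0, 100\] ETDRS letters.
#' @param beta_lld law for the low-luminance deficit:
#'   `lld = intercept + parafoveal_pdr_coef * mean parafoveal PDR
#'   probability + noise`, clamped to \[0, min(va, 100)\];
#'   `llva = va - lld`.
#' @param noise_sd_letters SD of the additive Gaussian noise on both laws.
#' @param rng_seed master seed; the full cohort is a deterministic function
#'   of the configuration.
#' @param sparing_spread_mm SD (mm) of the fovea-centred Gaussian from which
#'   lesion seed positions are drawn; larger values push lesions peripheral
#'   and increase the foveal-sparing fraction.
#' @param base_radius_mm median lesion-kernel radius before patient/eye
#'   burden scaling.
#' @param halo_range_mm uniform range of the PDR halo added to every kernel
#'   radius (photoreceptor degeneration extends beyond RPE-loss).
#' @param extra_patch_rate Poisson rate of small independent PDR patches.
#' @param ht_noise_meanlog,ht_noise_sdlog log-normal parameters of the
#'   smooth multiplicative field perturbing RPE-loss into hypertransmission;
#'   a positive meanlog makes hypertransmission slightly larger than
#'   RPE-loss on average.
#' @param burden_sdlog SD (log scale) of the patient-level lesion-burden
#'   random effect shared by both eyes of a patient.
#' @param area_threshold probability threshold at which calibration areas
#'   are measured.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 205,
                         frac_bilateral = 0.46,
                         grid = c(49, 49),
                         field_mm = 6,
                         n_seeds_range = c(1, 4),
                         target_median_areas_mm2 = c(RPE_LOSS = 7.82,
                                                     PDR = 14.4,
                                                     HT = 9.23,
                                                     RORA = 6.22),
                         beta_va = list(intercept_letters = 82,
                                        foveal_rora_coef = 28,
                                        extrafoveal_rora_area_coef = 0.35),
                         beta_lld = list(intercept_letters = 2,
                                         parafoveal_pdr_coef = 25),
                         noise_sd_letters = 12,
                         rng_seed = 1,
                         sparing_spread_mm = 1.15,
                         base_radius_mm = 0.86,
                         halo_range_mm = c(0.08, 0.5),
                         extra_patch_rate = 1,
                         ht_noise_meanlog = 0.13,
                         ht_noise_sdlog = 0.6,
                         burden_sdlog = 0.35,
                         area_threshold = 0.5) {
  cfg <- list(n_patients = as.integer(n_patients),
              frac_bilateral = frac_bilateral, grid = as.integer(grid),
              field_mm = field_mm, n_seeds_range = as.integer(n_seeds_range),
              target_median_areas_mm2 = target_median_areas_mm2,
              beta_va = beta_va, beta_lld = beta_lld,
              noise_sd_letters = noise_sd_letters,
              rng_seed = as.integer(rng_seed),
              sparing_spread_mm = sparing_spread_mm,
              base_radius_mm = base_radius_mm,
              halo_range_mm = halo_range_mm,
              extra_patch_rate = extra_patch_rate,
              ht_noise_meanlog = ht_noise_meanlog,
              ht_noise_sdlog = ht_noise_sdlog,
              burden_sdlog = burden_sdlog,
              area_threshold = area_threshold)
  validate_synth_config(structure(cfg, class = "synth_config"))
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1,
            cfg$frac_bilateral >= 0, cfg$frac_bilateral <= 1,
            cfg$noise_sd_letters >= 0,
            cfg$n_seeds_range[1] >= 0,
            cfg$n_seeds_range[2] >= cfg$n_seeds_range[1])
  tgt <- cfg$target_median_areas_mm2
  if (any(tgt <= 0) || any(tgt > cfg$field_mm^2))
    stop("area targets must lie in (0, field_mm^2]", call. = FALSE)
  for (b in list(cfg$beta_va, cfg$beta_lld)) {
    if (b$intercept_letters < 0 || b$intercept_letters > 100)
      stop("intercepts must lie in [0, 100] letters", call. = FALSE)
  }
  cfg
}

# Deterministic per-eye / per-stage seed derivation from the master seed.
# Stage codes keep independent streams apart; all seeds stay below 2^31.
derive_seed <- function(master, index = 0L, stage = 0L) {
  as.integer((as.numeric(master %% 1000003L) * 1009 + index * 7 + stage) %%
               2147483647)
}

# Upsample a coarse noise lattice to the full raster by bilinear
# interpolation; coordinates are clamped to the coarse centre range so edges
# extend the boundary values.
smooth_noise_field <- function(nr, nc, field_mm, coarse = 7L,
                               meanlog = 0, sdlog = 0.25) {
  vals <- matrix(stats::rlnorm(coarse * coarse, meanlog, sdlog), coarse, coarse)
  cx <- (seq_len(coarse) - 0.5) * field_mm / coarse
  gx <- (seq_len(nc) - 0.5) * field_mm / nc
  gy <- (seq_len(nr) - 0.5) * field_mm / nr
  gx <- pmin(pmax(gx, cx[1]), cx[coarse])
  gy <- pmin(pmax(gy, cx[1]), cx[coarse])
  xp <- matrix(gx, nr, nc, byrow = TRUE)
  yp <- matrix(gy, nr, nc)
  matrix(pracma::interp2(cx, cx, vals, as.vector(xp), as.vector(yp),
                         method = "linear"), nr, nc)
}

# Maximum-of-kernels lesion field: value exp(-d^2 / (2 r^2)) per seed.
kernel_field <- function(nr, nc, field_mm, cx, cy, radii) {
  gx <- (seq_len(nc) - 0.5) * field_mm / nc
  gy <- (seq_len(nr) - 0.5) * field_mm / nr
  f <- matrix(0, nr, nc)
  for (j in seq_along(cx)) {
    d2 <- outer((gy - cy[j])^2, (gx - cx[j])^2, `+`)
    f <- pmax(f, exp(-d2 / (2 * radii[j]^2)))
  }
  f
}

# Soft thresholding of a kernel field into a probability map. The logistic
# centre 0.45 and width 0.07 give near-binary confluent lesions with smooth
# margins; at the 0.5 binarisation threshold the lesion boundary sits at
# field value 0.45.
LESION_LOGISTIC_MID <- 0.45
LESION_LOGISTIC_WIDTH <- 0.07
field_to_prob <- function(f) {
  stats::plogis((f - LESION_LOGISTIC_MID) / LESION_LOGISTIC_WIDTH)
}

#' Generate the three raw lesion probability maps for one eye
#'
#' Samples lesion seeds from a fovea-centred Gaussian, grows an RPE-loss
#' field as the maximum of radial kernels, derives photoreceptor
#' degeneration (PDR) as the same kernels dilated by a halo plus independent
#' small patches (so PDR area stochastically dominates RPE-loss area), and
#' hypertransmission as the RPE-loss field under smooth multiplicative
#' noise. RORA is never generated directly; it is always derived downstream
#' via [derive_rora()].
#'
#' @param config a [synth_config()].
#' @param eye_index integer index of the eye within the cohort; together
#'   with `config$rng_seed` it fully determines the draw.
#' @param burden patient-level lesion-burden multiplier (shared between the
#'   two eyes of a bilateral patient).
#' @return named list of three [seg_volume()]s (`RPE_LOSS`, `PDR`, `HT`) at
#'   per-A-scan resolution.
#' @export
generate_lesions <- function(config, eye_index, burden = 1) {
  stopifnot(inherits(config, "synth_config"))
  nr <- config$grid[1]; nc <- config$grid[2]; fm <- config$field_mm
  set.seed(derive_seed(config$rng_seed, eye_index, 1L))
  zero <- matrix(0, nr, nc)
  make_vol <- function(g, feat)
    seg_volume(g, feature = feat, field_mm = c(fm, fm), min_bscans = 1)

  for (attempt in 1:5) {
    K <- resample_int(config$n_seeds_range)
    if (K == 0L)
      return(list(RPE_LOSS = make_vol(zero, "RPE_LOSS"),
                  PDR = make_vol(zero, "PDR"),
                  HT = make_vol(zero, "HT")))
    eye_jit <- stats::rlnorm(1, 0, 0.15)
    cx <- clamp(fm / 2 + stats::rnorm(K, 0, config$sparing_spread_mm),
                0.3, fm - 0.3)
    cy <- clamp(fm / 2 + stats::rnorm(K, 0, config$sparing_spread_mm),
                0.3, fm - 0.3)
    radii <- config$base_radius_mm * burden * eye_jit *
      stats::rlnorm(K, 0, 0.30)
    f_rpe <- kernel_field(nr, nc, fm, cx, cy, radii)

    halo <- stats::runif(1, config$halo_range_mm[1], config$halo_range_mm[2])
    k2 <- stats::rpois(1, config$extra_patch_rate)
    pcx <- c(cx, stats::runif(k2, 0.3, fm - 0.3))
    pcy <- c(cy, stats::runif(k2, 0.3, fm - 0.3))
    pradii <- c(radii + halo, stats::runif(k2, 0.3, 0.7))
    f_pdr <- kernel_field(nr, nc, fm, pcx, pcy, pradii)

    m <- smooth_noise_field(nr, nc, fm, coarse = 10L,
                            meanlog = config$ht_noise_meanlog,
                            sdlog = config$ht_noise_sdlog)
    f_ht <- f_rpe * m

    p_rpe <- field_to_prob(f_rpe)
    if (sum(p_rpe >= config$area_threshold) > 0 || attempt == 5)
      return(list(RPE_LOSS = make_vol(p_rpe, "RPE_LOSS"),
                  PDR = make_vol(field_to_prob(f_pdr), "PDR"),
                  HT = make_vol(pmin(field_to_prob(f_ht), 1), "HT")))
  }
}

resample_int <- function(range) {
  if (range[1] == range[2]) return(range[1])
  sample(seq.int(range[1], range[2]), 1L)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a synthetic GA cohort
#'
#' Draws the patient/eye structure (uni- or bilateral per
#' `frac_bilateral`, with a shared patient-level lesion burden), generates
#' the three raw feature volumes per eye with [generate_lesions()], annotates
#' a foveal centre near the field centre, and attaches VA / LLVA / LLD
#' outcomes under the configured structure-function law with
#' [generate_outcomes()].
#'
#' @param config a [synth_config()].
#' @return object of class `ga_cohort`: `eyes` (per-eye list with the three
#'   [enface_map()]s plus derived RORA), `outcomes` (data frame), `truth`
#'   (generating parameters and per-eye latent covariates), `config`.
#' @export
simulate_ga_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$rng_seed, 0L, 2L))
  n_pat <- config$n_patients
  bilateral <- stats::runif(n_pat) < config$frac_bilateral
  burden <- stats::rlnorm(n_pat, 0, config$burden_sdlog)
  first_side <- ifelse(stats::runif(n_pat) < 0.5, "OD", "OS")

  eye_tab <- do.call(rbind, lapply(seq_len(n_pat), function(p) {
    sides <- if (bilateral[p]) c("OD", "OS") else first_side[p]
    data.frame(patient_id = sprintf("P%03d", p), eye_side = sides,
               burden = burden[p], stringsAsFactors = FALSE)
  }))
  eye_tab$eye_id <- sprintf("%s_%s", eye_tab$patient_id, eye_tab$eye_side)
  n_eyes <- nrow(eye_tab)
  fm <- config$field_mm

  eyes <- vector("list", n_eyes)
  names(eyes) <- eye_tab$eye_id
  for (i in seq_len(n_eyes)) {
    vols <- generate_lesions(config, i, burden = eye_tab$burden[i])
    set.seed(derive_seed(config$rng_seed, i, 3L))
    fovea <- clamp(fm / 2 + stats::rnorm(2, 0, 0.15), 0.5, fm - 0.5)
    maps <- lapply(vols, function(v) {
      v$laterality <- eye_tab$eye_side[i]
      v$fovea_xy_mm <- fovea
      build_enface(v)
    })
    maps$RORA <- derive_rora(maps$RPE_LOSS, maps$PDR, maps$HT)
    eyes[[i]] <- list(maps = maps, fovea_xy_mm = fovea,
                      laterality = eye_tab$eye_side[i],
                      patient_id = eye_tab$patient_id[i],
                      eye_id = eye_tab$eye_id[i])
  }

  cohort <- structure(list(eyes = eyes, config = config,
                           truth = list(beta_va = config$beta_va,
                                        beta_lld = config$beta_lld,
                                        noise_sd_letters = config$noise_sd_letters,
                                        burden = stats::setNames(burden,
                                                                 sprintf("P%03d", seq_len(n_pat))))),
                      class = "ga_cohort")
  cohort$outcomes <- generate_outcomes(cohort, config)
  cohort$truth$covariates <- attr(cohort$outcomes, "covariates")
  cohort
}

#' Attach VA / LLVA / LLD outcomes to generated lesions
#'
#' Computes the latent structural covariates of every eye on the
#' fovea-centred standard grid (mean foveal RORA probability, extrafoveal
#' RORA area in mm^2, mean parafoveal PDR probability) and applies the
#' configured linear structure-function law with additive Gaussian noise:
#' `va` falls with foveal and extrafoveal RORA; the low-luminance deficit
#' `lld` grows with parafoveal PDR; `llva = va - lld`. All letter scores are
#' clamped to \[0, 100\] and `lld` to \[0, va\], so `llva <= va` and
#' `lld >= 0` always hold.
#'
#' @param cohort a `ga_cohort` (outcomes may be absent).
#' @param config a [synth_config()].
#' @return data frame with one row per eye: `patient_id`, `eye_id`,
#'   `eye_side`, `fovea_x_mm`, `fovea_y_mm`, `va_letters`, `llva_letters`,
#'   `lld_letters`; the latent covariates are attached as attribute
#'   `"covariates"`.
#' @export
generate_outcomes <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "ga_cohort") || is.list(cohort$eyes))
  eyes <- cohort$eyes
  res <- config$grid[1]
  labels <- etdrs_labels(res, extent_mm = 3)
  thr <- config$area_threshold
  cell_mm2 <- (2 * 3 / res)^2

  cov <- t(vapply(eyes, function(e) {
    std_rora <- standardize_map(e$maps$RORA, resolution = res)
    std_pdr <- standardize_map(e$maps$PDR, resolution = res)
    rm_rora <- region_means(std_rora, labels)
    rm_pdr <- region_means(std_pdr, labels)
    extrafov <- sum(std_rora$grid >= thr & labels$labels != 1L,
                    na.rm = TRUE) * cell_mm2
    c(foveal_rora = unname(rm_rora["foveal"]),
      extrafoveal_rora_area = extrafov,
      parafoveal_pdr = mean(rm_pdr[2:5]))
  }, numeric(3)))

  set.seed(derive_seed(config$rng_seed, 0L, 4L))
  n <- length(eyes)
  eps_va <- stats::rnorm(n, 0, config$noise_sd_letters)
  eps_lld <- stats::rnorm(n, 0, config$noise_sd_letters)
  bva <- config$beta_va; blld <- config$beta_lld
  va <- clamp(bva$intercept_letters -
                bva$foveal_rora_coef * cov[, "foveal_rora"] -
                bva$extrafoveal_rora_area_coef * cov[, "extrafoveal_rora_area"] +
                eps_va, 0, 100)
  lld <- clamp(blld$intercept_letters +
                 blld$parafoveal_pdr_coef * cov[, "parafoveal_pdr"] +
                 eps_lld, 0, pmin(va, 100))
  llva <- va - lld

  out <- data.frame(
    patient_id = vapply(eyes, `[[`, character(1), "patient_id"),
    eye_id = vapply(eyes, `[[`, character(1), "eye_id"),
    eye_side = vapply(eyes, `[[`, character(1), "laterality"),
    fovea_x_mm = vapply(eyes, function(e) e$fovea_xy_mm[1], numeric(1)),
    fovea_y_mm = vapply(eyes, function(e) e$fovea_xy_mm[2], numeric(1)),
    va_letters = unname(va), llva_letters = unname(llva),
    lld_letters = unname(lld), row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "covariates") <- cov
  out
}

#' @export
print.ga_cohort <- function(x, ...) {
  cat(sprintf("<ga_cohort> %d eyes / %d patients, %d x %d raster over %.0f mm\n",
              length(x$eyes), length(unique(x$outcomes$patient_id)),
              x$config$grid[1], x$config$grid[2], x$config$field_mm))
  if (!is.null(x$outcomes))
    cat(sprintf("  median VA %.1f, LLVA %.1f, LLD %.1f letters\n",
                stats::median(x$outcomes$va_letters),
                stats::median(x$outcomes$llva_letters),
                stats::median(x$outcomes$lld_letters)))
  invisible(x)
}

#' Cohort median lesion areas
#'
#' Median thresholded area per feature across all eyes, the quantity the
#' generator defaults are calibrated against.
#'
#' @param cohort a `ga_cohort`.
#' @param threshold probability threshold.
#' @return named numeric vector (mm^2) over RPE_LOSS, PDR, HT, RORA.
#' @export
cohort_median_areas <- function(cohort, threshold = cohort$config$area_threshold) {
  feats <- c("RPE_LOSS", "PDR", "HT", "RORA")
  areas <- vapply(cohort$eyes, function(e)
    vapply(feats, function(f) lesion_area(e$maps[[f]], threshold), numeric(1)),
    numeric(4))
  apply(areas, 1, stats::median)
}
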
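test_that("identical configuration reproduces the cohort bit for bit", {
  cfg <- synth_config(n_patients = 6, grid = c(25, 25), rng_seed = 12)
  a <- simulate_ga_cohort(cfg)
  b <- simulate_ga_cohort(cfg)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$eyes[[1]]$maps$RPE_LOSS$grid, b$eyes[[1]]$maps$RPE_LOSS$grid)
  expect_identical(a$eyes[[3]]$maps$RORA$grid, b$eyes[[3]]$maps$RORA$grid)
})

test_that("a zero seed count yields empty lesions and zero RORA area", {
  cfg <- synth_config(n_patients = 3, grid = c(25, 25),
                      n_seeds_range = c(0, 0), noise_sd_letters = 0,
                      rng_seed = 2)
  co <- simulate_ga_cohort(cfg)
  for (e in co$eyes) {
    for (f in c("RPE_LOSS", "PDR", "HT", "RORA"))
      expect_true(all(e$maps[[f]]$grid == 0))
    expect_equal(lesion_area(e$maps$RORA), 0)
  }
  # no lesion, no noise: VA equals the intercept exactly
  expect_equal(co$outcomes$va_letters,
               rep(cfg$beta_va$intercept_letters, nrow(co$outcomes)))
})

test_that("cohort structure: two eyes at most, shared patient, derived RORA", {
  co <- tiny_cohort()
  counts <- table(co$outcomes$patient_id)
  expect_true(all(counts <= 2))
  expect_equal(sort(names(co$eyes)), sort(co$outcomes$eye_id))
  e <- co$eyes[[1]]
  expect_setequal(names(e$maps), c("RPE_LOSS", "PDR", "HT", "RORA"))
  expect_equal(e$maps$RORA$grid,
               pmin(e$maps$RPE_LOSS$grid, e$maps$PDR$grid, e$maps$HT$grid))
})

test_that("feature nesting: RORA area never exceeds PDR or RPE-loss area", {
  co <- tiny_cohort()
  for (e in co$eyes) {
    a_rora <- lesion_area(e$maps$RORA)
    expect_lte(a_rora, lesion_area(e$maps$PDR))
    expect_lte(a_rora, lesion_area(e$maps$RPE_LOSS))
  }
})

test_that("outcome identities hold on every generated row", {
  oc <- tiny_cohort()$outcomes
  expect_equal(oc$lld_letters, oc$va_letters - oc$llva_letters)
  expect_true(all(oc$llva_letters <= oc$va_letters))
  expect_true(all(oc$lld_letters >= 0))
  expect_true(all(oc$va_letters >= 0 & oc$va_letters <= 100))
})

test_that("the structure-function law is applied exactly without noise", {
  # handcrafted eye with constant probability 0.6 everywhere:
  # foveal RORA mean = 0.6, so va = 85 - 50 * 0.6 = 55 when the area
  # coefficient is zero and noise is off
  cfg <- synth_config(n_patients = 1, grid = c(25, 25),
                      beta_va = list(intercept_letters = 85,
                                     foveal_rora_coef = 50,
                                     extrafoveal_rora_area_coef = 0),
                      beta_lld = list(intercept_letters = 0,
                                      parafoveal_pdr_coef = 10),
                      noise_sd_letters = 0, rng_seed = 5)
  mk <- function(f) enface_map(matrix(0.6, 25, 25), f, laterality = "OD",
                               fovea_xy_mm = c(3, 3))
  eye <- list(maps = list(RPE_LOSS = mk("RPE_LOSS"), PDR = mk("PDR"),
                          HT = mk("HT"), RORA = mk("RORA")),
              fovea_xy_mm = c(3, 3), laterality = "OD",
              patient_id = "P001", eye_id = "P001_OD")
  fake <- structure(list(eyes = list(P001_OD = eye), config = cfg),
                    class = "ga_cohort")
  oc <- generate_outcomes(fake, cfg)
  expect_equal(oc$va_letters, 55)
  # lld = 0 + 10 * mean parafoveal PDR = 6, llva = va - lld
  expect_equal(oc$lld_letters, 6)
  expect_equal(oc$llva_letters, 49)
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(target_median_areas_mm2 = c(RPE_LOSS = -1,
                                                        PDR = 1, HT = 1,
                                                        RORA = 1)),
               "targets")
  expect_error(synth_config(beta_va = list(intercept_letters = 150,
                                           foveal_rora_coef = 1,
                                           extrafoveal_rora_area_coef = 0)),
               "intercept")
  expect_error(synth_config(frac_bilateral = 1.4))
  expect_error(synth_config(noise_sd_letters = -2))
})

test_that("per-eye generation is independent of cohort context", {
  cfg <- synth_config(n_patients = 4, grid = c(25, 25), rng_seed = 31)
  v1 <- generate_lesions(cfg, 3, burden = 1.2)
  v2 <- generate_lesions(cfg, 3, burden = 1.2)
  expect_identical(v1$RPE_LOSS$data, v2$RPE_LOSS$data)
  v3 <- generate_lesions(cfg, 4, burden = 1.2)
  expect_false(identical(v1$RPE_LOSS$data, v3$RPE_LOSS$data))
})
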
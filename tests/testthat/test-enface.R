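test_that("A-scan column reduction detects presence with >= threshold", {
  expect_equal(reduce_column(c(0, 0, 0)),
               list(probability = 0, binary = FALSE))
  expect_equal(reduce_column(c(0.2, 0.9, 0.1)),
               list(probability = 0.9, binary = TRUE))
  # strictly below the threshold stays absent even at the boundary
  expect_equal(reduce_column(c(0.49, 0.49)),
               list(probability = 0.49, binary = FALSE))
  expect_true(reduce_column(c(0.5, 0.1))$binary)
  expect_error(reduce_column(numeric(0)), "empty")
  expect_equal(reduce_column(c(0.2, 0.8), reduce = "mean")$probability, 0.5)
})

test_that("en-face projection matches a double-loop column-max oracle", {
  for (s in 1:5) {
    set.seed(s)
    nb <- sample(4:8, 1); na <- sample(4:8, 1); depth <- sample(3:10, 1)
    bscans <- lapply(seq_len(nb),
                     function(i) matrix(runif(depth * na), depth, na))
    vol <- seg_volume(bscans, feature = "PDR", min_bscans = 1)
    ef <- build_enface(vol)
    oracle <- matrix(0, nb, na)
    for (i in seq_len(nb)) for (j in seq_len(na))
      oracle[i, j] <- max(bscans[[i]][, j])
    expect_equal(ef$grid, oracle)
  }
})

test_that("volumes already at A-scan resolution pass through unchanged", {
  g <- matrix(runif(49 * 49), 49, 49)
  vol <- seg_volume(g, feature = "RPE_LOSS", fovea_xy_mm = c(3, 3))
  ef <- build_enface(vol)
  expect_identical(ef$grid, g)
  expect_equal(ef$spacing_mm, c(6 / 49, 6 / 49))
  expect_equal(ef$fovea_xy_mm, c(3, 3))
})

test_that("en-face maximum of a single synthetic blob sits at the blob centre", {
  # depth-resolved blob: per-b-scan masks whose column max is the 2-D kernel
  nb <- 31; na <- 31; depth <- 6
  centre <- c(10, 22)   # (b-scan, A-scan)
  kern <- outer((seq_len(nb) - centre[1])^2, (seq_len(na) - centre[2])^2, `+`)
  kern <- exp(-kern / 40)
  bscans <- lapply(seq_len(nb), function(i)
    t(vapply(seq_len(depth), function(d) kern[i, ] * (d / depth), numeric(na))))
  ef <- build_enface(seg_volume(bscans, feature = "HT", min_bscans = 1))
  expect_equal(which(ef$grid == max(ef$grid), arr.ind = TRUE)[1, ],
               c(row = centre[1], col = centre[2]))
})

test_that("RORA is the cell-wise minimum and commutes with binarisation", {
  mk <- function(v, f) enface_map(matrix(v, 1, 3), feature = f,
                                  laterality = "OD")
  r <- derive_rora(mk(c(0.9, 0.0, 0.5), "RPE_LOSS"),
                   mk(c(0.8, 0.7, 0.5), "PDR"),
                   mk(c(0.7, 0.9, 0.5), "HT"))
  expect_equal(r$grid[1, ], c(0.7, 0.0, 0.5))
  expect_equal(r$feature, "RORA")

  # brute-force equivalence on a 10 x 10 toy grid: binarised RORA area at
  # t = 0.5 equals the cell count where all three features reach 0.5
  set.seed(7)
  g <- replicate(3, matrix(runif(100), 10, 10), simplify = FALSE)
  maps <- Map(function(m, f) enface_map(m, feature = f, laterality = "OD"),
              g, c("RPE_LOSS", "PDR", "HT"))
  rora <- derive_rora(maps[[1]], maps[[2]], maps[[3]])
  n_and <- sum(g[[1]] >= 0.5 & g[[2]] >= 0.5 & g[[3]] >= 0.5)
  cell <- prod(rora$spacing_mm)
  expect_equal(lesion_area(rora, 0.5), n_and * cell)
})

test_that("RORA derivation is idempotent and validates geometry", {
  a <- random_enface(8, 8, "RPE_LOSS", seed = 3)
  a$feature <- "RORA"
  expect_equal(derive_rora(a, a, a)$grid, a$grid)
  b <- random_enface(8, 9, "PDR", seed = 4)
  expect_error(derive_rora(a, b, a), "geometry")
  c_os <- random_enface(8, 8, "HT", laterality = "OS", seed = 5)
  expect_error(derive_rora(a, a, c_os), "laterality")
})

test_that("lesion area counts cells proportionally", {
  full <- enface_map(matrix(1, 12, 12), "RPE_LOSS", laterality = "OD")
  expect_equal(lesion_area(full, 0.5), 36)
  empty <- enface_map(matrix(0, 12, 12), "RPE_LOSS", laterality = "OD")
  expect_equal(lesion_area(empty, 0.5), 0)
  half <- enface_map(rbind(matrix(1, 6, 12), matrix(0, 6, 12)),
                     "RPE_LOSS", laterality = "OD")
  expect_equal(lesion_area(half, 0.5), 18)
})

test_that("area is non-increasing in threshold and RORA never exceeds constituents", {
  for (s in 1:5) {
    maps <- lapply(c("RPE_LOSS", "PDR", "HT"),
                   function(f) random_enface(12, 12, f, seed = s * 11))
    rora <- derive_rora(maps[[1]], maps[[2]], maps[[3]])
    thresholds <- seq(0.1, 0.9, by = 0.1)
    for (m in c(maps, list(rora))) {
      areas <- vapply(thresholds, function(t) lesion_area(m, t), numeric(1))
      expect_true(all(diff(areas) <= 0))
    }
    for (t in thresholds)
      expect_lte(lesion_area(rora, t),
                 min(vapply(maps, function(m) lesion_area(m, t), numeric(1))))
  }
})

test_that("constructors reject invalid probabilities and geometry", {
  expect_error(enface_map(matrix(1.2, 3, 3), "PDR", laterality = "OD"),
               "\\[0, 1\\]")
  expect_error(enface_map(matrix(0.5, 3, 3), "PDR", laterality = "OD",
                          fovea_xy_mm = c(7, 3)), "outside")
  expect_error(seg_volume(matrix(0.5, 10, 49), "PDR"), "25")
})
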
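test_that("band_moments matches hand computation and brute-force oracle", {
  m <- band_moments(c(1, 2, 3))
  expect_equal(m$mean_dn, 2)
  expect_equal(m$sd, 1)
  expect_equal(m$cv, 0.5)
  set.seed(3)
  for (i in 1:20) {
    x <- rgamma(sample(10:5000, 1), shape = 2, scale = 1000)
    got <- band_moments(x)
    want <- oracle_moments(x)
    for (f in names(want)) expect_equal(got[[f]], want[[f]], tolerance = 1e-10)
  }
})

test_that("degenerate pixel arrays are flagged, not fabricated", {
  m <- band_moments(rep(7, 10))
  expect_equal(m$sd, 0)
  expect_equal(m$cv, 0)
  expect_true(is.na(m$skewness) && is.na(m$kurtosis))
  m0 <- band_moments(rep(0, 10))
  expect_true(is.na(m0$cv)) # zero mean: cv undefined
  expect_error(band_moments(c(1)), "at least 2")
  expect_error(band_moments(c(NA, NA, 1)), "at least 2")
})

test_that("masked pixels (non-finite, negative) are excluded and counted", {
  x <- c(1, 2, 3, NA, Inf, -5)
  m <- band_moments(x)
  expect_equal(m$n_pixels, 3)
  expect_equal(m$n_masked, 3)
  expect_equal(m$mean_dn, 2)
})

test_that("symmetric arrays have zero skewness", {
  set.seed(4)
  x <- runif(500, 100, 200)
  sym <- c(x, 2 * mean(x) - x) # mirror about the mean (stays positive)
  expect_equal(band_moments(sym)$skewness, 0, tolerance = 1e-6)
})

test_that("scale-free moments are gain-invariant; sd scales exactly", {
  set.seed(5)
  x <- rgamma(2000, 3, scale = 500)
  m1 <- band_moments(x)
  for (g in c(0.25, 2, 17.5)) {
    m2 <- band_moments(g * x)
    expect_equal(m2$cv, m1$cv, tolerance = 1e-12)
    expect_equal(m2$skewness, m1$skewness, tolerance = 1e-12)
    expect_equal(m2$kurtosis, m1$kurtosis, tolerance = 1e-12)
    expect_equal(m2$sd, g * m1$sd, tolerance = 1e-12)
  }
})

test_that("crop_to_roi crops all bands identically with half-open bounds", {
  set.seed(6)
  bands <- setNames(lapply(1:5, function(i) matrix(runif(100 * 100), 100)),
                    SPECTRAL_BANDS)
  img <- multispectral_image(bands, "Q1", 1, 2)
  full <- crop_to_roi(img, c(0, 100, 0, 100))
  expect_identical(full$bands, img$bands)
  sub <- crop_to_roi(img, c(10, 60, 10, 60))
  expect_true(all(vapply(sub$bands, function(b) all(dim(b) == 50), TRUE)))
  expect_identical(sub$bands$B450, img$bands$B450[11:60, 11:60])
  expect_equal(sub$quadrat_id, "Q1")
  expect_error(crop_to_roi(img, c(10, 10, 0, 50)), "zero-area")
  expect_error(crop_to_roi(img, c(0, 101, 0, 50)), "outside")
})

test_that("observation_moments averages per-band moments arithmetically", {
  set.seed(7)
  base <- matrix(rgamma(400, 2, scale = 100), 20)
  # bands as scaled copies: scale-free moments identical across bands
  gains <- c(1, 0.5, 2, 3, 1.5)
  bands <- setNames(lapply(gains, function(g) g * base), SPECTRAL_BANDS)
  om <- observation_moments(multispectral_image(bands, "Q1", 1, 2))
  bm <- band_moments(base)
  expect_equal(om$averaged$cv, bm$cv, tolerance = 1e-10)
  expect_equal(om$averaged$skewness, bm$skewness, tolerance = 1e-10)
  expect_equal(om$averaged$sd, mean(gains) * bm$sd, tolerance = 1e-10)
  expect_equal(om$per_band$cv, rep(bm$cv, 5), tolerance = 1e-10)
  # identical arrays: averaged equals single-band
  same <- setNames(lapply(1:5, function(i) base), SPECTRAL_BANDS)
  om2 <- observation_moments(multispectral_image(same, "Q1", 1, 2))
  expect_equal(om2$averaged$kurtosis, bm$kurtosis)
  # hand-checked mean of per-band cvs
  expect_equal(mean(om$per_band$cv), om$averaged$cv)
})

test_that("undefined band moments are excluded from averaging, not zero-filled", {
  set.seed(8)
  bands <- setNames(lapply(1:5, function(i) matrix(runif(100, 1, 9), 10)),
                    SPECTRAL_BANDS)
  bands$NIR840 <- matrix(5, 10, 10) # constant band
  om <- observation_moments(multispectral_image(bands, "Q1", 1, 2))
  expect_equal(om$averaged$skewness,
               mean(om$per_band$skewness[1:4]))
  expect_gt(om$averaged$n_undefined, 0)
})

test_that("height filter keeps <= 8 m inclusively and logs counts", {
  rec <- data.frame(height_m = c(2, 4, 6, 8), id = 1:4)
  expect_message(out <- filter_observations(rec), "kept 4 of 4")
  expect_equal(nrow(out), 4)
  rec2 <- data.frame(height_m = c(2, 9, 12, NA), id = 1:4)
  expect_warning(
    expect_message(out2 <- filter_observations(rec2), "kept 1 of 4"),
    "missing height"
  )
  expect_equal(out2$id, 1L)
  counts <- attr(out2, "filter_counts")
  expect_equal(unname(counts["rows_in"]),
               unname(counts["rows_kept"] + counts["rows_filtered"] +
                        counts["rows_missing_height"]))
  empty <- data.frame(height_m = numeric())
  expect_equal(nrow(suppressMessages(filter_observations(empty))), 0)
})

test_that("block_average computes exact k x k block means and trims remainders", {
  m <- matrix(1:16, 4, 4)
  b2 <- block_average(m, 2)
  expect_equal(b2, matrix(c(mean(m[1:2, 1:2]), mean(m[3:4, 1:2]),
                            mean(m[1:2, 3:4]), mean(m[3:4, 3:4])), 2))
  expect_identical(block_average(m, 1), m)
  m5 <- matrix(runif(35), 5, 7)
  b <- block_average(m5, 2) # trims to 4 x 6
  expect_equal(dim(b), c(2L, 3L))
  expect_equal(b[1, 1], mean(m5[1:2, 1:2]))
  expect_equal(mean(block_average(m5[1:4, 1:6], 2)), mean(m5[1:4, 1:6]))
  expect_error(block_average(matrix(1, 2, 2), 3), "smaller than")
})

test_that("block averaging never increases the coefficient of variation", {
  set.seed(9)
  for (i in 1:20) {
    m <- matrix(rgamma(96 * 96, 2, scale = 50), 96)
    cv0 <- band_moments(m)$cv
    for (k in 2:4) expect_lte(band_moments(block_average(m, k))$cv, cv0 + 1e-12)
  }
  # equality iff blocks are internally constant (population-variance cv;
  # the sample-sd version differs by the n/(n-1) factor at tiny n)
  pop_cv <- function(x) sqrt(mean((x - mean(x))^2)) / mean(x)
  const_blocks <- kronecker(matrix(runif(4, 1, 9), 2, 2), matrix(1, 2, 2))
  expect_equal(pop_cv(block_average(const_blocks, 2)), pop_cv(const_blocks),
               tolerance = 1e-12)
})
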
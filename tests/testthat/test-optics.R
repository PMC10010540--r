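# Thin-film interference physics and color rendering.

test_that("Fresnel amplitude coefficient matches the normal-incidence formula", {
  expect_identical(fresnel_amplitude(1.48, 1.48), 0)
  expect_identical(fresnel_amplitude(1.0, 1.0), 0)
  # hand-evaluated (1.0 - 1.48) / (1.0 + 1.48)
  expect_equal(fresnel_amplitude(1.0, 1.48), -0.1935483870967742,
               tolerance = 1e-12)
  expect_lt(abs(fresnel_amplitude(1.0, 2.5)), 1)
  # sign encodes the phase flip at a low-to-high interface
  expect_lt(fresnel_amplitude(1.0, 1.48), 0)
  expect_gt(fresnel_amplitude(1.48, 1.334), 0)
  expect_error(fresnel_amplitude(-1, 1.5), "positive")
  expect_error(fresnel_amplitude(1.5, 0), "positive")
})

test_that("two-beam reflectance hits its closed-form landmarks", {
  m <- optical_model()
  r1 <- fresnel_amplitude(m$n_air, m$n_lipid)
  r2 <- fresnel_amplitude(m$n_lipid, m$n_aqueous)
  # zero thickness: zero path difference, cosine term = +1
  expect_equal(thin_film_reflectance(0, 480, m), (r1 + r2)^2,
               tolerance = 1e-12)
  # quarter-wave thickness: cosine term = -1
  lam <- 550
  expect_equal(thin_film_reflectance(lam / (4 * m$n_lipid), lam, m),
               (r1 - r2)^2, tolerance = 1e-12)
  # frozen value from an independent numerical evaluation of the formula
  expect_equal(thin_film_reflectance(100, 550, m), 0.05966159701770367,
               tolerance = 1e-10)
  expect_error(thin_film_reflectance(-5, 550, m), ">= 0")
  expect_error(thin_film_reflectance(100, 900, m), "outside")
})

test_that("two-beam reflectance respects the energy bounds and thickness period", {
  m <- optical_model()
  r1 <- abs(fresnel_amplitude(m$n_air, m$n_lipid))
  r2 <- abs(fresnel_amplitude(m$n_lipid, m$n_aqueous))
  set.seed(42)
  d <- runif(200, 0, 600)
  for (lam in c(380, 550, 780)) {
    R <- thin_film_reflectance(d, lam, m)
    expect_true(all(R >= (r1 - r2)^2 - 1e-12))
    expect_true(all(R <= (r1 + r2)^2 + 1e-12))
    period <- lam / (2 * m$n_lipid)
    expect_equal(thin_film_reflectance(d + period, lam, m),
                 thin_film_reflectance(d, lam, m), tolerance = 1e-9)
  }
})

test_that("two-beam model tracks the truncated Airy summation", {
  m <- optical_model()
  # frozen 10-term Airy value at the reference point (independent
  # evaluation); the truncated series equals the closed form to 1e-15
  expect_equal(airy_reflectance(100, 550), 0.05851415960190285,
               tolerance = 1e-12)
  # the two interface coefficients are small, so the first-order model is
  # within a few percent of the full summation everywhere; worst case sits
  # at the reflectance minima where the missing (1 - r1^2) transmission
  # factor on the second beam matters most
  d <- seq(0, 500, by = 2.5)
  for (lam in c(420, 550, 700)) {
    R2 <- thin_film_reflectance(d, lam, m)
    Ra <- airy_reflectance(d, lam)
    expect_lt(max(abs(R2 - Ra) / Ra), 0.05)
  }
  expect_lt(abs(thin_film_reflectance(100, 550, m) -
                  airy_reflectance(100, 550)) / airy_reflectance(100, 550),
            0.02)
})

test_that("spectral color conversion is neutral for flat spectra and green for 550 nm light", {
  m <- optical_model()
  nl <- length(m$wavelengths)
  flat <- spectrum_to_srgb(rep(0.04, nl), m)
  expect_equal(max(flat) - min(flat), 0, tolerance = 1e-3)
  expect_identical(unname(spectrum_to_srgb(rep(0, nl), m)), c(0, 0, 0))
  narrow <- as.numeric(abs(m$wavelengths - 550) <= 10) * 0.05
  rgb <- spectrum_to_srgb(narrow, m)
  expect_gt(rgb["g"], rgb["r"])
  expect_gt(rgb["g"], rgb["b"])
  expect_true(all(flat >= 0 & flat <= 1))
  expect_error(spectrum_to_srgb(rep(0.1, nl - 1), m), "expected")
})

test_that("rendering equals the per-pixel composition of the scalar operations", {
  m <- optical_model()
  set.seed(7)
  vals <- matrix(runif(30, 0, 500), 6, 5)
  mask <- matrix(runif(30) < 0.3, 6, 5)
  tm <- thickness_map(vals, mask)
  img <- render_interference(tm, m, noise_seed = 3)
  for (i in 1:6) for (j in 1:5) {
    if (mask[i, j]) next
    R <- thin_film_reflectance(vals[i, j], m$wavelengths, m)
    expect_equal(as.numeric(img[i, j, ]),
                 unname(spectrum_to_srgb(R, m)), tolerance = 1e-12)
  }
  # masked pixels show the desaturated exposed-surface gray: all three
  # channels equal, darker than the film colors
  gray_px <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(gray_px))) {
    px <- img[gray_px[k, 1], gray_px[k, 2], ]
    expect_equal(max(px) - min(px), 0, tolerance = 1e-12)
  }
})

test_that("uniform thickness renders a constant image and a full rupture mask overrides it", {
  m <- optical_model()
  tm <- thickness_map(matrix(120, 8, 9))
  img <- render_interference(tm, m)
  for (k in 1:3) expect_equal(max(img[, , k]) - min(img[, , k]), 0,
                              tolerance = 1e-12)
  tm2 <- thickness_map(matrix(120, 8, 9), matrix(TRUE, 8, 9))
  img2 <- render_interference(tm2, m, noise_seed = 1)
  expect_true(all(abs(img2[, , 1] - img2[, , 2]) < 1e-12))
  expect_lt(mean(img2), mean(img))
  # determinism of the rupture texture
  img3 <- render_interference(tm2, m, noise_seed = 1)
  expect_identical(img2, img3)
})

test_that("optical model validates its physics and round-trips through config files", {
  expect_error(optical_model(n_lipid = -1), "positive")
  expect_error(optical_model(wavelengths = c(500, 400)), "increasing")
  expect_error(optical_model(wavelengths = c(300, 500)), "within")
  expect_error(optical_model(illuminant = rep(0, 81)), "not all zero")
  m <- optical_model()
  expect_gt(m$n_lipid, m$n_aqueous)
  expect_gt(m$n_aqueous, m$n_air)

  js <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_lipid = 1.5, gain = 8), js, auto_unbox = TRUE)
  mj <- read_optical_model(js)
  expect_equal(mj$n_lipid, 1.5)
  expect_equal(mj$gain, 8)
  ym <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_aqueous = 1.34, rupture_gray = 0.25), ym)
  my <- read_optical_model(ym)
  expect_equal(my$n_aqueous, 1.34)
  expect_equal(my$rupture_gray, 0.25)
})

test_that("PNG writing quantises to 8 bits and round-trips", {
  img <- array(runif(24), c(2, 4, 3))
  f <- tempfile(fileext = ".png")
  write_image_png(img, f)
  back <- read_image_png(f)
  expect_equal(dim(back), dim(img))
  expect_equal(back, round(img * 255) / 255, tolerance = 1e-9)
})
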
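# Spectral integration, CIELAB transform, color difference and sRGB
# rendering.

test_that("perfect diffuser maps to the white point and (100, 0, 0) exactly", {
  xyz <- spectrum_to_xyz(flat_spectrum(1), ctx420)
  expect_equal(unname(xyz), unname(ctx420$white_point))
  expect_equal(xyz[["Y"]], 100)
  expect_equal(unname(spectrum_to_lab(flat_spectrum(1), ctx420)),
               c(100, 0, 0), tolerance = 1e-12)
  expect_equal(unname(spectrum_to_xyz(flat_spectrum(0), ctx420)), c(0, 0, 0))
})

test_that("spectral integration is linear in reflectance", {
  expect_equal(unname(spectrum_to_xyz(flat_spectrum(0.18), ctx420)),
               unname(0.18 * ctx420$white_point), tolerance = 1e-12)
  set.seed(7)
  r <- runif(31, 0.1, 0.9)
  sp <- reflectance_spectrum(standard_axis()$wavelengths_nm, r)
  for (alpha in c(0.25, 0.5, 0.9)) {
    spa <- reflectance_spectrum(standard_axis()$wavelengths_nm, alpha * r)
    expect_equal(spectrum_to_xyz(spa, ctx420),
                 alpha * spectrum_to_xyz(sp, ctx420), tolerance = 1e-12)
  }
})

test_that("narrow spectra are rejected unless zero-extension is on", {
  sp <- reflectance_spectrum(seq(500, 700, 10), rep(0.5, 21))
  expect_error(spectrum_to_xyz(sp, ctx420), "narrower")
  ctx_z <- colorimetry_context(zero_extend = TRUE)
  expect_silent(spectrum_to_xyz(sp, ctx_z))
  ctx_full <- colorimetry_context(range_nm = c(380, 780), zero_extend = TRUE)
  expect_equal(unname(spectrum_to_lab(
    reflectance_spectrum(seq(420, 730, 10), rep(1, 32)), ctx_full))[1],
    100, tolerance = 5)  # truncated support loses little of the D65 ybar mass
})

test_that("CIELAB transform matches the closed form and its inverse", {
  wp <- ctx420$white_point
  expect_equal(unname(xyz_to_lab(wp, ctx420)), c(100, 0, 0))
  expect_equal(unname(xyz_to_lab(c(0, 0, 0), ctx420)), c(0, 0, 0))
  lab18 <- xyz_to_lab(0.18 * wp, ctx420)
  expect_equal(lab18[["L"]], 116 * 0.18^(1 / 3) - 16, tolerance = 1e-9)
  expect_equal(lab18[["a"]], 0, tolerance = 1e-9)
  set.seed(5)
  for (i in 1:25) {
    xyz <- runif(3, 0, 1.1) * wp
    expect_equal(unname(lab_to_xyz(xyz_to_lab(xyz, ctx420), ctx420)),
                 unname(xyz), tolerance = 1e-9)
  }
  expect_error(xyz_to_lab(c(-5, 50, 50), ctx420), "negative")
})

test_that("CIELAB transform agrees with the grDevices reference implementation", {
  # feed our transform the exact white point convertColor uses, so the
  # comparison isolates the Lab math from the choice of D65 tabulation
  wp_chr <- grDevices::convertColor(matrix(c(100, 0, 0), 1), from = "Lab",
                                    to = "XYZ") * 100
  ctx_ref <- ctx420
  ctx_ref$white_point <- as.vector(wp_chr)
  set.seed(9)
  for (i in 1:100) {
    xyz <- runif(3, 0.05, 1) * ctx_ref$white_point
    ours <- xyz_to_lab(xyz, ctx_ref)
    ref <- as.vector(convertColor(matrix(xyz / 100, 1), from = "XYZ", to = "Lab"))
    expect_equal(unname(ours), ref, tolerance = 0.05)
  }
})

test_that("CIE76 delta E is the Euclidean metric on Lab", {
  expect_equal(delta_e(c(50, 10, 10), c(50, 10, 10)), 0)
  expect_equal(delta_e(c(50, 0, 0), c(53, 0, 4)), 5)
  set.seed(3)
  for (i in 1:50) {
    x <- rnorm(3, 50, 20); y <- rnorm(3, 50, 20); z <- rnorm(3, 50, 20)
    expect_gte(delta_e(x, y), 0)
    expect_equal(delta_e(x, y), delta_e(y, x))
    expect_lte(delta_e(x, z), delta_e(x, y) + delta_e(y, z) + 1e-12)
  }
})

test_that("CIEDE2000 variant behaves sanely without replacing the default", {
  expect_equal(delta_e(c(50, 2, -3), c(50, 2, -3), method = "ciede2000"), 0)
  expect_equal(delta_e(c(50, 10, 5), c(55, -3, 9), method = "ciede2000"),
               delta_e(c(55, -3, 9), c(50, 10, 5), method = "ciede2000"))
  # pure lightness pair near L = 50: SL is ~1, so dE2000 ~ dL
  expect_equal(delta_e(c(50, 0, 0), c(51, 0, 0), method = "ciede2000"), 1,
               tolerance = 1e-2)
})

test_that("vectorised cube conversion equals the per-pixel loop", {
  set.seed(21)
  nb <- 31; nr <- 4; nc <- 3
  vals <- array(runif(nb * nr * nc, 0.05, 0.95), c(nb, nr, nc))
  cube <- reflectance_cube(vals, standard_axis())
  lab <- cube_to_lab(cube, ctx420)
  for (r in 1:nr) for (c in 1:nc) {
    ref <- spectrum_to_lab(reflectance_spectrum(standard_axis()$wavelengths_nm,
                                                vals[, r, c]), ctx420)
    expect_equal(c(lab$L[r, c], lab$a[r, c], lab$b[r, c]), unname(ref),
                 tolerance = 1e-9)
  }
  # uniform cube -> every pixel identical; two-region cube -> exact boundary
  u <- cube_to_lab(uniform_cube(1), ctx420)
  expect_equal(unique(as.vector(u$L)), 100)
  expect_equal(unique(as.vector(u$a)), 0)
  two <- array(0.2, c(31, 2, 4)); two[, , 3:4] <- 0.6
  lab2 <- cube_to_lab(reflectance_cube(two, standard_axis()), ctx420)
  expect_equal(length(unique(as.vector(lab2$L))), 2)
})

test_that("L* is strictly increasing in neutral reflectance level", {
  levels <- seq(0.05, 1, 0.05)
  L <- vapply(levels, function(l) spectrum_to_lab(flat_spectrum(l), ctx420)[["L"]],
              numeric(1))
  expect_true(all(diff(L) > 0))
})

test_that("sRGB rendering hits the white, black and gray anchors", {
  expect_equal(lab_to_srgb(c(100, 0, 0)), c(255L, 255L, 255L))
  expect_equal(lab_to_srgb(c(0, 0, 0)), c(0L, 0L, 0L))
  gray <- lab_to_srgb(c(116 * 0.214^(1 / 3) - 16, 0, 0))
  expect_equal(gray[1], gray[2])
  expect_equal(gray[2], gray[3])
  # against the grDevices sRGB reference
  for (lab in list(c(60, 20, 15), c(35, -10, 40), c(80, 5, -20))) {
    ours <- lab_to_srgb(lab) / 255
    ref <- as.vector(convertColor(matrix(lab, 1), from = "Lab", to = "sRGB"))
    expect_equal(ours, ref, tolerance = 0.02)
  }
})

test_that("PNG rendering writes a valid file", {
  img <- const_lab(65, 15, 12, nr = 8, nc = 8)
  path <- withr::local_tempfile(fileext = ".png")
  clip <- lab_to_srgb_png(img, path)
  expect_true(file.exists(path))
  expect_equal(clip, 0)
  back <- png::readPNG(path)
  expect_equal(dim(back), c(8, 8, 3))
  expect_equal(length(unique(as.vector(back))), 3) # one constant per channel
})
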
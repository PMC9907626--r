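# Landmark handling, ROI resolution and per-ROI color statistics.

test_that("fixture landmark backend is deterministic and bounds-checked", {
  shp <- c(200, 200)
  lm <- face_template_landmarks(shp)
  out1 <- detect_landmarks(shp, lm)
  out2 <- detect_landmarks(shp, lm)
  expect_identical(out1$points, lm$points)
  expect_identical(out1$points, out2$points)
  bad <- lm$points; bad$row[5] <- 500
  expect_error(detect_landmarks(shp, landmark_set(bad)), "bounds")
  expect_error(landmark_set(lm$points[-1, ]), "68")
})

test_that("ROI resolution centers on the anchor and clamps at edges", {
  pts <- face_template_landmarks(c(300, 300))$points
  # force the anchor triple to a known centroid
  def <- roi_definition("Right_Cheek", c(3, 32, 37))
  pts$row[c(3, 32, 37)] <- 100; pts$col[c(3, 32, 37)] <- 100
  lm <- landmark_set(pts, image_shape = c(300, 300))
  rect <- resolve_roi(lm, def)
  expect_equal(c(rect$r0, rect$c0, rect$h, rect$w), c(63, 63, 75, 75))
  # near the corner: clamped to start at (0, 0)
  pts$row[c(3, 32, 37)] <- 10; pts$col[c(3, 32, 37)] <- 10
  rect2 <- resolve_roi(landmark_set(pts, image_shape = c(300, 300)), def)
  expect_equal(c(rect2$r0, rect2$c0), c(0, 0))
  # 1 x 1 ROI
  pts$row[c(3, 32, 37)] <- 5; pts$col[c(3, 32, 37)] <- 7
  r3 <- resolve_roi(landmark_set(pts, image_shape = c(300, 300)),
                    roi_definition("tiny", c(3, 32, 37), c(1, 1)))
  expect_equal(c(r3$r0, r3$c0, r3$h, r3$w), c(5, 7, 1, 1))
  expect_error(resolve_roi(lm, def, image_shape = c(50, 50)), "smaller")
})

test_that("ROI resolution is translation-equivariant", {
  set.seed(13)
  base <- face_template_landmarks(c(256, 256))$points
  def <- right_cheek_roi(c(21, 21))
  r0 <- resolve_roi(landmark_set(base, image_shape = c(400, 400)), def)
  for (shift in list(c(5, 7), c(40, 13), c(0, 60))) {
    moved <- base
    moved$row <- moved$row + shift[1]
    moved$col <- moved$col + shift[2]
    r1 <- resolve_roi(landmark_set(moved, image_shape = c(400, 400)), def)
    expect_equal(c(r1$r0, r1$c0), c(r0$r0 + shift[1], r0$c0 + shift[2]))
  }
})

test_that("ROI statistics match direct computation over the same pixels", {
  # uniform region: SD 0, single occupied bin
  img <- const_lab(60, 10, 15)
  rect <- structure(list(name = "Right_Cheek", r0 = 10L, c0 = 10L,
                         h = 75L, w = 75L), class = "roi_rect")
  st <- extract_roi_stats(img, rect)
  expect_equal(st$n_pixels, 5625)
  expect_equal(st$channels$L$mean, 60)
  expect_equal(st$channels$a$sd, 0)
  expect_equal(sum(st$channels$b$hist$counts > 0), 1)
  # two-valued region: mean 15, sample SD ~ 5.0004
  L <- matrix(10, 100, 100); L[, 51:100] <- 20
  img2 <- lab_image(L, L * 0, L * 0)
  rect2 <- structure(list(name = "x", r0 = 12L, c0 = 12L, h = 75L, w = 75L),
                     class = "roi_rect")
  st2 <- extract_roi_stats(img2, rect2)
  v <- as.vector(L[13:87, 13:87])
  expect_equal(st2$channels$L$mean, mean(v))
  expect_equal(st2$channels$L$sd, sd(v))
  # hand-checked value for an exact half/half split (even width)
  L3 <- cbind(matrix(10, 75, 38), matrix(20, 75, 38))
  img3 <- lab_image(L3, L3 * 0, L3 * 0)
  rect3 <- structure(list(name = "x", r0 = 0L, c0 = 0L, h = 75L, w = 76L),
                     class = "roi_rect")
  st3 <- extract_roi_stats(img3, rect3)
  expect_equal(st3$channels$L$mean, 15)
  expect_equal(st3$channels$L$sd, sqrt(25 * 5700 / 5699), tolerance = 1e-9)
  expect_error(extract_roi_stats(img, structure(list(name = "x", r0 = 90L,
                                                     c0 = 0L, h = 75L, w = 75L),
                                                class = "roi_rect")),
               "outside")
})

test_that("ROI mean equals a naive per-pixel recomputation from the cube", {
  set.seed(31)
  vals <- array(runif(31 * 40 * 40, 0.1, 0.8), c(31, 40, 40))
  cube <- reflectance_cube(vals, standard_axis())
  lab <- cube_to_lab(cube, ctx420)
  rect <- structure(list(name = "x", r0 = 5L, c0 = 9L, h = 12L, w = 10L),
                    class = "roi_rect")
  st <- extract_roi_stats(lab, rect)
  acc <- c(0, 0, 0)
  for (r in 6:17) for (c in 10:19)
    acc <- acc + spectrum_to_lab(reflectance_spectrum(
      standard_axis()$wavelengths_nm, vals[, r, c]), ctx420)
  expect_equal(c(st$channels$L$mean, st$channels$a$mean, st$channels$b$mean),
               unname(acc / 120), tolerance = 1e-9)
})

test_that("histogram counts conserve the pixel count, also with shared edges", {
  set.seed(17)
  img1 <- lab_image(matrix(rnorm(2500, 60), 50), matrix(rnorm(2500, 10), 50),
                    matrix(rnorm(2500, 15), 50))
  img2 <- lab_image(matrix(rnorm(2500, 63), 50), matrix(rnorm(2500, 8), 50),
                    matrix(rnorm(2500, 19), 50))
  rect <- structure(list(name = "x", r0 = 2L, c0 = 3L, h = 40L, w = 30L),
                    class = "roi_rect")
  br <- shared_breaks(img1, rect, img2, rect)
  for (img in list(img1, img2)) {
    st <- extract_roi_stats(img, rect, breaks = br)
    for (ch in c("L", "a", "b")) {
      expect_equal(sum(st$channels[[ch]]$hist$counts), 1200)
      expect_equal(st$channels[[ch]]$hist$edges, br[[ch]])
    }
  }
})

test_that("before/after differences give the signed shift and its delta E", {
  img0 <- const_lab(50, 0, 0)
  img1 <- const_lab(53, 0, 4)
  rect <- structure(list(name = "Right_Cheek", r0 = 0L, c0 = 0L, h = 20L, w = 20L),
                    class = "roi_rect")
  s0 <- extract_roi_stats(img0, rect); s1 <- extract_roi_stats(img1, rect)
  d <- roi_difference(s0, s1)
  expect_equal(c(d$dL, d$da, d$db, d$dE), c(3, 0, 4, 5))
  d0 <- roi_difference(s0, s0)
  expect_equal(c(d0$dL, d0$da, d0$db, d0$dE), c(0, 0, 0, 0))
  # darkening product: negative dL
  dark <- extract_roi_stats(const_lab(47, 0, 0), rect)
  expect_lt(roi_difference(s0, dark)$dL, 0)
  other <- rect; other$name <- "Left_Cheek"
  expect_error(roi_difference(s0, extract_roi_stats(img1, other)), "mismatch")
})

test_that("pixel pitch converts ROI geometry to micrometres", {
  expect_equal(pixel_pitch(12, 75), 160)
  expect_equal(pixel_pitch(1, 1), 1000)
  expect_error(pixel_pitch(12, 0), "positive")
})
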
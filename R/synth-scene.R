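# Synthetic scenes: a schematic ellipse-based face with a stored 68-point
# landmark layout, reflectance datacubes with multiplicative band noise,
# optional inverse-rendering to raw counts for calibration testing, and
# complete simulated studies with known ground truth.

#' Schematic 68-point facial landmark layout
#'
#' Places the standard 68-point annotation (jaw 1--17, brows 18--27, nose
#' 28--36, eyes 37--48, mouth 49--68) on an ellipse-based face template
#' scaled to the image, optionally jittered (emulating operator-to-operator
#' placement variation).
#'
#' @param image_shape `c(rows, cols)`.
#' @param jitter_sd Gaussian jitter SD in pixels (applied per point when the
#'   RNG is seeded by the caller).
#' @return A [landmark_set()] with `source = "fixture"`.
#' @export
face_template_landmarks <- function(image_shape, jitter_sd = 0) {
  nr <- image_shape[1]; nc <- image_shape[2]
  cr <- 0.52 * nr; cc <- 0.50 * nc
  a <- 0.40 * nr; b <- 0.36 * nc
  pts <- matrix(NA_real_, 68, 2)
  t <- seq(pi, 2 * pi, length.out = 17)             # jaw, image-left to image-right
  pts[1:17, ] <- cbind(cr - a * sin(t), cc + b * cos(t))
  pts[18:22, ] <- cbind(rep(cr - 0.55 * a, 5), cc + b * seq(-0.75, -0.15, length.out = 5))
  pts[23:27, ] <- cbind(rep(cr - 0.55 * a, 5), cc + b * seq(0.15, 0.75, length.out = 5))
  pts[28:31, ] <- cbind(cr + a * seq(-0.38, 0.05, length.out = 4), rep(cc, 4))
  pts[32:36, ] <- cbind(rep(cr + 0.16 * a, 5), cc + b * seq(-0.18, 0.18, length.out = 5))
  eye <- function(ecr, ecc) {
    ang <- seq(0, 2 * pi, length.out = 7)[1:6]
    cbind(ecr - 0.045 * a * sin(ang), ecc + 0.14 * b * cos(ang))
  }
  pts[37:42, ] <- eye(cr - 0.30 * a, cc - 0.40 * b)
  pts[43:48, ] <- eye(cr - 0.30 * a, cc + 0.40 * b)
  ang <- seq(0, 2 * pi, length.out = 13)[1:12]
  pts[49:60, ] <- cbind(cr + 0.55 * a - 0.10 * a * sin(ang), cc + 0.22 * b * cos(ang))
  ang <- seq(0, 2 * pi, length.out = 9)[1:8]
  pts[61:68, ] <- cbind(cr + 0.55 * a - 0.05 * a * sin(ang), cc + 0.12 * b * cos(ang))
  if (jitter_sd > 0) pts <- pts + matrix(rnorm(136, 0, jitter_sd), 68, 2)
  pts[, 1] <- pmin(pmax(pts[, 1], 0), nr - 1)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), nc - 1)
  landmark_set(data.frame(index = 1:68, row = round(pts[, 1]),
                          col = round(pts[, 2])),
               image_shape = image_shape, source = "fixture")
}

#' Synthetic scene description
#'
#' @param shape cube shape `c(bands, rows, cols)`; 31 x 256 x 256 is the
#'   desk-scale default.
#' @param params a [skin_spectrum_params()] for the face region.
#' @param effect optional [product_effect()] applied to the face spectrum.
#' @param noise a [noise_model()]; multiplicative Gaussian band noise.
#' @param seed integer seed; fixed seed gives an identical cube.
#' @param landmark_jitter_sd landmark placement jitter SD in pixels.
#' @param background_reflectance flat reflectance outside the face.
#' @param axis a [spectral_axis()] matching `shape[1]`.
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(shape = c(31, 256, 256),
                            params = skin_spectrum_params(),
                            effect = NULL, noise = noise_model(0.02),
                            seed = 1L, landmark_jitter_sd = 0,
                            background_reflectance = 0.05,
                            axis = NULL) {
  if (is.null(axis)) {
    axis <- if (shape[1] == 31) standard_axis()
    else spectral_axis(seq(420, 730, length.out = shape[1]))
  }
  structure(list(shape = as.integer(shape), params = params, effect = effect,
                 noise = noise, seed = as.integer(seed),
                 landmark_jitter_sd = landmark_jitter_sd,
                 background_reflectance = background_reflectance, axis = axis),
            class = "synthetic_scene")
}

face_mask <- function(nr, nc) {
  cr <- 0.52 * nr; cc <- 0.50 * nc
  a <- 0.46 * nr; b <- 0.42 * nc
  rows <- matrix(seq_len(nr) - 1, nr, nc)
  cols <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  ((rows - cr) / a)^2 + ((cols - cc) / b)^2 <= 1
}

#' Render a synthetic scene to a reflectance cube
#'
#' The face region carries the (optionally product-modulated) skin spectrum
#' with independent multiplicative Gaussian noise per band and pixel; the
#' background is a flat gray. Deterministic under a fixed seed.
#'
#' @param scene a [synthetic_scene()].
#' @param ctx a [colorimetry_context()] (used when the scene has a product
#'   effect to solve).
#' @return List with `cube` (a [reflectance_cube()]), `landmarks`
#'   (a [landmark_set()]), and `spectrum` (the noise-free face spectrum,
#'   the scene's ground truth).
#' @export
make_datacube <- function(scene, ctx = colorimetry_context()) {
  nb <- scene$shape[1]; nr <- scene$shape[2]; nc <- scene$shape[3]
  spec <- make_skin_spectrum(scene$params, scene$axis)
  if (!is.null(scene$effect)) spec <- apply_product_effect(spec, scene$effect, ctx)
  mask <- face_mask(nr, nc)
  npix_face <- sum(mask)
  res <- with_seed(scene$seed, {
    lm <- face_template_landmarks(c(nr, nc), scene$landmark_jitter_sd)
    eps <- matrix(rnorm(nb * npix_face), nb, npix_face)
    list(lm = lm, eps = eps)
  })
  vals <- array(scene$background_reflectance, c(nb, nr, nc))
  flat <- matrix(vals, nrow = nb)
  flat[, which(mask)] <- spec$reflectance + band_sigma(scene$noise, spec$reflectance) * res$eps
  flat[flat < 0] <- 0
  flat[flat > 1.2] <- 1.2
  cube <- reflectance_cube(array(flat, c(nb, nr, nc)), scene$axis,
                           provenance = list(synthetic = TRUE, seed = scene$seed,
                                             noise = scene$noise$fractional_sigma))
  list(cube = cube, landmarks = res$lm, spectrum = spec, mask = mask)
}

#' Inverse-render a reflectance cube to raw counts plus calibration frames
#'
#' Produces a raw acquisition (sample counts, dark, flat, white-standard
#' cube) that [compute_reflectance()] maps back to the input cube:
#' `S = D + flat * R / white_reflectance * (W - D)`. By default counts are
#' left unquantized so the round trip is exact; `quantize = TRUE` rounds to
#' integers, emulating a real CCD at the cost of quantization error.
#'
#' @param cube a [reflectance_cube()].
#' @param white_level white-standard count level.
#' @param dark_level dark count level.
#' @param flat_gradient peak-to-peak relative amplitude of a smooth
#'   synthetic flat-field gain pattern (0 for a uniform flat).
#' @param quantize round counts to integers.
#' @return List with `raw_cube` (3-D array) and `calib`
#'   (a [calibration_set()]).
#' @export
make_raw_acquisition <- function(cube, white_level = 4000, dark_level = 100,
                                 flat_gradient = 0, quantize = FALSE) {
  d <- dim(cube$values)
  nr <- d[2]; nc <- d[3]
  flat <- matrix(1, nr, nc)
  if (flat_gradient > 0) {
    g <- outer(seq(-1, 1, length.out = nr), seq(-1, 1, length.out = nc),
               function(r, c) 1 + flat_gradient / 2 * cos(pi * r / 2) * cos(pi * c / 2))
    flat <- g / mean(g)
  }
  dark <- matrix(dark_level, nr, nc)
  wr <- 0.99
  white <- array(NA_real_, d)
  raw <- array(NA_real_, d)
  for (b in seq_len(d[1])) {
    wb <- dark + flat * (white_level - dark_level)
    sb <- dark + flat * (cube$values[b, , ] / wr) * (white_level - dark_level)
    if (quantize) { wb <- round(wb); sb <- round(sb) }
    white[b, , ] <- wb
    raw[b, , ] <- sb
  }
  list(raw_cube = raw,
       calib = calibration_set(dark, flat, white, white_reflectance = wr))
}

#' Simulate a complete repeatability/reproducibility study
#'
#' Generates one acquisition per model x product x time point x repetition
#' x operator cell of the design (imager rows only), runs the analysis
#' pipeline on each before/after pair, and returns the effect records next
#' to the injected ground truth. Reproducibility (operator) variation is
#' modeled as landmark placement jitter; repeatability (repetition)
#' variation as a small per-model baseline color drift between repetitions.
#'
#' With `spatial = TRUE` every acquisition is rendered as a full datacube
#' and analysed through landmark detection, ROI resolution and per-pixel
#' color statistics. With `spatial = FALSE` the ROI mean is simulated
#' directly at the spectrum level (band noise scaled by `1/sqrt(n_pixels)`),
#' which is statistically equivalent for a homogeneous ROI and much faster.
#'
#' @param design a [study_design()] (imager acquisitions are simulated).
#' @param effects named list of per-product target shifts `c(dL, da, db)`;
#'   defaults emulate three foundations with small / strong-lightening /
#'   intermediate coverage.
#' @param seed master seed; all per-acquisition seeds derive from it.
#' @param shape cube shape for spatial mode.
#' @param roi a [roi_definition()]; its size must fit the cube.
#' @param noise a [noise_model()].
#' @param operator_jitter_sd landmark jitter SD in pixels (reproducibility).
#' @param repetition_drift_sd SD (CIELAB units) of the per-model baseline
#'   drift between repetitions (repeatability).
#' @param effect_sd SD (CIELAB units, scalar or length 3) of the
#'   model-by-product scatter of the realised product effect about its
#'   target -- the same product does not shift every model's color equally.
#'   This component persists across repetitions and operators (it is a
#'   property of the model-product pairing), so it dominates the group SDs
#'   (0.7--1.5 range typical of foundation screening panels at the default
#'   1.0) without degrading the repetition correlation.
#' @param repetition_effect_sd SD of the additional, repetition-specific
#'   scatter of the realised effect (amount applied, product batch, skin
#'   state on the day); this is what separates the two repetitions of the
#'   same test. Default 0.25.
#' @param positioning_sd fast-path stand-in for ROI-selection systematics:
#'   SD (CIELAB units) of an independent per-acquisition shift of the
#'   measured ROI-mean color caused by re-positioning and landmark jitter
#'   over a spatially varying face. Default 0.12. In spatial mode the same
#'   physics is rendered explicitly via `pattern_amp` + landmark jitter.
#' @param pattern_amp spatial mode only: amplitudes `c(gain, tilt)` of a
#'   smooth across-face variation of the skin spectrum (relative gain and
#'   red-blue tilt), which converts landmark jitter into genuine
#'   ROI-selection color shifts. Default `c(0.015, 0.03)`.
#' @param spatial render full cubes (`TRUE`) or simulate ROI means at the
#'   spectrum level (`FALSE`).
#' @param out_dir optional directory; spatial cubes are written there in the
#'   single-file container format.
#' @param ctx a [colorimetry_context()].
#' @return List of class `hsi_simulated_study`: `effects` (tidy data frame
#'   of effect records), `ground_truth` (injected per-product shifts and
#'   per-model/repetition drifts), `design`, `config`.
#' @export
simulate_study <- function(design = study_design(),
                           effects = list(A = c(0.3, -0.2, 1.1),
                                          B = c(3.9, -2.1, -1.2),
                                          C = c(1.5, -1.5, -2.0)),
                           seed = 1L, shape = c(31, 96, 96),
                           roi = right_cheek_roi(c(20, 20)),
                           noise = noise_model(0.02),
                           operator_jitter_sd = 3,
                           repetition_drift_sd = 0.3,
                           effect_sd = 1.0,
                           repetition_effect_sd = 0.25,
                           positioning_sd = 0.12,
                           pattern_amp = c(0.015, 0.03),
                           spatial = TRUE, out_dir = NULL,
                           ctx = colorimetry_context()) {
  stopifnot(inherits(design, "study_design"))
  if (!setequal(names(effects), design$products))
    stop_validation("effects must be named by the design's products")
  axis <- if (shape[1] == 31) standard_axis()
  else spectral_axis(seq(420, 730, length.out = shape[1]))
  models <- sprintf("M%02d", seq_len(design$n_models))
  n_roi_px <- prod(roi$size_px)
  derive_seed <- function(...) {
    as.integer((sum(c(seed, ...) * c(7919, 104729, 1299709, 15485863,
                                     32452843, 49979687)[seq_len(length(c(seed, ...)))]) %%
                  2147483587) + 1)
  }
  drifts <- list()
  rows <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  for (mi in seq_along(models)) {
    base_spec <- make_skin_spectrum(skin_spectrum_params(seed = derive_seed(mi)),
                                    axis)
    for (r in seq_len(design$n_repetitions)) {
      drift <- with_seed(derive_seed(mi, r, 1),
                         rnorm(3, 0, repetition_drift_sd))
      drifts[[paste(models[mi], r, sep = "/")]] <- drift
      t0_spec <- apply_product_effect(base_spec, drift, ctx)
      for (p in design$products) {
        pi_ <- match(p, design$products)
        persistent <- with_seed(derive_seed(mi, pi_, 977),
                                rnorm(3, 0, rep(effect_sd, length.out = 3)))
        per_rep <- with_seed(derive_seed(mi, r, pi_, 97),
                             rnorm(3, 0, rep(repetition_effect_sd, length.out = 3)))
        realised <- effects[[p]] + persistent + per_rep
        timm_spec <- apply_product_effect(t0_spec, realised, ctx)
        for (o in design$operators) {
          meas <- lapply(list(T0 = t0_spec, Timm = timm_spec), function(sp) {
            acq_seed <- derive_seed(mi, r, match(p, design$products),
                                    match(o, design$operators),
                                    if (identical(sp, t0_spec)) 1 else 2)
            if (spatial) {
              scene <- synthetic_scene(shape = shape,
                                       noise = noise, seed = acq_seed,
                                       landmark_jitter_sd = operator_jitter_sd,
                                       axis = axis)
              sc <- render_scene_with_spectrum(scene, sp, pattern_amp = pattern_amp)
              if (!is.null(out_dir)) {
                fn <- file.path(out_dir, sprintf("%s_%s_rep%d_%s_%s.rds.gz",
                                                 models[mi], p, r, o,
                                                 if (identical(sp, t0_spec)) "T0" else "Timm"))
                write_cube(sc$cube, fn)
              }
              lab <- cube_to_lab(sc$cube, ctx)
              lm <- detect_landmarks(lab, sc$landmarks)
              rect <- resolve_roi(lm, roi, lab$shape)
              st <- extract_roi_stats(lab, rect)
              c(st$channels$L$mean, st$channels$a$mean, st$channels$b$mean)
            } else {
              draws <- with_seed(acq_seed, {
                list(eps = rnorm(length(sp$reflectance)),
                     pos = rnorm(3, 0, positioning_sd))
              })
              noisy <- sp$reflectance + band_sigma(noise, sp$reflectance) /
                sqrt(n_roi_px) * draws$eps
              spectrum_to_lab(reflectance_spectrum(sp$wavelengths_nm,
                                                   pmin(pmax(noisy, 0), 1.2)),
                              ctx) + draws$pos
            }
          })
          rows[[length(rows) + 1]] <- data.frame(
            model = models[mi], product = p, repetition = r, operator = o,
            instrument = "HSI",
            dL = meas$Timm[1] - meas$T0[1],
            da = meas$Timm[2] - meas$T0[2],
            db = meas$Timm[3] - meas$T0[3],
            dE = sqrt(sum((meas$Timm - meas$T0)^2)))
        }
      }
    }
  }
  eff <- do.call(rbind, rows)
  rownames(eff) <- NULL
  structure(list(effects = eff,
                 ground_truth = list(product_effects = effects, drifts = drifts),
                 design = design,
                 config = list(seed = seed, shape = shape,
                               roi = roi$name, roi_size = roi$size_px,
                               noise = noise$fractional_sigma,
                               operator_jitter_sd = operator_jitter_sd,
                               repetition_drift_sd = repetition_drift_sd,
                               effect_sd = effect_sd,
                               spatial = spatial)),
            class = "hsi_simulated_study")
}

# internal: render a scene with an explicit face spectrum and an optional
# smooth across-face variation (relative gain + red-blue spectral tilt)
render_scene_with_spectrum <- function(scene, spectrum, pattern_amp = c(0, 0)) {
  nb <- scene$shape[1]; nr <- scene$shape[2]; nc <- scene$shape[3]
  mask <- face_mask(nr, nc)
  npix_face <- sum(mask)
  res <- with_seed(scene$seed, {
    lm <- face_template_landmarks(c(nr, nc), scene$landmark_jitter_sd)
    eps <- matrix(rnorm(nb * npix_face), nb, npix_face)
    list(lm = lm, eps = eps)
  })
  flat <- matrix(scene$background_reflectance, nb, nr * nc)
  face_vals <- spectrum$reflectance +
    band_sigma(scene$noise, spectrum$reflectance) * res$eps
  if (any(pattern_amp > 0)) {
    rows <- (which(mask) - 1) %% nr
    cols <- (which(mask) - 1) %/% nr
    g1 <- pattern_amp[1] * (0.6 * sin(2 * pi * rows / nr + 0.7) +
                              0.4 * cos(2 * pi * cols / nc + 1.3))
    g2 <- pattern_amp[2] * (0.5 * sin(2 * pi * rows / nr + 2.1) -
                              0.5 * cos(2 * pi * cols / nc + 0.4))
    tilt <- (spectrum$wavelengths_nm - 575) / 155
    face_vals <- face_vals * (1 + rep(g1, each = nb) +
                                tilt * rep(g2, each = nb))
  }
  flat[, which(mask)] <- face_vals
  flat[flat < 0] <- 0
  flat[flat > 1.2] <- 1.2
  cube <- reflectance_cube(array(flat, c(nb, nr, nc)), scene$axis,
                           provenance = list(synthetic = TRUE, seed = scene$seed))
  list(cube = cube, landmarks = res$lm, spectrum = spectrum, mask = mask)
}
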
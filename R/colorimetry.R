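# Reflectance -> CIE XYZ -> L*a*b* under D65 with the CIE 1964 10 degree
# observer. Tables ship with the package (10 nm CIE tabulations) and are
# interpolated once onto the 5 nm working grid of the integration range.

cie_table <- function(name) {
  key <- paste0("table_", name)
  if (!is.null(.hsi_cache[[key]])) return(.hsi_cache[[key]])
  path <- system.file("extdata", name, package = "hsicolor", mustWork = TRUE)
  tab <- read.csv(path)
  .hsi_cache[[key]] <- tab
  tab
}

#' Colorimetry context: observer, illuminant and integration range
#'
#' Fixes everything needed to turn a reflectance spectrum into tristimulus
#' values: the CIE 1964 10 degree observer color matching functions, the D65
#' relative spectral power distribution, a 5 nm integration grid over
#' `range_nm`, and the normalisation constant
#' `k = 100 / sum(S * ybar * dl)` computed over the same range so that a
#' perfect diffuser maps to `Y = 100` exactly.
#'
#' The default range is the imager's own spectral support, 420--730 nm.
#' A 380--780 nm range suits full-range spectroradiometer spectra; with
#' `zero_extend = TRUE`, spectra narrower than the range are zero-padded
#' instead of rejected.
#'
#' @param range_nm integration range `c(min, max)` in nm.
#' @param step_nm integration step (default 5 nm).
#' @param zero_extend pad missing spectral support with zeros instead of
#'   raising an error.
#' @return An object of class `colorimetry_context` with fields `grid`
#'   (wavelengths), `cmf` (3 x n matrix), `illuminant`, `k`, `white_point`
#'   (`Xn, Yn = 100, Zn`).
#' @export
colorimetry_context <- function(range_nm = c(420, 730), step_nm = 5,
                                zero_extend = FALSE) {
  cmf <- cie_table("cie1964_10deg_cmf_10nm.csv")
  ill <- cie_table("illuminant_d65_10nm.csv")
  support <- range(cmf$wavelength_nm)
  if (range_nm[1] < support[1] || range_nm[2] > support[2] ||
      range_nm[1] >= range_nm[2])
    stop_validation("integration range must lie within the tabulated support %g--%g nm",
                    support[1], support[2])
  grid <- seq(range_nm[1], range_nm[2], by = step_nm)
  xb <- approx(cmf$wavelength_nm, cmf$xbar, grid)$y
  yb <- approx(cmf$wavelength_nm, cmf$ybar, grid)$y
  zb <- approx(cmf$wavelength_nm, cmf$zbar, grid)$y
  S <- approx(ill$wavelength_nm, ill$power, grid)$y
  k <- 100 / sum(S * yb)
  wp <- c(X = k * sum(S * xb), Y = 100, Z = k * sum(S * zb))
  structure(list(grid = grid, step_nm = step_nm,
                 cmf = rbind(x = xb, y = yb, z = zb),
                 illuminant = S, k = k, white_point = wp,
                 range_nm = range_nm, zero_extend = zero_extend,
                 observer = "CIE 1964 10deg", illuminant_name = "D65"),
            class = "colorimetry_context")
}

#' @export
print.colorimetry_context <- function(x, ...) {
  cat(sprintf("<colorimetry_context> %s / %s, %g--%g nm @ %g nm, white point (%.3f, %.1f, %.3f)\n",
              x$observer, x$illuminant_name, x$range_nm[1], x$range_nm[2],
              x$step_nm, x$white_point[1], x$white_point[2], x$white_point[3]))
  invisible(x)
}

# Linear-interpolation matrix mapping band samples at `wl` onto `grid`.
# Band values are treated as point samples at band centers (no FWHM
# deconvolution); outside the band support rows are zero (only permitted
# when zero-extension is on).
resample_matrix <- function(wl, grid, zero_extend = FALSE) {
  if (!zero_extend && (min(wl) > grid[1] + 1e-9 || max(wl) < grid[length(grid)] - 1e-9))
    stop_validation(paste0(
      "spectrum support %.1f--%.1f nm is narrower than the integration range ",
      "%.1f--%.1f nm; truncate the range or enable zero_extend"),
      min(wl), max(wl), grid[1], grid[length(grid)])
  A <- matrix(0, nrow = length(grid), ncol = length(wl))
  for (i in seq_along(grid)) {
    g <- grid[i]
    if (g < min(wl) || g > max(wl)) next
    j <- findInterval(g, wl, rightmost.closed = TRUE)
    if (j == length(wl)) { A[i, j] <- 1; next }
    t <- (g - wl[j]) / (wl[j + 1] - wl[j])
    A[i, j] <- 1 - t
    A[i, j + 1] <- t
  }
  A
}

#' Tristimulus values of a reflectance spectrum
#'
#' Resamples the spectrum linearly to the context's 5 nm grid and integrates
#' `X = k * sum(R * S * xbar * dl)` (and likewise Y, Z).
#'
#' @param spectrum a [reflectance_spectrum()].
#' @param ctx a [colorimetry_context()].
#' @return Named numeric vector `c(X, Y, Z)`; a perfect diffuser returns the
#'   context white point with `Y = 100`.
#' @export
spectrum_to_xyz <- function(spectrum, ctx = colorimetry_context()) {
  A <- resample_matrix(spectrum$wavelengths_nm, ctx$grid, ctx$zero_extend)
  r <- as.vector(A %*% spectrum$reflectance)
  xyz <- ctx$k * as.vector(ctx$cmf %*% (ctx$illuminant * r))
  names(xyz) <- c("X", "Y", "Z")
  xyz
}

# CIELAB companding function and inverse
lab_f <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
}
lab_f_inv <- function(ft) {
  delta <- 6 / 29
  ifelse(ft > delta, ft^3, 3 * delta^2 * (ft - 4 / 29))
}

#' CIE L*a*b* from tristimulus values
#'
#' Standard CIELAB transform relative to the context white point, with the
#' linear-segment branch of `f` below `(6/29)^3`.
#'
#' @param xyz numeric `c(X, Y, Z)` (or a 3-row matrix of columns).
#' @param ctx a [colorimetry_context()] supplying the white point.
#' @return Named vector `c(L, a, b)` (or 3-row matrix).
#' @export
xyz_to_lab <- function(xyz, ctx = colorimetry_context()) {
  wp <- ctx$white_point
  if (is.matrix(xyz)) {
    if (nrow(xyz) != 3L) stop_structural("xyz matrix must have 3 rows")
    if (min(xyz) < -1e-9) stop_validation("negative tristimulus value")
    fx <- lab_f(xyz[1, ] / wp[1]); fy <- lab_f(xyz[2, ] / wp[2]); fz <- lab_f(xyz[3, ] / wp[3])
    return(rbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz)))
  }
  if (any(xyz < -1e-9)) stop_validation("negative tristimulus value")
  fx <- lab_f(xyz[[1]] / wp[[1]]); fy <- lab_f(xyz[[2]] / wp[[2]])
  fz <- lab_f(xyz[[3]] / wp[[3]])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' @rdname xyz_to_lab
#' @param lab numeric `c(L, a, b)`.
#' @export
lab_to_xyz <- function(lab, ctx = colorimetry_context()) {
  wp <- ctx$white_point
  fy <- (lab[[1]] + 16) / 116
  fx <- fy + lab[[2]] / 500
  fz <- fy - lab[[3]] / 200
  xyz <- c(X = wp[[1]] * lab_f_inv(fx), Y = wp[[2]] * lab_f_inv(fy),
           Z = wp[[3]] * lab_f_inv(fz))
  xyz
}

#' Reflectance spectrum straight to L*a*b*
#'
#' @inheritParams spectrum_to_xyz
#' @return Named vector `c(L, a, b)`.
#' @export
spectrum_to_lab <- function(spectrum, ctx = colorimetry_context()) {
  xyz_to_lab(spectrum_to_xyz(spectrum, ctx), ctx)
}

#' Color difference between two L*a*b* colors
#'
#' Default is the CIE76 Euclidean distance
#' `sqrt(dL^2 + da^2 + db^2)`. The CIEDE2000 formula is available behind
#' `method = "ciede2000"` but is never the default.
#'
#' @param c1,c2 numeric `c(L, a, b)`.
#' @param method `"cie76"` (default) or `"ciede2000"`.
#' @return Non-negative scalar.
#' @export
delta_e <- function(c1, c2, method = c("cie76", "ciede2000")) {
  method <- match.arg(method)
  if (method == "cie76") return(sqrt(sum((as.numeric(c1) - as.numeric(c2))^2)))
  delta_e2000(as.numeric(c1), as.numeric(c2))
}

# CIEDE2000 (kL = kC = kH = 1)
delta_e2000 <- function(lab1, lab2) {
  L1 <- lab1[1]; a1 <- lab1[2]; b1 <- lab1[3]
  L2 <- lab2[1]; a2 <- lab2[2]; b2 <- lab2[3]
  C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1; a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)
  h1p <- if (C1p == 0) 0 else (atan2(b1, a1p) * 180 / pi) %% 360
  h2p <- if (C2p == 0) 0 else (atan2(b2, a2p) * 180 / pi) %% 360
  dLp <- L2 - L1
  dCp <- C2p - C1p
  dhp <- if (C1p * C2p == 0) 0 else {
    d <- h2p - h1p
    if (abs(d) <= 180) d else if (d > 180) d - 360 else d + 360
  }
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp * pi / 360)
  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hbp <- if (C1p * C2p == 0) h1p + h2p else {
    d <- abs(h1p - h2p); s <- h1p + h2p
    if (d <= 180) s / 2 else if (s < 360) (s + 360) / 2 else (s - 360) / 2
  }
  T <- 1 - 0.17 * cos((hbp - 30) * pi / 180) + 0.24 * cos(2 * hbp * pi / 180) +
    0.32 * cos((3 * hbp + 6) * pi / 180) - 0.20 * cos((4 * hbp - 63) * pi / 180)
  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * T
  RT <- -sin(2 * dtheta * pi / 180) * RC
  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
         RT * (dCp / SC) * (dHp / SH))
}

#' Per-pixel L*a*b* image
#'
#' Container for the three CIELAB planes of an image.
#'
#' @param L,a,b numeric matrices of equal shape.
#' @param context_id identifier of the colorimetry context used.
#' @return An object of class `lab_image`.
#' @export
lab_image <- function(L, a, b, context_id = "D65/1964-10deg") {
  if (!identical(dim(L), dim(a)) || !identical(dim(L), dim(b)))
    stop_structural("L, a, b planes must share one shape")
  if (any(!is.finite(L)) || any(!is.finite(a)) || any(!is.finite(b)))
    stop_validation("lab_image planes must be finite")
  structure(list(L = L, a = a, b = b, shape = dim(L), context_id = context_id),
            class = "lab_image")
}

#' @export
print.lab_image <- function(x, ...) {
  cat(sprintf("<lab_image> %d x %d pixels (%s), L* range %.1f--%.1f\n",
              x$shape[1], x$shape[2], x$context_id, min(x$L), max(x$L)))
  invisible(x)
}

#' Convert a reflectance cube to a per-pixel L*a*b* image
#'
#' Vectorised application of [spectrum_to_xyz()] and [xyz_to_lab()] to every
#' pixel: the band-to-grid resampling and the spectral integration compose
#' into one `3 x bands` weight matrix applied to the unfolded cube, so the
#' result is identical (to floating tolerance) to looping over pixels.
#'
#' @param cube a [reflectance_cube()].
#' @param ctx a [colorimetry_context()]; the cube axis must cover its range.
#' @return A [lab_image()].
#' @export
cube_to_lab <- function(cube, ctx = colorimetry_context()) {
  d <- dim(cube$values)
  A <- resample_matrix(cube$axis$wavelengths_nm, ctx$grid, ctx$zero_extend)
  W <- ctx$k * (sweep(ctx$cmf, 2, ctx$illuminant, `*`) %*% A) # 3 x bands
  flat <- matrix(cube$values, nrow = d[1])                     # bands x npix
  xyz <- W %*% flat                                            # 3 x npix
  lab <- xyz_to_lab(pmax(xyz, 0), ctx)
  lab_image(matrix(lab[1, ], d[2], d[3]),
            matrix(lab[2, ], d[2], d[3]),
            matrix(lab[3, ], d[2], d[3]),
            context_id = sprintf("%s/%s %g-%g nm", ctx$illuminant_name,
                                 ctx$observer, ctx$range_nm[1], ctx$range_nm[2]))
}
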
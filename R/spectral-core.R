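# Datacube data model and the calibration chain: raw CCD counts -> dark
# subtraction -> flat-field correction -> white-standard normalisation ->
# fractional reflectance per voxel.

#' Spectral axis of a band-sequential acquisition
#'
#' Describes the band centers (nm) and the tunable-filter bandwidth used for
#' an acquisition. The standard full-range sequence covers 420--730 nm in 31
#' bands at the 32 nm bandwidth setting.
#'
#' @param wavelengths_nm numeric vector of band centers in nanometres;
#'   strictly increasing, all within \[420, 730\].
#' @param bandwidth_fwhm_nm filter bandwidth (FWHM, nm); one of 10, 18, 32.
#' @return An object of class `spectral_axis`.
#' @export
#' @examples
#' standard_axis()
spectral_axis <- function(wavelengths_nm, bandwidth_fwhm_nm = 32) {
  wl <- as.numeric(wavelengths_nm)
  if (length(wl) < 1L) stop_validation("spectral axis needs at least one band")
  if (any(!is.finite(wl))) stop_validation("non-finite wavelength in axis")
  if (any(diff(wl) <= 0)) stop_validation("wavelengths must be strictly increasing")
  if (min(wl) < 420 || max(wl) > 730)
    stop_validation("wavelengths must lie within [420, 730] nm (got %.1f--%.1f)",
                    min(wl), max(wl))
  if (!bandwidth_fwhm_nm %in% c(10, 18, 32))
    stop_validation("bandwidth_fwhm_nm must be one of 10, 18, 32")
  structure(list(wavelengths_nm = wl, bandwidth_fwhm_nm = bandwidth_fwhm_nm),
            class = "spectral_axis")
}

#' @rdname spectral_axis
#' @export
standard_axis <- function() {
  spectral_axis(seq(420, 730, length.out = 31), bandwidth_fwhm_nm = 32)
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %d bands, %.1f--%.1f nm, FWHM %g nm\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), x$bandwidth_fwhm_nm))
  invisible(x)
}

#' Reflectance datacube
#'
#' A three-dimensional voxel grid of fractional reflectance, indexed
#' `[band, row, col]`, together with its spectral axis and calibration
#' provenance. Pixel coordinates are 0-based, row-major, origin top-left.
#'
#' @param values numeric 3-D array `[band, row, col]` of fractional
#'   reflectance; non-negative.
#' @param axis a [spectral_axis()] whose length equals `dim(values)[1]`.
#' @param provenance named list of calibration/configuration identifiers.
#' @param ceiling upper clamp applied during calibration (values above it were
#'   clipped); stored for validation.
#' @return An object of class `reflectance_cube`.
#' @export
reflectance_cube <- function(values, axis, provenance = list(), ceiling = 1.2) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_structural("cube values must be a 3-D array [band, row, col]")
  if (dim(values)[1] != length(axis$wavelengths_nm))
    stop_structural("band count (%d) does not match axis length (%d)",
                    dim(values)[1], length(axis$wavelengths_nm))
  if (any(!is.finite(values))) stop_validation("cube contains non-finite values")
  if (min(values) < 0) stop_validation("cube contains negative reflectance")
  if (max(values) > ceiling + 1e-12)
    stop_validation("cube exceeds clamp ceiling %.3f", ceiling)
  structure(list(values = values, axis = axis, provenance = provenance,
                 ceiling = ceiling),
            class = "reflectance_cube")
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$values)
  vc <- voxel_count(x)
  cat(sprintf("<reflectance_cube> %d x %d x %d (band x row x col), %s voxels (%d Mvox)\n",
              d[1], d[2], d[3], format(vc$voxels, big.mark = ","), vc$megavoxels))
  invisible(x)
}

#' Reflectance spectrum
#'
#' @param wavelengths_nm band centers (nm), strictly increasing.
#' @param reflectance fractional reflectance values, same length.
#' @param sigma optional per-band fractional (1-sigma) uncertainty.
#' @param ceiling maximum admissible reflectance (clamp ceiling).
#' @return An object of class `reflectance_spectrum`.
#' @export
reflectance_spectrum <- function(wavelengths_nm, reflectance, sigma = NULL,
                                 ceiling = 1.2) {
  wl <- as.numeric(wavelengths_nm); r <- as.numeric(reflectance)
  if (length(wl) != length(r))
    stop_structural("wavelengths and reflectance lengths differ (%d vs %d)",
                    length(wl), length(r))
  if (any(diff(wl) <= 0)) stop_format("wavelengths must be strictly increasing")
  if (any(!is.finite(r)) || min(r) < 0 || max(r) > ceiling + 1e-12)
    stop_validation("reflectance must lie in [0, %.3f]", ceiling)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(r)) stop_structural("sigma length mismatch")
    if (any(sigma < 0)) stop_validation("sigma must be non-negative")
  }
  structure(list(wavelengths_nm = wl, reflectance = r, sigma = sigma),
            class = "reflectance_spectrum")
}

#' Dark-count subtraction
#'
#' Subtracts the CCD dark frame from a raw frame. Pixels where the dark
#' exceeds the raw counts are clamped to zero (counts are physical); a
#' warning reports how many pixels were clamped.
#'
#' @param counts matrix of raw CCD counts (non-negative).
#' @param dark matrix of dark counts, same shape.
#' @return Matrix of dark-corrected counts, `max(counts - dark, 0)`.
#' @export
dark_correct <- function(counts, dark) {
  if (!identical(dim(counts), dim(dark)))
    stop_structural("frame shape %s does not match dark shape %s",
                    paste(dim(counts), collapse = "x"),
                    paste(dim(dark), collapse = "x"))
  out <- counts - dark
  n_neg <- sum(out < 0)
  if (n_neg > 0) {
    warning(sprintf("dark_correct: clamped %d negative pixel(s) to 0", n_neg),
            call. = FALSE)
    out[out < 0] <- 0
  }
  out
}

#' Flat-field correction
#'
#' Divides a frame by the (gain-normalised) flat field, correcting
#' pixel-to-pixel non-uniformity of the CCD response.
#'
#' @param frame matrix of counts.
#' @param flat matrix of unitless gains, strictly positive, same shape.
#' @return `frame / flat`, elementwise.
#' @export
flat_correct <- function(frame, flat) {
  if (!identical(dim(frame), dim(flat)))
    stop_structural("frame shape does not match flat shape")
  if (any(flat <= 0))
    stop_validation("flat field contains %d non-positive value(s)", sum(flat <= 0))
  frame / flat
}

#' Normalise a flat field to unit mean gain
#'
#' Applied on ingest so that flat-field division is gain-neutral.
#' @param flat matrix of raw flat-field response.
#' @return Matrix with mean exactly 1.
#' @export
normalize_flat <- function(flat) {
  if (any(flat <= 0)) stop_validation("flat field must be strictly positive")
  flat / mean(flat)
}

#' Calibration frame set
#'
#' Bundles the dark frame, flat field, and the white-standard cube used to
#' convert raw counts to reflectance. The flat is normalised to mean 1 on
#' ingest. The flat may be a single matrix (applied to every band) or a
#' 3-D array with one gain frame per band.
#'
#' @param dark matrix of dark counts.
#' @param flat matrix (or `[band, row, col]` array) of flat-field gains.
#' @param white_cube 3-D array `[band, row, col]` of white-standard counts.
#' @param white_reflectance known reflectance of the white standard
#'   (default 0.99 for a 99% standard).
#' @param average_white if `TRUE` and `white_cube` has a 4th replicate
#'   dimension, replicate captures are averaged (off by default).
#' @return An object of class `calibration_set`.
#' @export
calibration_set <- function(dark, flat, white_cube, white_reflectance = 0.99,
                            average_white = FALSE) {
  if (length(dim(white_cube)) == 4L) {
    if (!average_white)
      stop_validation("white_cube has replicate captures; set average_white = TRUE to average them")
    white_cube <- apply(white_cube, 1:3, mean)
  }
  if (!is.array(white_cube) || length(dim(white_cube)) != 3L)
    stop_structural("white_cube must be a 3-D array [band, row, col]")
  shp <- dim(white_cube)[2:3]
  if (!identical(dim(dark), shp))
    stop_structural("dark shape does not match white cube spatial shape")
  per_band_flat <- is.array(flat) && length(dim(flat)) == 3L
  if (per_band_flat) {
    if (!identical(dim(flat), dim(white_cube)))
      stop_structural("per-band flat shape does not match white cube")
    for (b in seq_len(dim(flat)[1])) flat[b, , ] <- normalize_flat(flat[b, , ])
  } else {
    if (!identical(dim(flat), shp))
      stop_structural("flat shape does not match white cube spatial shape")
    flat <- normalize_flat(flat)
  }
  if (!is_scalar_number(white_reflectance) || white_reflectance <= 0 ||
      white_reflectance > 1)
    stop_validation("white_reflectance must be a fraction in (0, 1]")
  structure(list(dark = dark, flat = flat, white_cube = white_cube,
                 white_reflectance = white_reflectance,
                 per_band_flat = per_band_flat),
            class = "calibration_set")
}

#' Convert a raw band-sequential acquisition to a reflectance cube
#'
#' Per voxel, the reflectance is
#' `R = white_reflectance * (S - D) / (W - D)` where `S` are the sample
#' counts, `D` the dark counts and `W` the white-standard counts, with `S`
#' and `W` flat-field corrected after dark subtraction. Values are clamped
#' to `[0, ceiling]`; the number of clipped voxels is recorded in the
#' provenance.
#'
#' @param raw_cube 3-D array `[band, row, col]` of raw sample counts.
#' @param calib a [calibration_set()].
#' @param axis a [spectral_axis()]; defaults to [standard_axis()] when the
#'   cube has 31 bands.
#' @param ceiling reflectance clamp ceiling (default 1.2, above the 99%
#'   standard so that specular/noise excursions survive for uncertainty
#'   analysis).
#' @return A [reflectance_cube()].
#' @export
compute_reflectance <- function(raw_cube, calib, axis = NULL, ceiling = 1.2) {
  if (!is.array(raw_cube) || length(dim(raw_cube)) != 3L)
    stop_structural("raw_cube must be a 3-D array [band, row, col]")
  if (!identical(dim(raw_cube), dim(calib$white_cube)))
    stop_structural("raw cube shape %s does not match white cube shape %s",
                    paste(dim(raw_cube), collapse = "x"),
                    paste(dim(calib$white_cube), collapse = "x"))
  nb <- dim(raw_cube)[1]
  if (is.null(axis)) {
    if (nb == 31L) axis <- standard_axis()
    else stop_validation("axis must be supplied for a %d-band cube", nb)
  }
  if (length(axis$wavelengths_nm) != nb)
    stop_structural("axis length %d does not match band count %d",
                    length(axis$wavelengths_nm), nb)

  out <- array(NA_real_, dim(raw_cube))
  n_clipped <- 0L
  n_clamped_dark <- 0L
  for (b in seq_len(nb)) {
    flat_b <- if (calib$per_band_flat) calib$flat[b, , ] else calib$flat
    s <- raw_cube[b, , ] - calib$dark
    n_clamped_dark <- n_clamped_dark + sum(s < 0)
    s[s < 0] <- 0
    s <- s / flat_b
    w <- (calib$white_cube[b, , ] - calib$dark) / flat_b
    bad <- which(w <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop_calibration(
        "white minus dark is non-positive at band %d (%.1f nm), pixel (row %d, col %d)",
        b, axis$wavelengths_nm[b], bad[1, 1] - 1L, bad[1, 2] - 1L)
    r <- calib$white_reflectance * s / w
    n_clipped <- n_clipped + sum(r > ceiling)
    r[r > ceiling] <- ceiling
    out[b, , ] <- r
  }
  if (n_clamped_dark > 0)
    hsi_log("compute_reflectance: %d sample voxel(s) below dark, clamped to 0",
            n_clamped_dark)
  reflectance_cube(out, axis,
                   provenance = list(white_reflectance = calib$white_reflectance,
                                     clip_ceiling = ceiling,
                                     n_clipped = n_clipped,
                                     n_below_dark = n_clamped_dark),
                   ceiling = ceiling)
}

#' Voxel count and megavoxel rounding of a cube
#'
#' @param cube a [reflectance_cube()].
#' @return List with `voxels` (bands x rows x cols) and `megavoxels`
#'   (`round(voxels / 1e6)`). The standard full-frame sequence,
#'   31 x 2016 x 2016, gives 126 megavoxels.
#' @export
voxel_count <- function(cube) {
  d <- dim(cube$values)
  n <- prod(d)
  list(voxels = n, megavoxels = round(n / 1e6))
}

#' Mean reflectance spectrum over a pixel mask
#'
#' @param cube a [reflectance_cube()].
#' @param mask logical matrix (rows x cols) selecting pixels, or a two-column
#'   matrix of 0-based `(row, col)` indices. `NULL` selects all pixels.
#' @param with_sigma if `TRUE`, attach the per-band standard error of the
#'   mean (sample SD / sqrt(n)).
#' @return A [reflectance_spectrum()].
#' @export
mean_spectrum <- function(cube, mask = NULL, with_sigma = FALSE) {
  d <- dim(cube$values)
  if (is.null(mask)) {
    idx <- seq_len(d[2] * d[3])
  } else if (is.logical(mask)) {
    if (!identical(dim(mask), d[2:3]))
      stop_structural("mask shape does not match cube spatial shape")
    idx <- which(mask)
  } else {
    mask <- as.matrix(mask)
    if (ncol(mask) != 2L) stop_structural("index mask must have two columns (row, col)")
    if (any(mask < 0) || any(mask[, 1] >= d[2]) || any(mask[, 2] >= d[3]))
      stop_validation("mask indices outside cube bounds")
    idx <- (mask[, 1] + 1L) + (mask[, 2]) * d[2]
  }
  if (length(idx) == 0L) stop_validation("mask selects no pixels")
  flat <- matrix(cube$values, nrow = d[1])[, idx, drop = FALSE]
  m <- rowMeans(flat)
  sig <- NULL
  if (with_sigma) {
    n <- length(idx)
    sig <- if (n > 1) apply(flat, 1, sd) / sqrt(n) else rep(0, d[1])
  }
  reflectance_spectrum(cube$axis$wavelengths_nm, m, sigma = sig,
                       ceiling = cube$ceiling)
}
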
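# L*a*b* -> sRGB rendering for visual inspection. sRGB is defined with a
# D65 white, and the L*a*b* values here are already D65-relative, so the
# render maps Lab -> XYZ (sRGB D65 white) -> linear RGB -> gamma, with no
# chromatic adaptation. Out-of-gamut channels are clipped and counted.

srgb_matrix <- function() {
  matrix(c(3.2404542, -1.5371385, -0.4985314,
           -0.9692660, 1.8760108, 0.0415560,
           0.0556434, -0.2040259, 1.0572252),
         nrow = 3, byrow = TRUE)
}

srgb_white <- c(X = 95.047, Y = 100, Z = 108.883)

srgb_gamma <- function(c) {
  ifelse(c <= 0.0031308, 12.92 * c, 1.055 * c^(1 / 2.4) - 0.055)
}

#' Render a L*a*b* image (or color) to sRGB
#'
#' @param image a [lab_image()], or a numeric `c(L, a, b)` triple.
#' @return For an image, an `rows x cols x 3` array in `[0, 1]` with an
#'   attribute `clipped_fraction`; for a triple, an integer `c(R, G, B)` in
#'   0--255.
#' @export
lab_to_srgb <- function(image) {
  if (is.numeric(image) && length(image) == 3) {
    rgb <- lab_to_srgb_core(matrix(image, nrow = 3))
    return(as.integer(round(pmin(pmax(rgb$rgb, 0), 1) * 255)))
  }
  stopifnot(inherits(image, "lab_image"))
  lab <- rbind(as.vector(image$L), as.vector(image$a), as.vector(image$b))
  res <- lab_to_srgb_core(lab)
  out <- array(0, c(image$shape, 3))
  for (ch in 1:3) out[, , ch] <- matrix(pmin(pmax(res$rgb[ch, ], 0), 1),
                                        image$shape[1], image$shape[2])
  attr(out, "clipped_fraction") <- res$clipped_fraction
  out
}

lab_to_srgb_core <- function(lab) {
  fy <- (lab[1, ] + 16) / 116
  fx <- fy + lab[2, ] / 500
  fz <- fy - lab[3, ] / 200
  xyz <- rbind(srgb_white[1] * lab_f_inv(fx),
               srgb_white[2] * lab_f_inv(fy),
               srgb_white[3] * lab_f_inv(fz)) / 100
  lin <- srgb_matrix() %*% xyz
  clipped <- mean(lin < 0 | lin > 1)
  lin <- pmin(pmax(lin, 0), 1)
  list(rgb = srgb_gamma(lin), clipped_fraction = clipped)
}

#' Write a L*a*b* image to an 8-bit sRGB PNG file
#'
#' @param image a [lab_image()].
#' @param path output file path.
#' @return Invisibly, the fraction of pixels with at least one clipped
#'   (out-of-gamut) channel.
#' @export
lab_to_srgb_png <- function(image, path) {
  rgb <- lab_to_srgb(image)
  clip <- attr(rgb, "clipped_fraction")
  if (clip > 0) hsi_log("lab_to_srgb_png: %.2f%% of channel values clipped", 100 * clip)
  ok <- tryCatch({ png::writePNG(rgb, target = path); TRUE },
                 error = function(e) stop_structural("cannot write PNG to '%s': %s",
                                                     path, conditionMessage(e)))
  invisible(clip)
}
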
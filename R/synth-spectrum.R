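# Synthetic skin-like reflectance spectra and product-induced color shifts.
# The spectral model is phenomenological, not biophysical: a low blue-green
# baseline, a melanin-like monotone rise toward the red, and two
# hemoglobin-like absorption dips near 545 and 575 nm -- enough structure to
# land in the skin-tone region of CIELAB and to respond realistically to
# smooth spectral modulations.

#' Parameters of a synthetic skin reflectance spectrum
#'
#' With `seed` given, parameters are drawn once (uniformly within realistic
#' ranges) to emulate between-model variation; without it, the stated
#' defaults are used. Reflectance units are fractions.
#'
#' @param seed optional integer; per-model parameter draw.
#' @param baseline blue-green reflectance floor.
#' @param slope amplitude of the monotone melanin-like rise toward 730 nm.
#' @param dip545,dip575 depths of the hemoglobin-like dips at 545/575 nm.
#' @return An object of class `skin_spectrum_params`.
#' @export
skin_spectrum_params <- function(seed = NULL, baseline = 0.22, slope = 0.32,
                                 dip545 = 0.06, dip575 = 0.05) {
  if (!is.null(seed)) {
    p <- with_seed(seed, list(baseline = runif(1, 0.16, 0.28),
                              slope = runif(1, 0.26, 0.38),
                              dip545 = runif(1, 0.04, 0.08),
                              dip575 = runif(1, 0.03, 0.07)))
    baseline <- p$baseline; slope <- p$slope
    dip545 <- p$dip545; dip575 <- p$dip575
  }
  if (baseline <= 0 || slope < 0 || dip545 < 0 || dip575 < 0)
    stop_validation("invalid skin spectrum parameters")
  structure(list(baseline = baseline, slope = slope, dip545 = dip545,
                 dip575 = dip575, seed = seed),
            class = "skin_spectrum_params")
}

#' Generate a synthetic skin reflectance spectrum
#'
#' @param params a [skin_spectrum_params()].
#' @param axis a [spectral_axis()].
#' @return A [reflectance_spectrum()] on the axis, smooth and strictly
#'   inside (0, 1).
#' @export
make_skin_spectrum <- function(params = skin_spectrum_params(),
                               axis = standard_axis()) {
  wl <- axis$wavelengths_nm
  r <- params$baseline +
    params$slope / (1 + exp(-(wl - 585) / 28)) -
    params$dip545 * exp(-0.5 * ((wl - 545) / 12)^2) -
    params$dip575 * exp(-0.5 * ((wl - 575) / 10)^2)
  if (min(r) <= 0 || max(r) >= 1)
    stop_validation("parameters drive reflectance out of (0, 1): range %.3f--%.3f",
                    min(r), max(r))
  reflectance_spectrum(wl, r)
}

#' Product effect expressed as a target L*a*b* shift
#'
#' @param dL,da,db target shift in CIELAB units.
#' @return An object of class `product_effect`.
#' @export
product_effect <- function(dL, da, db) {
  structure(list(target = c(L = dL, a = da, b = db)), class = "product_effect")
}

#' Apply a product effect to a spectrum as a smooth spectral modulation
#'
#' Solves for a three-mode spectral perturbation (a flat offset plus smooth
#' red and blue lobes) whose induced CIELAB shift matches the target, by
#' Newton iteration with a finite-difference Jacobian. The achieved shift is
#' within `tol` of the target per channel; an unreachable target (one that
#' would push reflectance out of (0, 1)) raises a convergence error.
#'
#' @param spectrum a [reflectance_spectrum()].
#' @param effect a [product_effect()], or numeric `c(dL, da, db)`.
#' @param ctx a [colorimetry_context()].
#' @param tol per-channel tolerance on the achieved CIELAB shift.
#' @param max_iter Newton iteration cap.
#' @return The modulated [reflectance_spectrum()] with attribute
#'   `achieved_shift`.
#' @export
apply_product_effect <- function(spectrum, effect, ctx = colorimetry_context(),
                                 tol = 0.01, max_iter = 40) {
  target <- if (inherits(effect, "product_effect")) effect$target else {
    stopifnot(is.numeric(effect), length(effect) == 3)
    c(L = effect[[1]], a = effect[[2]], b = effect[[3]])
  }
  wl <- spectrum$wavelengths_nm
  basis <- cbind(flat = rep(1, length(wl)),
                 red = exp(-0.5 * ((wl - 620) / 45)^2),
                 blue = exp(-0.5 * ((wl - 460) / 40)^2))
  lab0 <- spectrum_to_lab(spectrum, ctx)
  shift_of <- function(coef) {
    r <- spectrum$reflectance + as.vector(basis %*% coef)
    if (min(r) <= 1e-4 || max(r) >= 1 - 1e-4) return(NULL)
    spectrum_to_lab(reflectance_spectrum(wl, r), ctx) - lab0
  }
  coef <- c(0, 0, 0)
  h <- 1e-4
  for (iter in seq_len(max_iter)) {
    cur <- shift_of(coef)
    if (is.null(cur))
      stop(structure(class = c("hsi_convergence_error", "error", "condition"),
                     list(message = sprintf(
                       "product effect (%.2f, %.2f, %.2f) is unreachable within (0, 1) reflectance",
                       target[1], target[2], target[3]), call = sys.call(-1))))
    err <- target - cur
    if (max(abs(err)) <= tol) {
      out <- reflectance_spectrum(wl, spectrum$reflectance + as.vector(basis %*% coef))
      attr(out, "achieved_shift") <- cur
      attr(out, "modulation_coef") <- coef
      return(out)
    }
    J <- matrix(0, 3, 3)
    for (j in 1:3) {
      cp <- coef; cp[j] <- cp[j] + h
      cm <- coef; cm[j] <- cm[j] - h
      sp <- shift_of(cp); sm <- shift_of(cm)
      if (is.null(sp) || is.null(sm))
        stop(structure(class = c("hsi_convergence_error", "error", "condition"),
                       list(message = "modulation left the admissible reflectance range",
                            call = sys.call(-1))))
      J[, j] <- (sp - sm) / (2 * h)
    }
    stepv <- tryCatch(solve(J, err), error = function(e) NULL)
    if (is.null(stepv))
      stop(structure(class = c("hsi_convergence_error", "error", "condition"),
                     list(message = "singular Jacobian in product-effect solve",
                          call = sys.call(-1))))
    # damp long steps to stay in the admissible range
    lim <- 0.2 / max(abs(stepv), 0.2)
    coef <- coef + stepv * min(1, lim)
  }
  stop(structure(class = c("hsi_convergence_error", "error", "condition"),
                 list(message = sprintf(
                   "product-effect solve did not converge in %d iterations", max_iter),
                      call = sys.call(-1))))
}
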
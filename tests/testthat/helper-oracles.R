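# Shared fixtures and independent oracles used across the suite.

ctx420 <- colorimetry_context()

flat_spectrum <- function(level, axis = standard_axis()) {
  reflectance_spectrum(axis$wavelengths_nm, rep(level, length(axis$wavelengths_nm)))
}

# small uniform cube
uniform_cube <- function(level, nb = 31, nr = 4, nc = 4) {
  reflectance_cube(array(level, c(nb, nr, nc)), standard_axis())
}

# constant Lab image
const_lab <- function(L, a, b, nr = 100, nc = 100) {
  lab_image(matrix(L, nr, nc), matrix(a, nr, nc), matrix(b, nr, nc))
}

# Monte-Carlo oracle for propagate_to_lab: draw noisy spectra, push each
# through the (vectorised) spectral->Lab path, take per-channel SDs.
mc_lab_sigma <- function(spectrum, noise, ctx, n = 10000, seed = 42) {
  nb <- length(spectrum$reflectance)
  sig <- noise$fractional_sigma *
    switch(noise$scaling, signal = spectrum$reflectance,
           full_scale = rep(0.99, nb))
  draws <- withr::with_seed(seed,
    spectrum$reflectance + sig * matrix(rnorm(nb * n), nb, n))
  draws <- pmin(pmax(draws, 0), 1.2)
  cube <- reflectance_cube(array(draws, c(nb, n, 1)),
                           spectral_axis(spectrum$wavelengths_nm))
  lab <- cube_to_lab(cube, ctx)
  c(sd(lab$L), sd(lab$a), sd(lab$b))
}

# Brute-force Tukey grouping oracle: explicit all-pairs studentized-range
# comparison and maximal-clique enumeration over all subsets.
brute_tukey_groups <- function(summ, alpha = 0.01) {
  k <- nrow(summ)
  summ <- summ[order(summ$mean), ]
  dfw <- sum(summ$n) - k
  msw <- sum((summ$n - 1) * summ$sd^2) / dfw
  sig <- matrix(FALSE, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(msw / 2 * (1 / summ$n[i] + 1 / summ$n[j]))
    p <- ptukey(abs(summ$mean[i] - summ$mean[j]) / se, k, dfw, lower.tail = FALSE)
    sig[i, j] <- sig[j, i] <- p < alpha
  }
  # maximal cliques by exhaustive subset enumeration
  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(0:(k - 1))) > 0))
  ok <- vapply(subsets, function(s) {
    all(!sig[s, s, drop = FALSE])
  }, logical(1))
  cands <- subsets[ok]
  maximal <- cands[vapply(cands, function(s) {
    !any(vapply(cands, function(t) length(t) > length(s) && all(s %in% t), logical(1)))
  }, logical(1))]
  lapply(maximal, function(s) sort(summ$group[s]))
}

random_summaries <- function(k = 3, n = 9) {
  data.frame(group = LETTERS[1:k],
             mean = rnorm(k, 0, 2),
             sd = runif(k, 0.5, 1.5),
             n = n)
}
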
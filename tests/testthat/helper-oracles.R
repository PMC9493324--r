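# Independent closed-form least-squares oracle (Sigma formulas), kept free of
# stats::lm so regression code is cross-checked against a second route.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  fitted <- intercept + slope * x
  sst <- sum((y - sy / n)^2)
  r2 <- if (sst == 0) 1 else 1 - sum((y - fitted)^2) / sst
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Gaussian emission band on a wavelength grid
gaussian_spectrum <- function(center, height = 100, sigma = 20,
                              wl = seq(300, 500, 1), temperature = 298) {
  spectrum(wl, height * exp(-(wl - center)^2 / (2 * sigma^2)),
           temperature = temperature)
}

# Noiseless 1:1 static-quenching series: F = F0 / (1 + K * Q)
static_series <- function(K = 1e5, Q = c(0, 2, 4, 6, 8, 10) * 1e-6,
                          F0 = 1000, center = 338, sigma = 20,
                          temperature = 298) {
  spectra <- lapply(Q, function(q)
    gaussian_spectrum(center, F0 / (1 + K * q), sigma,
                      temperature = temperature))
  titration_series(spectra, Q)
}
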
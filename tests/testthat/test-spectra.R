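test_that("spectrum and titration_series enforce their invariants", {
  wl <- seq(300, 500, 1)
  expect_error(spectrum(wl[1:2], c(1, 2)), "length >= 3")
  expect_error(spectrum(c(1, 2, 2.5, 2.4), 1:4), "strictly increasing")
  expect_error(spectrum(wl, c(NA, rep(1, length(wl) - 1))), "finite")
  expect_error(spectrum(wl, rep(-1, length(wl))), "non-negative")
  expect_silent(spectrum(wl, rep(-1, length(wl)), signal_kind = "cd",
                         temperature = 298))

  sp <- function(t = 298) gaussian_spectrum(338, temperature = t)
  expect_error(titration_series(list(sp(), sp()), c(1e-6, 2e-6)),
               "no F0 reference")
  expect_error(titration_series(list(sp(), sp(), sp()), c(0, 1e-6, 1e-6)),
               "unique")
  expect_error(titration_series(list(sp(), sp(305)), c(0, 1e-6)),
               "temperature")
  ts <- titration_series(list(sp(), sp()), c(1e-6, 0))
  expect_equal(ts$quencher_conc, c(0, 1e-6))  # sorted, reference first
})

test_that("find_peak locates symmetric and off-grid band centers", {
  # center on the grid: exact for any smoothing window
  pk <- find_peak(gaussian_spectrum(338), window = 1)
  expect_equal(pk$position, 338)
  expect_false(pk$boundary)
  pk5 <- find_peak(gaussian_spectrum(338), window = 5)
  expect_equal(pk5$position, 338)

  # off-grid center: parabolic refinement vs dense-grid argmax oracle
  dense <- seq(330, 345, 0.001)
  oracle <- dense[which.max(exp(-(dense - 337.4)^2 / 800))]
  pk <- find_peak(gaussian_spectrum(337.4), window = 1)
  expect_equal(pk$method, "parabolic")
  expect_lt(abs(pk$position - oracle), 0.1)
})

test_that("peak finding is translation-equivariant on a fixed grid", {
  base <- find_peak(gaussian_spectrum(335), window = 1)$position
  for (delta in c(0.1, 0.25, 0.5, 0.75, 1.3, 2.6)) {
    shifted <- find_peak(gaussian_spectrum(335 + delta), window = 1)$position
    expect_lt(abs((shifted - base) - delta), 0.05)
  }
})

test_that("find_peak flags boundary maxima and rejects flat spectra", {
  wl <- seq(300, 400, 1)
  expect_warning(pk <- find_peak(spectrum(wl, seq_along(wl)), window = 1),
                 "boundary")
  expect_true(pk$boundary)
  expect_equal(pk$method, "argmax")
  expect_equal(pk$position, 400)
  expect_error(find_peak(spectrum(wl, rep(5, length(wl)))), "no peak")
  expect_error(find_peak(gaussian_spectrum(338), window = 4), "odd")
  nonuniform <- spectrum(c(300, 301, 303, 306, 310),
                         c(1, 2, 5, 2, 1))
  expect_error(find_peak(nonuniform, window = 3), "uniform")
  expect_silent(find_peak(nonuniform, window = 1))
})

test_that("classify_shift reports direction, delta and blue/red labels", {
  pk <- function(pos, kind = "wavelength_nm")
    structure(list(position = pos, height = 1, method = "argmax",
                   boundary = FALSE, axis_kind = kind), class = "peak_info")
  s <- classify_shift(pk(338), pk(335.5), tolerance = 0.5)
  expect_equal(s$direction, "downshift")
  expect_equal(s$delta, -2.5)
  expect_match(s$label, "blue shift")

  expect_equal(classify_shift(pk(338), pk(338))$direction, "none")
  expect_equal(classify_shift(pk(338), pk(338))$delta, 0)

  s <- classify_shift(pk(1651, "wavenumber_cm-1"), pk(1655, "wavenumber_cm-1"),
                      tolerance = 1)
  expect_equal(s$direction, "upshift")
  expect_equal(s$delta, 4)
  expect_no_match(s$label, "red")  # axis-level label on a wavenumber axis

  expect_error(classify_shift(pk(338), pk(1651, "wavenumber_cm-1")),
               "axis kinds")
})

test_that("quench_ratios reproduces the closed-form static model exactly", {
  K <- 1e5
  Q <- c(0, 2, 4, 6, 8, 10) * 1e-6
  r <- quench_ratios(static_series(K = K, Q = Q))
  expect_equal(r$quencher_conc, Q)
  expect_equal(r$F0_over_F, 1 + K * Q)
  expect_equal(r$F0_minus_F_over_F, K * Q)
  expect_false(any(r$enhancement))
  expect_equal(attr(r, "eval_wavelength"), 338)

  # reference-only series
  one <- titration_series(list(gaussian_spectrum(338)), 0)
  r1 <- quench_ratios(one)
  expect_equal(nrow(r1), 1L)
  expect_equal(unlist(r1[1, c("F0_over_F", "F0_minus_F_over_F")],
                      use.names = FALSE), c(1, 0))
})

test_that("noisy quench ratios stay near the noiseless values", {
  tr <- ground_truth(noise_rel = 0.01, blueshift_max = 0, seed = 11)
  tr0 <- ground_truth(noise_rel = 0, blueshift_max = 0, seed = 11)
  gr <- design_grid(temperatures = 298)
  noisy <- quench_ratios(simulate_titration(tr, gr)[[1]])
  clean <- quench_ratios(simulate_titration(tr0, gr)[[1]])
  expect_lt(max(abs(noisy$F0_over_F / clean$F0_over_F - 1)), 0.03)
})

test_that("quench_ratios flags enhancement and rejects non-positive F", {
  sp0 <- gaussian_spectrum(338, height = 100)
  sp_up <- gaussian_spectrum(338, height = 120)   # brighter than reference
  ts <- titration_series(list(sp0, sp_up), c(0, 1e-6))
  r <- quench_ratios(ts)
  expect_true(r$enhancement[r$quencher_conc > 0])

  wl <- seq(300, 500, 1)
  dead <- spectrum(wl, rep(0, length(wl)), temperature = 298)
  ts2 <- titration_series(list(sp0, dead), c(0, 1e-6))
  expect_error(quench_ratios(ts2), "non-positive intensity")
})

test_that("molar ellipticity applies the conversion pointwise", {
  wl <- seq(190, 250, 1)
  mk <- function(theta) cd_record(
    spectrum(wl, rep(theta, length(wl)), signal_kind = "cd"),
    protein_conc = 1, path_length = 1, residue_count = 1)
  expect_equal(unique(molar_ellipticity(mk(0.5))$signal), 0.05)
  expect_equal(unique(molar_ellipticity(mk(0))$signal), 0)

  # hand-calculator oracle: 0.01 / (400 * 6e-6 * 0.1 * 10)
  rec <- cd_record(spectrum(wl, rep(0.01, length(wl)), signal_kind = "cd"),
                   protein_conc = 6e-6, path_length = 0.1, residue_count = 400)
  expect_equal(unique(molar_ellipticity(rec)$signal), 4.16666666666667,
               tolerance = 1e-12)
})

test_that("molar ellipticity is linear in theta, inverse-linear in R, C, l", {
  wl <- seq(190, 250, 1)
  theta <- sin(wl / 10)
  base <- cd_record(spectrum(wl, theta, signal_kind = "cd"),
                    protein_conc = 2e-6, path_length = 0.2, residue_count = 300)
  ref <- molar_ellipticity(base)$signal
  scale_field <- function(conc = 2e-6, pl = 0.2, res = 300, th = theta)
    molar_ellipticity(cd_record(spectrum(wl, th, signal_kind = "cd"),
                                conc, pl, res))$signal
  expect_equal(scale_field(th = 3 * theta), 3 * ref)
  expect_equal(scale_field(conc = 4e-6), ref / 2)
  expect_equal(scale_field(pl = 0.4), ref / 2)
  expect_equal(scale_field(res = 600), ref / 2)
})

test_that("millidegree convenience flag divides the CD signal by 1000", {
  wl <- seq(190, 250, 1)
  rec <- cd_record(spectrum(wl, rep(500, length(wl)), signal_kind = "cd"),
                   1, 1, 1, from_millideg = TRUE)
  expect_equal(unique(rec$spectrum$signal), 0.5)
  expect_error(cd_record(spectrum(wl, rep(1, length(wl)), signal_kind = "cd"),
                         0, 1, 1), "protein_conc")
  expect_error(cd_record(spectrum(wl, rep(1, length(wl)), signal_kind = "cd"),
                         1, 1, 0), "residue_count")
})
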
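test_that("stern_volmer_fit recovers an exact line and the kq identity", {
  ratios <- data.frame(quencher_conc = c(0, 1, 2) * 1e-5,
                       F0_over_F = c(1, 2, 3))
  fit <- stern_volmer_fit(ratios, temperature = 273)
  expect_equal(fit$K_SV, 1e5)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_false(fit$intercept_flag)
  # kq = K_SV / tau0 with tau0 = 1e-8 s puts kq on the 1e13 scale
  fit2 <- stern_volmer_fit(data.frame(quencher_conc = c(0, 1, 2) * 1e-5,
                                      F0_over_F = 1 + 1.07e5 * c(0, 1, 2) * 1e-5),
                           tau0 = 1e-8)
  expect_equal(fit2$kq, 1.07e13)
})

test_that("kq = K_SV / tau0 holds exactly across random fits", {
  set.seed(401)
  for (i in 1:20) {
    q <- sort(c(0, runif(5, 1e-6, 1e-4)))
    k <- 10^runif(1, 3, 6)
    tau0 <- 10^runif(1, -9, -7)
    fit <- stern_volmer_fit(
      data.frame(quencher_conc = q, F0_over_F = 1 + k * q + rnorm(6, 0, 0.01)),
      tau0 = tau0)
    expect_identical(fit$kq, fit$K_SV / tau0)
    expect_gte(fit$r_squared, 0)
    expect_lte(fit$r_squared, 1)
  }
})

test_that("both regressions match the closed-form OLS oracle", {
  set.seed(77)
  for (i in 1:25) {
    q <- sort(runif(8, 1e-6, 5e-5))
    y <- 1 + 8e4 * q + rnorm(8, 0, 0.05)
    y <- pmax(y, 1.001)
    fit <- suppressWarnings(
      stern_volmer_fit(data.frame(quencher_conc = q, F0_over_F = y)))
    orc <- ols_oracle(q, y)
    expect_equal(fit$K_SV, orc$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-10)

    dl <- double_log_fit(data.frame(quencher_conc = q, F0_over_F = y))
    orc2 <- ols_oracle(log10(q), log10(y - 1))
    expect_equal(dl$n, orc2$slope, tolerance = 1e-10)
    expect_equal(log10(dl$Ka), orc2$intercept, tolerance = 1e-10)
  }
})

test_that("double_log_fit inverts noiseless binding models exactly", {
  Q <- c(2, 4, 6, 8, 10) * 1e-6
  # 1:1 static model
  r <- data.frame(quencher_conc = c(0, Q), F0_over_F = 1 + 1e5 * c(0, Q))
  dl <- double_log_fit(r)
  expect_equal(dl$n, 1, tolerance = 1e-9)
  expect_equal(dl$Ka, 1e5, tolerance = 1e-6)
  expect_equal(dl$r_squared, 1)
  # generalized (F0-F)/F = Ka Q^n
  Ka <- 5e4; n <- 1.2
  r2 <- data.frame(quencher_conc = Q, F0_over_F = 1 + Ka * Q^n)
  dl2 <- double_log_fit(r2)
  expect_equal(dl2$n, n, tolerance = 1e-9)
  expect_equal(dl2$Ka, Ka, tolerance = 1e-4)
})

test_that("Stern-Volmer and double-log fits agree on 1:1 static data", {
  series <- static_series(K = 7.3e4)
  r <- quench_ratios(series)
  sv <- stern_volmer_fit(r)
  dl <- double_log_fit(r)
  expect_equal(sv$K_SV, dl$Ka, tolerance = 1e-6)
  expect_equal(dl$n, 1, tolerance = 1e-6)
})

test_that("concentration rescaling moves K_SV and Ka as 1/c", {
  Q <- c(0, 2, 4, 6, 8, 10) * 1e-6
  y <- 1 + 1e5 * Q
  for (c_scale in c(10, 0.1)) {
    r <- data.frame(quencher_conc = Q * c_scale, F0_over_F = y)
    expect_equal(stern_volmer_fit(r)$K_SV, 1e5 / c_scale, tolerance = 1e-9)
    expect_equal(double_log_fit(r)$Ka, 1e5 / c_scale, tolerance = 1e-6)
  }
})

test_that("fit preconditions and row exclusions are enforced", {
  expect_error(stern_volmer_fit(data.frame(quencher_conc = c(0, 1e-5),
                                           F0_over_F = c(1, 2))),
               "underdetermined")
  # enhancement rows are excluded before fitting
  r <- data.frame(quencher_conc = c(0, 2, 4, 6, 8) * 1e-6,
                  F0_over_F = c(1, 1.2, 1.4, 1.6, 0.9),
                  F0_minus_F_over_F = c(0, 0.2, 0.4, 0.6, -0.1),
                  enhancement = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  fit <- stern_volmer_fit(r)
  expect_equal(fit$n_points, 4L)
  expect_equal(fit$K_SV, 1e5, tolerance = 1e-9)
  expect_warning(dl <- double_log_fit(r), "dropped")
  expect_equal(dl$n_points, 3L)
  expect_error(double_log_fit(data.frame(quencher_conc = c(0, 1e-6, 2e-6),
                                         F0_over_F = c(1, 1.1, 1.2))),
               "fewer than 3")
  expect_warning(stern_volmer_fit(data.frame(quencher_conc = c(0, 1, 2) * 1e-5,
                                             F0_over_F = c(1.3, 2.3, 3.3))),
                 "intercept")
})

test_that("constrained Stern-Volmer fit passes through (0, 1)", {
  q <- c(0, 2, 4, 6, 8) * 1e-6
  y <- 1.05 + 9e4 * q
  fit <- suppressWarnings(
    stern_volmer_fit(data.frame(quencher_conc = q, F0_over_F = y),
                     constrain_intercept = TRUE))
  expect_identical(fit$intercept, 1)
  # oracle: least squares through (0,1) -> slope = sum(q (y-1)) / sum(q^2)
  expect_equal(fit$K_SV, sum(q * (y - 1)) / sum(q^2), tolerance = 1e-12)
})

test_that("mechanism classification reproduces the textbook cases", {
  # measured K_SV decreasing with T and kq far above the diffusion limit
  tab <- data.frame(temperature = c(273, 298, 318, 338),
                    K_SV = c(1.07, 0.97, 0.96, 0.95) * 1e5,
                    stderr_K_SV = c(0.01, 0.02, 0.03, 0.07) * 1e5)
  tab$kq <- tab$K_SV / 1e-8
  call <- classify_mechanism(tab)
  expect_equal(call$verdict, "static")
  expect_true(all(call$kq_exceeds_diffusion_limit))
  expect_equal(call$ksv_temperature_trend, "decreasing")

  # collisional signature: low kq, K_SV rising with T
  dyn <- data.frame(temperature = c(273, 298, 318, 338),
                    K_SV = c(0.8, 0.9, 1.0, 1.1) * 1e2)
  dyn$kq <- rep(1e9, 4)
  expect_equal(classify_mechanism(dyn)$verdict, "dynamic")

  # conflicting criteria
  conf <- dyn; conf$kq <- conf$K_SV / 1e-8 * 1e6
  expect_equal(classify_mechanism(conf)$verdict, "ambiguous")

  expect_error(classify_mechanism(tab[1, ]), "trend undefined")
})
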
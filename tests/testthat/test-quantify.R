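test_that("difference spectra are pointwise, linear and axis-checked", {
  p <- acquisition_params(n_points = 256)
  a <- to_spectrum(line_fid(p, -100), p)
  b <- to_spectrum(line_fid(p, -300), p)
  expect_equal(difference_spectrum(a, a)$values, complex(256) * 0)
  d1 <- difference_spectrum(a, b)
  a2 <- processed_spectrum(2 * a$values, a$ppm_axis, p)
  b2 <- processed_spectrum(2 * b$values, b$ppm_axis, p)
  expect_equal(difference_spectrum(a2, b2)$values, 2 * d1$values)
  short <- acquisition_params(n_points = 128)
  expect_error(difference_spectrum(a, to_spectrum(line_fid(short, -100),
                                                  short)),
               "axis")
})

test_that("the edited spectrum combines the blocks per mode", {
  sp <- preprocess_set(phantom_acq(9))
  gp <- famous_glu_spectrum(sp, "phantom")
  expect_equal(gp$values,
               difference_spectrum(sp$control1, sp$selinv1)$values)
  expect_error(famous_glu_spectrum(sp, "invivo"), "missing block")
})

test_that("metabolite nulling removes most in-band macromolecule signal", {
  art <- quiet_artifacts()
  sys <- make_brain_system(glu_mM = 0, naa_mM = 0, cr_mM = 0)  # MM only
  acq <- simulate_acquisition(sys, PARAMS_IV, art, FSI, IR, "invivo")
  sp <- preprocess_set(acq)
  band <- c(2.25, 2.45)
  mm_single <- integrate_band(
    difference_spectrum(sp$control1, sp$selinv1), band)
  mm_famous <- integrate_band(famous_glu_spectrum(sp, "invivo"), band)
  ratio <- abs(mm_single) / abs(mm_famous)
  # double-IR residual at T1 = 0.3 s gives ~3.6x reduction
  expect_gte(ratio, 3)
  expected <- 1 / (1 - double_ir_mz(0.3, IR$ti1_ms / 1000,
                                    IR$ti2_ms / 1000))
  expect_equal(ratio, expected, tolerance = 0.02)

  # without macromolecules the second difference pair is nearly empty
  sys2 <- make_brain_system(mm = FALSE, naa_mM = 0, cr_mM = 0)
  sp2 <- preprocess_set(simulate_acquisition(sys2, PARAMS_IV, art,
                                             FSI, IR, "invivo"))
  pair2 <- difference_spectrum(sp2$control2, sp2$selinv2)
  pair1 <- difference_spectrum(sp2$control1, sp2$selinv1)
  expect_lt(abs(integrate_band(pair2, band)),
            0.05 * abs(integrate_band(pair1, band)))
})

test_that("Lorentzian fitting recovers exact and noisy parameters", {
  p <- acquisition_params()
  spec <- to_spectrum(line_fid(p, -698.4, amp = 6, fwhm_hz = 18), p)
  fit <- fit_lorentzian(spec, c(1.9, 2.8))
  expect_equal(fit$area, 3, tolerance = 1e-4)        # one-sided FT: amp/2
  expect_equal(fit$center_ppm, 4.7 - 698.4 / 297.2, tolerance = 1e-5)
  expect_equal(fit$fwhm_hz, 18, tolerance = 1e-2)

  # Monte-Carlo bias at SNR ~ 50
  areas <- withr::with_seed(99, vapply(1:200, function(i) {
    noisy <- processed_spectrum(
      spec$values + complex(real = rnorm(4096, 0, 2e-3),
                            imaginary = rnorm(4096, 0, 2e-3)),
      spec$ppm_axis, p)
    fit_lorentzian(noisy, c(1.9, 2.8))$area
  }, numeric(1)))
  expect_lt(abs(mean(areas) / 3 - 1), 0.01)

  # initial-guess independence
  f1 <- fit_lorentzian(spec, c(1.9, 2.8),
                       start = list(fwhm_hz = 40, f0_hz = 690))
  expect_equal(f1$area, fit$area, tolerance = 1e-6)
})

test_that("band integration matches the Lorentzian CDF oracle", {
  p <- acquisition_params()
  zero <- processed_spectrum(complex(4096) * 0, ppm_axis(p), p)
  expect_equal(integrate_band(zero, c(2.25, 2.45)), 0)

  spec <- to_spectrum(line_fid(p, -698.42, amp = 2, fwhm_hz = 15), p)
  got <- integrate_band(spec, c(2.25, 2.45))
  # CDF oracle: fraction of a unit-area 15 Hz Lorentzian inside +/-29.72 Hz
  half <- 0.1 * 297.2
  frac <- (2 / pi) * atan(2 * half / 15)
  expect_equal(got, 1 * frac, tolerance = 0.01)
  expect_equal(frac, 0.843, tolerance = 1e-3)

  off <- integrate_band(spec, c(3.0, 3.2))     # fully off-peak
  expect_lt(abs(off), 0.02)
  expect_error(integrate_band(spec, c(20, 30)), "outside")
})

test_that("editing efficiency follows the inversion profile", {
  expect_equal(editing_efficiency(function(off) rep(-1, length(off))), 1)
  expect_equal(editing_efficiency(function(off) rep(0, length(off))), 0.5)
  k <- editing_efficiency(FSI)
  expect_equal(k, 0.5, tolerance = 5e-3)
  expect_error(editing_efficiency(FSI, numeric(0), numeric(0)), "empty")
})

test_that("absolute concentration applies the water-reference formula", {
  cfg <- quant_config(kappa = 0.5, water_fraction = 0.8)
  expect_equal(absolute_concentration(0, 100, cfg), 0)
  c1 <- absolute_concentration(10, 1e5, cfg)
  # closed form: (10 / (0.5*2)) / (1e5 / 2) * 0.8 * 55510
  expect_equal(c1, 10 / (0.5 * 2) / (1e5 / 2) * 0.8 * 55510)
  cfg2 <- quant_config(kappa = 0.5, water_fraction = 0.4)
  expect_equal(absolute_concentration(10, 1e5, cfg2), c1 / 2)
  expect_error(absolute_concentration(1, 0, cfg), "positive")
})

test_that("noise-free phantom pipeline recovers the true concentration", {
  q <- famous_pipeline(9, "phantom", noise_sigma = 0, fsi = FSI, ir = IR)
  expect_equal(q$concentration_mM, 9, tolerance = 0.03)
})

test_that("phantom series is linear in concentration", {
  concs <- c(6, 9, 12, 15)
  rec0 <- vapply(concs, function(cc)
    famous_pipeline(cc, "phantom", noise_sigma = 0, fsi = FSI,
                    ir = IR)$concentration_mM, numeric(1))
  fit0 <- lm(rec0 ~ concs)
  expect_equal(unname(coef(fit0)[2]), 1, tolerance = 0.03)
  expect_lt(abs(unname(coef(fit0)[1])), 0.02 * 15)

  recn <- purrr::map2_dbl(concs, 201:204, function(cc, seed)
    famous_pipeline(cc, "phantom", seed = seed, fsi = FSI,
                    ir = IR)$concentration_mM)
  fitn <- summary(lm(recn ~ concs))
  expect_gte(fitn$r.squared, 0.99)
  expect_true(all(abs(recn - rec0) / concs < 0.05))
})

test_that("macromolecule suppression reduces in-vivo quantification bias", {
  sys <- make_brain_system()
  acq <- simulate_acquisition(sys, PARAMS_IV, quiet_artifacts(), FSI, IR,
                              "invivo")
  sp <- preprocess_set(acq)
  cfg <- quant_config(water_fraction = 0.8)
  q_iv <- quantify_glu(sp, FSI, IR, mode = "invivo", config = cfg)
  q_ph <- quantify_glu(sp, FSI, IR, mode = "phantom", config = cfg)
  err_iv <- abs(q_iv$concentration_mM - 9.57) / 9.57
  err_ph <- abs(q_ph$concentration_mM - 9.57) / 9.57
  expect_lt(err_iv, err_ph / 2)   # nulling at least halves the bias
  expect_lt(err_iv, 0.05)         # recovery within 5% despite MM/NAA
  expect_gt(q_ph$concentration_mM, 9.57)   # unsuppressed MM biases high
})

test_that("a glutamate-free brain yields a noise-limited concentration", {
  q <- famous_pipeline(0, "invivo", seed = 5, fsi = FSI, ir = IR,
                       mm = FALSE, naa_mM = 0, cr_mM = 0)
  expect_lt(q$concentration_mM, 0.3)
})

test_that("tidy and glance summarize a quantification", {
  q <- famous_pipeline(9, "phantom", noise_sigma = 0, fsi = FSI, ir = IR)
  td <- tidy(q)
  expect_true(all(c("quantity", "value") %in% names(td)))
  expect_equal(td$value[td$quantity == "kappa"], q$kappa)
  g <- glance(q)
  expect_equal(g$mode, "phantom")
  expect_equal(g$concentration_mM, q$concentration_mM)
})
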
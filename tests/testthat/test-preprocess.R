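test_that("channel combination is a matched filter", {
  p <- acquisition_params(n_points = 512)
  w1 <- line_fid(p, 0, amp = 3)
  # single channel: output equals input up to a unit-modulus phase
  out <- combine_channels(list(w1), list(w1))
  expect_equal(Mod(out$samples), Mod(w1$samples), tolerance = 1e-12)

  # two equal-magnitude channels at phases 0 and pi/2: compare with an
  # exhaustive phase-rotation oracle
  f <- line_fid(p, -100, amp = 1)
  ch <- list(raw_fid(f$samples, f$dwell_s),
             raw_fid(f$samples * exp(1i * pi / 2), f$dwell_s))
  wat <- list(w1, raw_fid(w1$samples * exp(1i * pi / 2), w1$dwell_s))
  got <- combine_channels(ch, wat)
  oracle <- max(vapply(seq(0, 2 * pi, length.out = 3601), function(phi)
    Mod(ch[[1]]$samples[1] + exp(-1i * phi) * ch[[2]]$samples[1]),
    numeric(1))) / sqrt(2)
  expect_equal(Mod(got$samples[1]), oracle, tolerance = 1e-4)

  expect_error(combine_channels(ch, list(raw_fid(0 * w1$samples,
                                                 w1$dwell_s),
                                         raw_fid(0 * w1$samples,
                                                 w1$dwell_s))),
               "zero water signal")
})

test_that("combined SNR is at least the best single channel's", {
  p <- acquisition_params(n_points = 256)
  gains <- c(1, 0.7, 1.3)
  phases <- c(0, 1.1, -0.6)
  # 60 Hz lines decay fully before the noise-estimation tail
  clean <- line_fid(p, -50, amp = 30, fwhm_hz = 60)$samples
  wins <- withr::with_seed(7, vapply(1:100, function(i) {
    ch <- purrr::map2(gains, phases, function(g, ph)
      raw_fid(g * exp(1i * ph) * clean +
                complex(real = rnorm(256), imaginary = rnorm(256)),
              dwell_time(p)))
    wat <- purrr::map2(gains, phases, function(g, ph)
      raw_fid(g * exp(1i * ph) *
                line_fid(p, 0, amp = 1000, fwhm_hz = 60)$samples +
                complex(real = rnorm(256), imaginary = rnorm(256)),
              dwell_time(p)))
    snr <- function(x) Mod(x[1]) / stats::sd(Re(x[180:256]))
    # small slack absorbs noise in the tail-based SD estimate
    snr(combine_channels(ch, wat)$samples) >=
      0.98 * max(vapply(ch, function(f) snr(f$samples), numeric(1)))
  }, logical(1)))
  expect_gte(mean(wins), 0.95)
})

test_that("eddy-current correction is Klose phase deconvolution", {
  p <- acquisition_params(n_points = 512)
  wat <- line_fid(p, 0, amp = 5)     # real positive envelope
  fid <- line_fid(p, -300, amp = 2)
  expect_equal(eddy_current_correct(fid, wat)$samples, fid$samples,
               tolerance = 1e-12)
  # water corrected by itself: non-negative real
  t <- (0:511) * dwell_time(p)
  phi <- 0.8 * exp(-t / 0.004)
  watp <- raw_fid(wat$samples * exp(1i * phi), wat$dwell_s)
  self <- eddy_current_correct(watp, watp)
  expect_equal(max(abs(Im(self$samples))), 0, tolerance = 1e-12)
  expect_true(all(Re(self$samples) >= 0))
  # shared transient removed exactly
  fidp <- raw_fid(fid$samples * exp(1i * phi), fid$dwell_s)
  expect_equal(eddy_current_correct(fidp, watp)$samples, fid$samples,
               tolerance = 1e-12)
})

test_that("apodization broadens lines additively and keeps the integral", {
  p <- acquisition_params()
  fid <- line_fid(p, -698.4, amp = 4, fwhm_hz = 15)
  expect_identical(apodize(fid, 0)$samples, fid$samples)
  apo <- apodize(fid, 7)
  expect_equal(apo$samples[1], fid$samples[1])   # t = 0 untouched
  fit <- fit_lorentzian(to_spectrum(apo, p), c(2.1, 2.6))
  bin_hz <- p$sweep_width_hz / p$n_points
  expect_equal(fit$fwhm_hz, 22, tolerance = bin_hz)
  expect_error(apodize(fid, -1), "non-negative")
})

test_that("to_spectrum follows the FT conventions", {
  p <- acquisition_params(n_points = 1024)
  delta <- raw_fid(c(1, rep(0, 1023)), dwell_time(p))
  flat <- to_spectrum(delta, p)
  expect_equal(max(Mod(flat$values)), min(Mod(flat$values)),
               tolerance = 1e-12)

  fid <- line_fid(p, -698, amp = 1, fwhm_hz = 10)
  spec <- to_spectrum(fid, p)
  pk <- spec$ppm_axis[which.max(Re(spec$values))]
  expect_lt(abs(pk - (4.7 - 698 / 297.2)), abs(diff(spec$ppm_axis)[1]))

  # integral bookkeeping: the spectral integral equals the one-sided
  # FT limit at t = 0, i.e. half the first FID sample
  total <- sum(spec$values) * p$sweep_width_hz / p$n_points
  expect_equal(total, fid$samples[1] / 2, tolerance = 1e-12)
})

test_that("automated phasing recovers an applied zero-order phase", {
  p <- acquisition_params()
  wat <- to_spectrum(line_fid(p, 0, amp = 5), p)
  phased <- auto_phase(wat, wat)
  expect_equal(phased$provenance$auto_phase$phi0_rad, 0, tolerance = 1e-9)

  rot <- processed_spectrum(wat$values * exp(1i * pi / 4), wat$ppm_axis,
                            p)
  rec <- auto_phase(rot, rot)
  # grid-search oracle for the best zero-order phase
  sel <- wat$ppm_axis >= 4.2 & wat$ppm_axis <= 5.2
  grid <- seq(-pi, pi, length.out = 20001)
  oracle <- grid[which.max(vapply(grid, function(ph)
    sum(Re(rot$values[sel] * exp(1i * ph))), numeric(1)))]
  expect_equal(rec$provenance$auto_phase$phi0_rad, -pi / 4,
               tolerance = 0.01)
  expect_equal(rec$provenance$auto_phase$phi0_rad, oracle,
               tolerance = 0.001)
  # idempotent
  again <- auto_phase(rec, rec)
  expect_equal(again$provenance$auto_phase$phi0_rad, 0, tolerance = 1e-6)
})

test_that("the full chain removes the simulated eddy transient exactly", {
  art_eddy <- quiet_artifacts()
  art_none <- quiet_artifacts()
  art_none$eddy_terms <- list()
  a1 <- simulate_acquisition(make_phantom_system(9), PARAMS_PH, art_eddy,
                             FSI, IR, "phantom")
  a0 <- simulate_acquisition(make_phantom_system(9), PARAMS_PH, art_none,
                             FSI, IR, "phantom")
  s1 <- preprocess_set(a1)
  s0 <- preprocess_set(a0)
  rel <- max(Mod(s1$control1$values - s0$control1$values)) /
    max(Mod(s0$control1$values))
  expect_lt(rel, 1e-10)
})

test_that("preprocessing shares weights and phase across blocks and
           normalizes average counts", {
  acq <- phantom_acq(9)
  sp <- preprocess_set(acq)
  w <- purrr::map(sp, ~ .x$provenance$combine$weights)
  expect_true(all(vapply(w, identical, logical(1), w$water_ref)))
  phi <- vapply(sp, function(s) s$provenance$auto_phase$phi0_rad,
                numeric(1))
  expect_true(all(phi == phi[["water_ref"]]))

  # with suppression off, the 8-average water block and the 32-average
  # control block carry equal water-line areas after normalization
  art <- quiet_artifacts()
  art$water_suppression_factor <- 1
  spn <- preprocess_set(simulate_acquisition(make_phantom_system(0),
                                             PARAMS_PH, art, FSI, IR,
                                             "phantom"))
  a_w <- fit_lorentzian(spn$water_ref, c(3.7, 5.7))$area
  a_c <- fit_lorentzian(spn$control1, c(3.7, 5.7))$area
  expect_equal(a_c, a_w, tolerance = 1e-6)

  # water suppression visible after processing
  sup <- max(Re(sp$water_ref$values)) / max(Re(sp$control1$values))
  expect_gte(sup, 100)

  acq_nowater <- acq
  acq_nowater$blocks$water_ref <- NULL
  expect_error(preprocess_set(acq_nowater), "water_ref")
})

test_that("the chain is linear and ECC/apodization commute", {
  acq <- phantom_acq(7)
  scaled <- acq
  scaled$blocks <- purrr::map(scaled$blocks, function(fids)
    purrr::map(fids, function(f)
      raw_fid(3 * f$samples, f$dwell_s, f$n_averages, f$channel_index)))
  s1 <- preprocess_set(acq)
  s3 <- preprocess_set(scaled)
  expect_equal(s3$control1$values, 3 * s1$control1$values,
               tolerance = 1e-10)

  p <- acquisition_params(n_points = 512)
  t <- (0:511) * dwell_time(p)
  wat <- raw_fid(line_fid(p, 0, amp = 5)$samples *
                   exp(1i * 0.5 * exp(-t / 0.01)), dwell_time(p))
  fid <- raw_fid(line_fid(p, -200)$samples *
                   exp(1i * 0.5 * exp(-t / 0.01)), dwell_time(p))
  ab <- apodize(eddy_current_correct(fid, wat), 7)
  ba <- eddy_current_correct(apodize(fid, 7), wat)
  expect_equal(ab$samples, ba$samples, tolerance = 1e-12)
})
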
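#' Combine phased-array channels
#'
#' Water-reference matched filter: channel weights proportional to the
#' conjugate of the first sample of each channel's water-reference FID,
#' normalized to unit power (`sum |w|^2 = 1`). The same weights are reused
#' for every block of a scan so that inter-block amplitude ratios are
#' preserved.
#'
#' @param fids List of [raw_fid()] objects, one per channel.
#' @param water_fids The water-reference FIDs of the same channels.
#' @return A single combined [raw_fid()].
#' @export
combine_channels <- function(fids, water_fids) {
  if (length(fids) != length(water_fids))
    abort("channel counts differ between block and water reference.")
  lens <- vapply(fids, function(f) length(f$samples), integer(1))
  if (length(unique(lens)) != 1)
    abort("all channel FIDs must share one length.")
  w <- vapply(water_fids, function(f) Conj(f$samples[1]), complex(1))
  pw <- sum(Mod(w)^2)
  if (pw == 0) abort("zero water signal on all channels; cannot combine.")
  w <- w / sqrt(pw)
  out <- Reduce(`+`, purrr::map2(fids, w, function(f, wc) wc * f$samples))
  raw_fid(out, fids[[1]]$dwell_s, n_averages = fids[[1]]$n_averages,
          channel_index = NA_integer_)
}

# the weights alone, for provenance
combination_weights <- function(water_fids) {
  w <- vapply(water_fids, function(f) Conj(f$samples[1]), complex(1))
  w / sqrt(sum(Mod(w)^2))
}

#' Eddy-current phase correction
#'
#' Klose-style pointwise phase deconvolution: the instantaneous phase of
#' the (combined) water-reference FID is subtracted from the target FID,
#' `out(t) = fid(t) * exp(-i arg(water(t)))`. Because the water line sits
#' on resonance with zero intrinsic phase, its instantaneous phase is the
#' eddy-current transient itself; correcting the water reference by its
#' own phase leaves a non-negative real signal.
#'
#' Samples where the water magnitude falls below `floor_frac` of its
#' maximum carry the last valid phase forward (flagged in the result's
#' attributes).
#'
#' @param fid Target [raw_fid()].
#' @param water_fid Water-reference [raw_fid()] of the same length/dwell.
#' @param floor_frac Relative magnitude floor for trusting the water
#'   phase.
#' @return The corrected [raw_fid()]; attribute `ecc_flagged` gives the
#'   number of floored samples.
#' @export
eddy_current_correct <- function(fid, water_fid, floor_frac = 1e-8) {
  if (length(fid$samples) != length(water_fid$samples) ||
      abs(fid$dwell_s - water_fid$dwell_s) > 0)
    abort("target and water FIDs must share length and dwell time.")
  mag <- Mod(water_fid$samples)
  ok <- mag >= floor_frac * max(mag)
  phase <- Arg(water_fid$samples)
  if (!ok[1]) phase[1] <- 0
  if (any(!ok)) {
    for (i in which(!ok)) if (i > 1) phase[i] <- phase[i - 1]
  }
  out <- raw_fid(fid$samples * exp(-1i * phase), fid$dwell_s,
                 n_averages = fid$n_averages,
                 channel_index = fid$channel_index)
  attr(out, "ecc_flagged") <- sum(!ok)
  out
}

#' Exponential apodization
#'
#' Multiplies the FID by `exp(-pi * lb_hz * t)`, broadening every
#' Lorentzian line by `lb_hz` while leaving the first sample - and hence
#' the total spectral integral - unchanged. The processing chain default
#' is 7 Hz.
#'
#' @param fid A [raw_fid()].
#' @param lb_hz Line broadening (Hz), non-negative.
#' @return The apodized [raw_fid()].
#' @export
apodize <- function(fid, lb_hz = 7) {
  if (lb_hz < 0) abort("`lb_hz` must be non-negative.")
  if (lb_hz == 0) return(fid)
  t <- (seq_along(fid$samples) - 1) * fid$dwell_s
  raw_fid(fid$samples * exp(-pi * lb_hz * t), fid$dwell_s,
          n_averages = fid$n_averages, channel_index = fid$channel_index)
}

#' Fourier transform a FID to a spectrum
#'
#' Discrete Fourier transform scaled by the dwell time, so that the
#' spectral integral (per Hz) of a line equals its time-domain `t = 0`
#' amplitude contribution, ordered onto the decreasing ppm axis of
#' [ppm_axis()]. A decaying complex sinusoid of decay rate `R` transforms
#' to [lorentzian()] with `fwhm = R/pi` at the matching ppm.
#'
#' @param fid A [raw_fid()].
#' @param params The owning [acquisition_params()].
#' @param provenance Provenance list carried into the result.
#' @return A [processed_spectrum()].
#' @export
to_spectrum <- function(fid, params, provenance = list()) {
  if (length(fid$samples) != params$n_points)
    abort("FID length does not match `params$n_points`.")
  s <- fid$samples
  # first-point scaling: the rectangle rule over a one-sided signal
  # overweights t = 0 by half a sample, which would add a flat baseline
  # of dwell * s[1] / 2 across the spectrum
  s[1] <- s[1] / 2
  X <- fft(s) * fid$dwell_s
  f <- fft_freqs_hz(params$n_points, params$sweep_width_hz)
  ord <- order(f, decreasing = TRUE)
  provenance$fourier_transform <- list(scale = "dwell")
  processed_spectrum(X[ord], ppm_axis(params), params, provenance)
}

#' Automated zero-order phasing
#'
#' Chooses the zero-order phase that maximizes the real integral of the
#' water region of the water-reference spectrum (closed form: minus the
#' argument of the complex integral over the window) and applies that same
#' phase to the target spectrum, so all five spectra of a scan share one
#' phase.
#'
#' @param spectrum Target [processed_spectrum()].
#' @param water_spectrum Water-reference spectrum on the same axis.
#' @param water_window_ppm Window treated as the water region.
#' @return The phased [processed_spectrum()]; `provenance$auto_phase`
#'   records the applied phase and whether water was detectable.
#' @export
auto_phase <- function(spectrum, water_spectrum,
                       water_window_ppm = c(4.2, 5.2)) {
  if (length(spectrum$values) != length(water_spectrum$values) ||
      max(abs(spectrum$ppm_axis - water_spectrum$ppm_axis)) > 1e-12)
    abort("spectra must share one ppm axis.")
  sel <- water_spectrum$ppm_axis >= water_window_ppm[1] &
    water_spectrum$ppm_axis <= water_window_ppm[2]
  z <- sum(water_spectrum$values[sel])
  flagged <- FALSE
  if (Mod(z) < .Machine$double.eps * 100) {
    phi0 <- 0
    flagged <- TRUE
  } else {
    phi0 <- -Arg(z)
  }
  prov <- spectrum$provenance
  prov$auto_phase <- list(phi0_rad = phi0, water_detected = !flagged)
  processed_spectrum(spectrum$values * exp(1i * phi0), spectrum$ppm_axis,
                     spectrum$params, prov)
}

#' Automated processing of a full acquisition
#'
#' The automated chain applied identically to every block: normalize by
#' the stored average count, combine channels with water-derived matched
#' filter weights, eddy-current correct against the combined water
#' reference, apodize (default 7 Hz), Fourier transform, and apply the
#' common water-derived zero-order phase. Every step is recorded in each
#' spectrum's provenance.
#'
#' @param acq An [acquisition_set()].
#' @param lb_hz Exponential line broadening (Hz).
#' @param water_window_ppm Water region for automated phasing.
#' @return A named list of [processed_spectrum()] objects (class
#'   `famous_spectra`) with the acquisition's params and mode attached as
#'   attributes.
#' @export
preprocess_set <- function(acq, lb_hz = 7, water_window_ppm = c(4.2, 5.2)) {
  stopifnot(inherits(acq, "acquisition_set"))
  if (!"water_ref" %in% names(acq$blocks))
    abort("missing water_ref block: eddy-current correction impossible.")
  params <- acq$params

  norm_block <- function(fids) {
    purrr::map(fids, function(f) {
      if (f$n_averages > 0)
        raw_fid(f$samples / f$n_averages, f$dwell_s, n_averages = 1,
                channel_index = f$channel_index)
      else f
    })
  }
  blocks <- purrr::map(acq$blocks, norm_block)
  wts <- combination_weights(blocks$water_ref)
  combined <- purrr::map(blocks, combine_channels,
                         water_fids = blocks$water_ref)
  water_c <- combined$water_ref
  out <- purrr::imap(combined, function(fid, lab) {
    ecc <- eddy_current_correct(fid, water_c)
    apo <- apodize(ecc, lb_hz)
    to_spectrum(apo, params, provenance = list(
      normalize = list(by = acq$params$averages[[lab]]),
      combine = list(weights = wts),
      ecc = list(flagged = attr(ecc, "ecc_flagged")),
      apodize = list(lb_hz = lb_hz)))
  })
  water_spec <- out$water_ref
  out <- purrr::map(out, auto_phase, water_spectrum = water_spec,
                    water_window_ppm = water_window_ppm)
  structure(out, class = "famous_spectra", params = params,
            mode = acq$mode)
}

#' @export
print.famous_spectra <- function(x, ...) {
  cat("<famous_spectra>", attr(x, "mode"), "mode:",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
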
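#' Acquisition parameters for a FAMOUS single-voxel scan
#'
#' Bundles the timing and sampling parameters of one five-spectrum
#' acquisition. Defaults follow the 7T single-voxel protocol used throughout
#' the package: TR 3000 ms, TE 21 ms, 4096 complex points, 6000 Hz sweep
#' width, 4 dummy scans per block, 8 water-reference and 32 water-suppressed
#' averages.
#'
#' @param tr_ms Repetition time (ms).
#' @param te_ms Echo time (ms). Recorded as metadata; the amplitude model
#'   absorbs T2/TE decay into the linewidths.
#' @param n_points Complex samples per FID.
#' @param sweep_width_hz Receiver bandwidth (Hz); dwell time is its inverse.
#' @param dummy_scans Dummy (steady-state) scans per block.
#' @param averages Named vector of average counts per acquisition block.
#'   Names must be a subset of `water_ref, control1, selinv1, control2,
#'   selinv2`.
#' @param spectrometer_freq_mhz Proton frequency (MHz); 297.2 at 7 T.
#' @param reference_ppm Chemical shift assigned to the carrier (water
#'   on-resonance at 4.7 ppm).
#'
#' @return An object of class `acq_params`.
#' @seealso [famous_protocol()] for the phantom and in-vivo presets.
#' @export
#' @examples
#' p <- acquisition_params()
#' dwell_time(p)
acquisition_params <- function(tr_ms = 3000, te_ms = 21, n_points = 4096,
                               sweep_width_hz = 6000, dummy_scans = 4,
                               averages = c(water_ref = 8L, control1 = 32L,
                                            selinv1 = 32L, control2 = 32L,
                                            selinv2 = 32L),
                               spectrometer_freq_mhz = 297.2,
                               reference_ppm = 4.7) {
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points <= 0)
    abort("`n_points` must be a single positive number.")
  if (sweep_width_hz <= 0) abort("`sweep_width_hz` must be positive.")
  if (spectrometer_freq_mhz <= 0)
    abort("`spectrometer_freq_mhz` must be positive.")
  if (tr_ms <= 0) abort("`tr_ms` must be positive.")
  if (dummy_scans < 0) abort("`dummy_scans` must be non-negative.")
  if (is.null(names(averages)) || !all(names(averages) %in% FAMOUS_BLOCKS))
    abort(paste0("`averages` must be named with a subset of: ",
                 paste(FAMOUS_BLOCKS, collapse = ", ")))
  if (any(averages < 0)) abort("average counts must be non-negative.")
  structure(
    list(tr_ms = tr_ms, te_ms = te_ms, n_points = as.integer(n_points),
         sweep_width_hz = sweep_width_hz, dummy_scans = dummy_scans,
         averages = averages,
         spectrometer_freq_mhz = spectrometer_freq_mhz,
         reference_ppm = reference_ppm),
    class = "acq_params"
  )
}

#' @export
print.acq_params <- function(x, ...) {
  cat("<acq_params> TR", x$tr_ms, "ms, TE", x$te_ms, "ms,",
      x$n_points, "pts,", x$sweep_width_hz, "Hz SW,",
      x$spectrometer_freq_mhz, "MHz\n")
  cat("  averages:", paste(names(x$averages), x$averages, sep = "=",
                           collapse = ", "),
      "| dummies:", x$dummy_scans, "\n")
  invisible(x)
}

#' Protocol presets
#'
#' The two published protocols: `"phantom"` acquires three blocks
#' (water reference, Control1, Selinv1; 4 min 12 s), `"invivo"` all five
#' (7 min 48 s).
#'
#' @param mode `"phantom"` or `"invivo"`.
#' @return An [acquisition_params()] object.
#' @export
#' @examples
#' scan_duration(famous_protocol("invivo"))
famous_protocol <- function(mode = c("invivo", "phantom")) {
  mode <- match.arg(mode)
  av <- if (mode == "phantom") {
    c(water_ref = 8L, control1 = 32L, selinv1 = 32L)
  } else {
    c(water_ref = 8L, control1 = 32L, selinv1 = 32L,
      control2 = 32L, selinv2 = 32L)
  }
  acquisition_params(averages = av)
}

#' Dwell time of an acquisition (s)
#' @param params An [acquisition_params()] object.
#' @export
dwell_time <- function(params) 1 / params$sweep_width_hz

#' Chemical-shift axis for an acquisition
#'
#' Returns the ppm coordinate of each spectral point produced by
#' [to_spectrum()], ordered by decreasing ppm (the field's plotting
#' convention). The carrier sits at `reference_ppm`; a frequency offset
#' `f` Hz maps to `reference_ppm + f / spectrometer_freq_mhz`.
#'
#' @param params An [acquisition_params()] object.
#' @return Numeric vector of length `n_points`, strictly decreasing.
#' @export
#' @examples
#' ax <- ppm_axis(acquisition_params())
#' range(ax)   # spans sweep_width_hz / spectrometer_freq_mhz ppm
ppm_axis <- function(params) {
  stopifnot(inherits(params, "acq_params"))
  f <- fft_freqs_hz(params$n_points, params$sweep_width_hz)
  params$reference_ppm +
    sort(f, decreasing = TRUE) / params$spectrometer_freq_mhz
}

# DFT bin frequencies (Hz) in fft() output order
fft_freqs_hz <- function(n, sw) {
  k <- 0:(n - 1)
  ifelse(k < ceiling(n / 2), k, k - n) * (sw / n)
}

#' Complex Lorentzian spectral density
#'
#' The frequency-domain lineshape of an exponentially decaying sinusoid.
#' With `phase = 0` the real part integrates (over all frequencies) to
#' `area` and peaks at `2 * area / (pi * fwhm)`.
#'
#' @param f Frequencies at which to evaluate (Hz).
#' @param area Integrated area of the real part at zero phase.
#' @param f0 Center frequency (Hz).
#' @param fwhm Full width at half maximum (Hz), must be positive.
#' @param phase Phase (rad).
#' @return Complex vector of spectral density values (per Hz).
#' @export
#' @examples
#' Re(lorentzian(0, area = 1, f0 = 0, fwhm = 10))  # 2 / (10 * pi)
lorentzian <- function(f, area, f0, fwhm, phase = 0) {
  if (fwhm <= 0) abort("`fwhm` must be positive.")
  (area / pi) * exp(1i * phase) / (fwhm / 2 + 1i * (f - f0))
}

#' A single resonance line
#'
#' One row of a [spectral_system()] line table. Amplitudes are carried in
#' mM-proton units (concentration times proton count), so the
#' water-referenced concentration ratio needs no hidden scale factors.
#'
#' @param center_ppm Chemical shift (ppm).
#' @param proton_amplitude Concentration x proton count (mM-protons).
#' @param fwhm_hz Lorentzian full width at half maximum (Hz).
#' @param t1_s Longitudinal relaxation time (s).
#' @param class One of `"water"`, `"metabolite"`, `"macromolecule"`.
#' @param phase_rad Intrinsic phase (rad).
#' @param label Optional line label.
#' @return A one-row tibble.
#' @export
resonance_line <- function(center_ppm, proton_amplitude, fwhm_hz, t1_s,
                           class = c("metabolite", "water", "macromolecule"),
                           phase_rad = 0, label = NA_character_) {
  class <- match.arg(class)
  if (fwhm_hz <= 0) abort("`fwhm_hz` must be positive.")
  if (t1_s <= 0) abort("`t1_s` must be positive.")
  if (proton_amplitude < 0) abort("`proton_amplitude` must be non-negative.")
  tibble(label = label, class = class, center_ppm = center_ppm,
         proton_amplitude = proton_amplitude, fwhm_hz = fwhm_hz,
         t1_s = t1_s, phase_rad = phase_rad)
}

#' Ground-truth voxel content
#'
#' Holds the resonance-line table of a simulated voxel together with its
#' tissue water fraction and the true glutamate concentration. The water
#' line carries `2 * 55510 * water_fraction` mM-protons (two protons per
#' water molecule at pure-water molarity).
#'
#' @param lines Tibble of resonance lines (rows from [resonance_line()]).
#' @param water_fraction Dimensionless tissue water content, in (0, 1].
#' @param glu_concentration_mM Scalar ground-truth glutamate concentration.
#' @return An object of class `spectral_system`.
#' @seealso [make_phantom_system()], [make_brain_system()]
#' @export
spectral_system <- function(lines, water_fraction, glu_concentration_mM) {
  if (water_fraction <= 0 || water_fraction > 1)
    abort("`water_fraction` must be in (0, 1].")
  lines <- as_tibble(lines)
  wl <- lines[lines$class == "water", ]
  if (nrow(wl) != 1) abort("exactly one water line is required.")
  expected <- 2 * WATER_MOLARITY_MM * water_fraction
  if (abs(wl$proton_amplitude - expected) > 1e-6 * expected)
    abort(sprintf(
      "water proton_amplitude must be 2 * 55510 * water_fraction = %.1f.",
      expected))
  structure(list(lines = lines, water_fraction = water_fraction,
                 glu_concentration_mM = glu_concentration_mM),
            class = "spectral_system")
}

#' @export
print.spectral_system <- function(x, ...) {
  cat("<spectral_system>", nrow(x$lines), "lines, water fraction",
      x$water_fraction, ", Glu", x$glu_concentration_mM, "mM\n")
  print(x$lines, ...)
  invisible(x)
}

#' A raw free-induction decay
#'
#' One receiver channel's complex time-domain signal. `n_averages` records
#' how many averages were summed into `samples` (scanner convention: the
#' stored FID is the sum, not the mean; [preprocess_set()] normalizes).
#'
#' @param samples Complex vector.
#' @param dwell_s Sample spacing (s).
#' @param n_averages Averages summed into this FID.
#' @param channel_index Receiver channel id.
#' @return An object of class `raw_fid`.
#' @export
raw_fid <- function(samples, dwell_s, n_averages = 1, channel_index = 1L) {
  if (dwell_s <= 0) abort("`dwell_s` must be positive.")
  if (n_averages < 0) abort("`n_averages` must be non-negative.")
  structure(list(samples = as.complex(samples), dwell_s = dwell_s,
                 n_averages = n_averages,
                 channel_index = as.integer(channel_index)),
            class = "raw_fid")
}

#' @export
print.raw_fid <- function(x, ...) {
  cat("<raw_fid>", length(x$samples), "pts, dwell", signif(x$dwell_s, 4),
      "s, ch", x$channel_index, ",", x$n_averages, "avg\n")
  invisible(x)
}

#' One FAMOUS acquisition (five labelled multi-channel FID sets)
#'
#' @param params An [acquisition_params()] object.
#' @param blocks Named list; each element is a list of [raw_fid()] objects,
#'   one per receiver channel. In-vivo sets carry all five block labels,
#'   phantom sets `water_ref`, `control1`, `selinv1`.
#' @param mode `"invivo"` or `"phantom"`.
#' @param ground_truth Optional [spectral_system()] (simulated sets).
#' @param seed Optional simulation seed, recorded for reproducibility.
#' @return An object of class `acquisition_set`.
#' @export
acquisition_set <- function(params, blocks, mode = "invivo",
                            ground_truth = NULL, seed = NULL) {
  stopifnot(inherits(params, "acq_params"))
  required <- if (mode == "phantom") PHANTOM_BLOCKS else FAMOUS_BLOCKS
  missing <- setdiff(required, names(blocks))
  if (length(missing) > 0)
    abort(paste0("missing acquisition block(s): ",
                 paste(missing, collapse = ", ")))
  nch <- unique(vapply(blocks, length, integer(1)))
  if (length(nch) != 1)
    abort("all blocks must share the same channel count.")
  for (b in names(blocks)) {
    for (fid in blocks[[b]]) {
      if (length(fid$samples) != params$n_points)
        abort(sprintf("block '%s': FID length %d != n_points %d.",
                      b, length(fid$samples), params$n_points))
    }
  }
  structure(list(params = params, blocks = blocks, mode = mode,
                 ground_truth = ground_truth, seed = seed),
            class = "acquisition_set")
}

#' @export
print.acquisition_set <- function(x, ...) {
  cat("<acquisition_set>", x$mode, "mode,",
      length(x$blocks[[1]]), "channel(s), blocks:",
      paste(names(x$blocks), collapse = ", "), "\n")
  invisible(x)
}

#' A processed frequency-domain spectrum
#'
#' @param values Complex spectral values (per Hz).
#' @param ppm_axis Chemical-shift coordinate per point (strictly
#'   decreasing).
#' @param params The owning [acquisition_params()].
#' @param provenance List recording the processing steps applied.
#' @return An object of class `processed_spectrum`.
#' @export
processed_spectrum <- function(values, ppm_axis, params,
                               provenance = list()) {
  if (length(values) != length(ppm_axis))
    abort("`values` and `ppm_axis` lengths differ.")
  d <- diff(ppm_axis)
  if (!(all(d > 0) || all(d < 0)))
    abort("`ppm_axis` must be strictly monotonic.")
  structure(list(values = as.complex(values), ppm_axis = ppm_axis,
                 params = params, provenance = provenance),
            class = "processed_spectrum")
}

#' @export
print.processed_spectrum <- function(x, ...) {
  cat("<processed_spectrum>", length(x$values), "pts,",
      signif(max(x$ppm_axis), 4), "to", signif(min(x$ppm_axis), 4), "ppm;",
      "steps:", paste(names(x$provenance), collapse = " > "), "\n")
  invisible(x)
}

#' @export
as_tibble.processed_spectrum <- function(x, ...) {
  tibble(ppm = x$ppm_axis, real = Re(x$values), imag = Im(x$values))
}
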
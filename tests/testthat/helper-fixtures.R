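# shared fixtures: designed once, reused across test files
FSI <- design_fsi_pulse()
IR <- optimize_double_ir_delays()
PARAMS_PH <- famous_protocol("phantom")
PARAMS_IV <- famous_protocol("invivo")

quiet_artifacts <- function(seed = NULL, ...) {
  artifact_model(noise_sigma = 0, seed = seed, ...)
}

one_channel <- function() tibble::tibble(gain = 1, phase_rad = 0)

# noise-free phantom acquisition at a given concentration
phantom_acq <- function(conc, artifacts = quiet_artifacts(), ...) {
  simulate_acquisition(make_phantom_system(conc, ...), PARAMS_PH,
                       artifacts, FSI, IR, mode = "phantom")
}

# a synthetic FID holding one decaying complex sinusoid
line_fid <- function(params, offset_hz, amp = 1, fwhm_hz = 15, phase = 0,
                     n_averages = 1) {
  t <- (0:(params$n_points - 1)) * dwell_time(params)
  raw_fid(amp * exp(1i * phase + 2i * pi * offset_hz * t -
                      pi * fwhm_hz * t),
          dwell_time(params), n_averages = n_averages)
}
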
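# Shared fixtures: ideal (artefact-free) and study-like noise settings, and
# a short 3-sweep protocol for tests that only need the mandatory voltages.

clean_noise <- function(leak = 0, leak_offset = 0, tau = Inf) {
  noise_model(gaussian_sd_pA = 0, leak_conductance_pA_per_mV = leak,
              leak_offset_pA = leak_offset, rundown_tau_sweeps = tau,
              patch_amplitude_cv = 0, offset_range_mV = 0)
}

study_noise <- function(sd = 10) {
  noise_model(gaussian_sd_pA = sd, leak_conductance_pA_per_mV = 0.05,
              leak_offset_pA = 0, rundown_tau_sweeps = 20,
              patch_amplitude_cv = 0.3, offset_range_mV = 3)
}

minimal_protocol <- function(...) {
  step_protocol(test_voltages_mV = c(-100, 100, 120), ...)
}

wt_params <- function() calibrate_amplitude(barrier_params())
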
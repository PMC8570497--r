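# Shared fixtures: small, fast study-like objects built in code.

# default juvenile-calyx circuit: tau_cl = 10 us
fix_params <- function(g_cl = 1e-6, c_cl = 10e-12, ...) {
  circuit_params(c_cl = c_cl, g_cl = g_cl, ...)
}

# a short APW train protocol for unit tests (the full study protocol of
# 45 stimuli is exercised in the acceptance suite)
fix_protocol <- function(n = 12L, interval = 10e-3, decay = 1, broad = 1) {
  train_protocol(n_stimuli = n, interval = interval,
                 amplitude_decay = decay, broadening = broad)
}

fix_recording <- function(scenario = "resistive", noise_sd = 0, seed = 1,
                          params = fix_params(), n = 12L, dt = 20e-6, ...) {
  synthesize_p5_recording(shape = ap_shape(), protocol = fix_protocol(n = n),
                          params = params, scenario = scenario,
                          noise_sd = noise_sd, seed = seed, dt = dt, ...)
}

# single-epoch Gaussian calcium current fixture
fix_ca <- function(amplitude = -2e-9, tau_ca = 0.25e-3, dt = 5e-6,
                   t_peak = 2e-3, duration = 4e-3) {
  make_calcium_current(amplitude, t_peak, tau_ca, dt, duration)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
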
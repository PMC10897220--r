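# Shared fixtures: a reduced session design and quick simulated datasets.

# one session, one band, modest trial count: fast but realistic
tiny_design <- function(n_per_noise = 200, bands = "lsf") {
  design_spec(n_sessions = 1, n_no_noise = 0, n_per_noise = n_per_noise,
              noise_bands = bands)
}

flat_observer <- function(d_base = 1.8) null_observer(d_base = d_base, lapse = 0)

# observer with a single strong transient dip and nothing else
dip_only_observer <- function(depth = 1.2, center = 220) {
  observer_params(dip_depth = c(lsf = depth, msf = 0, hsf = 0),
                  dip_center_ms = c(lsf = center, msf = 185, hsf = 190),
                  osc_amp = 0, simultaneity_cost = 0, lapse = 0)
}

# observer with a pure periodic masking modulation
osc_only_observer <- function(amp = 0.8, freq = 5) {
  observer_params(dip_depth = 0,
                  osc_freq_hz = c(lsf = freq, msf = freq, hsf = freq),
                  osc_amp = c(lsf = amp, msf = 0, hsf = 0),
                  simultaneity_cost = 0, lapse = 0)
}

expect_tibble_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
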
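# shared builders for the test suite

ust_band <- function() transducer_band(22e6, 78e6)

# low-frequency transducer for cheap records sampled at 25 MS/s
lf_transducer <- function() transducer_model(transducer_band(2e6, 12e6))

soft_tissue <- function() medium(1500)

# single-wavelength scheme mirroring laser 1 of the reference system
single_laser <- function(n_pulses = 50) {
  fwm_scheme(200e3, 0, 1, n_pulses = n_pulses, pulse_width = 6.7e-9,
             pulse_energy = 189e-9)
}

# one absorber per wavelength at distinct depths, each lit by exactly one
# wavelength, so cross-talk is directly measurable
disjoint_phantom <- function(n = 4) {
  lapply(seq_len(n), function(j)
    absorber(j * 1e-3, per_wavelength_amplitude = as.numeric(seq_len(n) == j)))
}

# expected arrival windows (one-way delay +- half_width) per absorber
arrival_windows <- function(n = 4, vs = 1500, half_width = 0.3e-6) {
  lapply(seq_len(n), function(j) {
    d <- j * 1e-3 / vs
    c(d - half_width, d + half_width)
  })
}
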
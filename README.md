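# fwmot

Signal processing for **frequency-wavelength-multiplexed optoacoustic
(photoacoustic) tomography**: design calculators, a forward simulator,
frequency-comb demultiplexing, delay-and-sum B-scan reconstruction and
dual-wavelength oxygenation read-outs, for anyone building or analysing
pulse-train optoacoustic systems — instrument developers sizing a
multi-wavelength design, and analysts processing (or emulating)
single-channel acquisition records.

## The idea

A train of `N_p` nanosecond optical pulses at repetition rate `f_rep`
generates ultrasound only at the harmonics `k·f_rep` — a frequency comb.
The averaged one-period signal is recovered in the Fourier domain by
keeping the comb and discarding everything else,

    S_a(ω) = S_r(ω) · Σ_{k=1..N_h} δ(ω − k·ω₀),   ω₀ = 2π·f_rep,

which is equivalent to time-domain period averaging and improves SNR by
`√N_p`. Pulsing laser `j` at the slightly shifted rate
`f_rep,j = f_rep,1 + (j−1)·δf` interleaves disjoint combs, so several
wavelengths fire **concurrently** and are separated afterwards by
projecting the record onto each laser's comb — no compromise on depth of
view (`DoV = v_s·T`), SNR, or acquisition time, where time-domain
interleaving must sacrifice one of the three. The admissible shift range
follows from the spectral resolution `df = 1/t_acq`:

    δf_min = df / k_low,    δf_max = (f_rep,1 − df) / (k_high·(N − 1)),

with `k_low..k_high` the in-band harmonic indices of the ultrasound
transducer. These bounds give the multiplexing capacity: 28 wavelengths
at the reference design point (200 kHz, 100 pulses, 22–78 MHz band)
versus 5 for time interleaving at 1.5 mm depth of view per wavelength.

## Worked example

Design check, then a four-wavelength simulated acquisition with one
absorber per wavelength, demultiplexed and scored:

```r
library(fwmot)

design_limits(200e3, 100, 4, transducer_band(22e6, 78e6))
#> Design limits (f_rep,1 = 200000 Hz, N_p = 100, N = 4):
#>   DoV 7.5 mm | t_acq 0.5 ms | df 2000 Hz
#>   in-band harmonics k = 110..390 (281 lines)
#>   delta_f in [18.18, 169.2] Hz (feasible)
#>   N_p,min 12 | capacity: 28 wavelengths (FWM), 5 (TD)

sc <- reference_scheme()           # 4 diodes, delta_f = 125 Hz
phantom <- lapply(1:4, function(j)
  absorber(j * 1e-3, per_wavelength_amplitude = as.numeric(1:4 == j)))
rec <- simulate_record(sc, phantom, transducer_model(),
                       noise_model(white_noise_std = 1e-3,
                                   emi_amplitude = 5e-4, seed = 11),
                       medium(), 200e6)
rec
#> Acquisition record: 101937 samples @ 200 MS/s (0.5097 ms), 4 wavelength(s)

ascans <- demux_all(rec)           # one A-scan per wavelength
wins <- lapply(1:4, function(j) {
  d <- j * 1e-3 / 1500; c(d - 0.3e-6, d + 0.3e-6)
})
measure_snr(ascans[[1]], wins[[1]], c(3.5e-6, 4.8e-6))
#> SNR: S = 1.571 V, N = 0.0001604 V -> 39.9 dB

round(crosstalk_db(ascans, wins), 1)
#>       [,1]  [,2]  [,3]  [,4]
#> [1,]   0.0 -24.5 -25.4 -28.2
#> [2,] -29.3   0.0 -25.7 -26.7
#> [3,] -35.1 -29.5   0.0 -25.3
#> [4,] -33.5 -30.8 -27.0   0.0
```

Each wavelength sees its own absorber (diagonal) while every other
wavelength's absorber stays below −24 dB — i.e. each A-scan is recovered
without material cross-talk even though all four lasers fired into one
channel simultaneously.

A command-line front end wrapping the same functions ships in
`inst/cli/fwmot.R` (subcommands `design`, `simulate`, `demux`, `recon`,
`analyze`, `fixtures`); `simulate | demux | recon` compose through files
alone.

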
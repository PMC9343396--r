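---
title: "Frequency-wavelength multiplexing of optoacoustic pulse trains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-wavelength multiplexing of optoacoustic pulse trains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwmot)
```

## The signal model

A train of $N_p$ short optical pulses at repetition rate $f_{rep}$
deposits energy transients that generate ultrasound only at the discrete
harmonics $k f_{rep}$ of the repetition rate — a frequency comb under the
envelope of a single pulse's spectrum, whose first node sits at
$1/t_p$ for pulse width $t_p$.  All other frequencies of the recorded
voltage trace $S_r(t)$ carry noise only.  The one-period averaged signal
can therefore be recovered in the Fourier domain by keeping the comb and
discarding everything else,

$$S_a(\omega) = S_r(\omega)\sum_{k=1}^{N_h}\delta(\omega - k\,\omega_0),
\qquad \omega_0 = 2\pi f_{rep},$$

which is numerically identical to splitting the record into $N_p$
sections of one period $T = 1/f_{rep}$ and averaging them point by
point; both routes improve the SNR by $\sqrt{N_p}$ on white noise.  The
package implements both (`td_average()`, `comb_filter()`) and the test
suite asserts their equality to $10^{-9}$ relative on integer-period
records.

The multiplexing idea follows from the comb picture: giving laser $j$
the slightly shifted repetition rate $f_{rep,j} = f_{rep,1} +
(j-1)\,\delta f$ interleaves $N$ disjoint combs in frequency, so all
wavelengths can fire concurrently — no depth-of-view, SNR or
acquisition-time sacrifice — and are separated afterwards by evaluating
the comb projection at each laser's own $\omega_0$.  Time-domain
alternatives must compromise one of the three: interleaving pulses
within the period divides the per-wavelength depth of view $DoV = v_s T$
by $N$; dropping the rate and pulse count to $f_{rep}/N$, $N_p/N$ costs
$\sqrt N$ in SNR; keeping the pulse count at the reduced rate costs $N$
in acquisition time (`scheme_tradeoffs()`).

## Design arithmetic

With the signal processed over the acquisition time
$t_{acq} = N_p/f_{rep,1}$, comb lines closer than the spectral
resolution $df = 1/t_{acq}$ are unresolvable.  Writing $(k_{low},
k_{high})$ for the first and last harmonic index inside the transducer
band $[f_{low}, f_{high}]$ (band edges inclusive), the admissible shift
range is

$$\delta f_{min} = \frac{df}{k_{low}}, \qquad
  \delta f_{max} = \frac{f_{rep,1} - df}{k_{high}\,(N-1)}:$$

below $\delta f_{min}$ adjacent lasers collide at the bottom of the
band, above $\delta f_{max}$ laser $N$'s $k$-th harmonic collides with
laser 1's $(k{+}1)$-th at the top.  Feasibility is
$\delta f_{min} \le \delta f_{max}$ with ties allowed.  The closed form
uses laser 1's harmonic index range for every laser (the shift is
orders of magnitude below $f_{rep,1}$, so the index drift is
negligible); an independent brute-force validator
(`comb_lines_separated()`) instead enumerates every laser's true comb
and checks all pairwise spacings against $df$, and the test suite holds
the two accountable to each other across a grid of configurations.
Wavelength capacity (`max_wavelengths_fwm()`) is the largest feasible
$N$ by linear scan — 28 at the reference design point
($f_{rep,1} = 200$ kHz, $N_p = 100$, 22–78 MHz band) against 5 for
time interleaving with 1.5 mm of depth per wavelength — and
`min_pulses()` is the least $N_p$ by scan from 1.  One consequence the
closed form makes explicit: *narrowing* the band relaxes the constraint
set (fewer in-band lines), so capacity grows as the band shrinks and
saturates at $N_p$ when a single harmonic remains; capacity is
monotone non-decreasing in $N_p$.

All design quantities are plain arithmetic on scalars
(`depth_of_view()`, `acquisition_time()`, `frequency_resolution()`,
`harmonic_indices()`, `exposure()`, `snr_db()`, `averaging_gain_db()`),
aggregated by `design_limits()`.  The speed of sound defaults to
1500 m/s — the soft-tissue value consistent with a 7.5 mm depth of view
at 200 kHz — and is configurable everywhere.  SNR follows the
convention $10\log_{10}(S/N)$ with $S$ a signal intensity and $N$ the
noise-floor standard deviation; the same $10\log_{10}$ convention is
applied to the cross-talk matrix of amplitude ratios, so $-20$ dB
corresponds to an amplitude ratio of $10^{-2}$.

## The forward simulator

`simulate_record()` emulates the single-channel acquisition so that
every downstream stage is testable without hardware.  Its components:

* **Acoustic wavelet.** Each absorber returns a band-limited bipolar
  wavelet delayed by its distance over $v_s$.  The wavelet is a
  Gaussian-windowed cosine at the transducer's centre frequency whose
  magnitude spectrum falls to one half at the band edges, i.e. exactly
  the `gaussian_bandpass` response of the transducer model (50 MHz
  centre, 112% fractional bandwidth by default).  A first-derivative-
  of-Gaussian shape was considered and rejected: its spectrum
  ($\propto f e^{-(2\pi f\sigma)^2/2}$) neither matches a symmetric
  bandpass nor decays fast enough above Nyquist at 200 MS/s.
* **Exact-time evaluation.** Wavelets are evaluated analytically at the
  exact sample instants of each arrival rather than shifted on the
  sample grid.  This matters: grid-shifting by interpolation modulates
  each pulse by its fractional sample offset, and for lasers whose
  period is a non-integer number of samples that modulation puts
  sidebands *between* the combs — an artifact of the implementation,
  not of the physics.
* **Anti-aliasing front end.** The deterministic signal is synthesized
  on a 2$\times$ oversampled grid, brick-wall low-passed below the
  output Nyquist frequency and decimated, mirroring the analog
  filtering a real receive chain applies before digitization.  Without
  it, wavelet energy above Nyquist folds onto frequencies between the
  combs and reappears as irreducible cross-talk.
* **Artifacts.** Each trigger injects an exponentially damped EMI
  sinusoid (driver interference, mid-band ring frequency by default so
  it overlaps the signal); absorbers may carry delayed reflection
  echoes; white Gaussian noise is added last.  Per-pulse energy jitter
  is multiplicative log-normal with a stated coefficient of variation,
  timing jitter additive Gaussian, and both draws are stored with the
  record as the simulated photodiode reference that
  `correct_pulse_variations()` consumes.  Everything is reproducible
  from the integer seed; identical seeds give bit-identical records.
* **Scanning.** `make_bscan()` moves the detector across strictly
  increasing lateral positions, computes Euclidean-distance delays and
  restricts sensitivity to a cone about the axis (half-angle from the
  transducer model, apex at the detector plane, uniform weight inside
  — the two-dimensional conic-section approximation).  DAQ bit
  quantization is not modelled; amplitudes are continuous.

What the simulator does **not** emulate: acoustic attenuation and
dispersion, speed-of-sound heterogeneity, laser pulse shape beyond its
energy, transducer focusing diffraction, and any tissue motion.
Passing tests therefore demonstrate the correctness of the signal
processing under the stated model, not instrument-grade performance on
real tissue.

## Demultiplexing

`comb_filter()` projects the record onto $\{\cos, \sin\}$ pairs at the
exact frequencies $k f_{rep,j}$ by per-frequency least squares (the
2$\times$2 normal equations), walking the harmonic ladder with an
iterated complex phasor so no large design matrix is formed.  Exact
frequencies matter because with $N_{p,1} = 100$ and $N_{p,j} = 101$ the
record is an integer number of periods for at most one laser, so
harmonics fall between FFT bins; a nearest-FFT-bin mode is retained as
the fast option.  DC is excluded throughout (the receive chain is
AC-coupled and the comb sum starts at $k = 1$).

`demux_all()` adds two things on top:

* **Analysis window.** Projection is restricted to the common overlap
  of all lasers' train durations.  Inside that window every laser's
  contribution is exactly periodic; outside it, train edges (lasers
  with different pulse counts stop at different times) are transients
  the comb model cannot represent, and their leakage between lasers
  dominates the cross-talk budget if left in.  Each wavelength's
  A-scan is then synthesized over one period aligned to its own first
  trigger.
* **Joint least squares by block coordinate descent.** Separating $N$
  interleaved combs exactly is one joint least-squares problem over
  all lasers' harmonics.  Solving it directly is quadratic in the
  total harmonic count, so the solver sweeps laser by laser,
  re-projecting each against the record minus the synthesized
  contributions of the others.  Because an admissible $\delta f$
  guarantees comb-line spacing of at least $df$, the blocks are weakly
  coupled and one sweep (the default, `refine = 1`) already drops the
  residual finite-record leakage well below $-20$ dB; `refine = 0`
  recovers the plain independent projection.

The default harmonic set is every sub-Nyquist harmonic of each laser,
which models the record completely; a band-restricted mode
(`band = transducer_band(...)`) mirrors an analysis confined to the
transducer bandwidth at the cost of mild truncation ringing of the
wavelet.  Harmonics at or above Nyquist are refused.  When the scheme's
$\delta f$ lies outside the admissible range the function warns and
proceeds, since cross-talk is then expected rather than an error.

Numerical details: the per-frequency normal equations fall back to the
cosine-only solution when the 2$\times$2 determinant vanishes (a
harmonic at Nyquist); `td_average()` resamples non-integer
samples-per-period sections onto a common grid by linear interpolation
rather than truncating; band-edge harmonic indices are computed with a
$10^{-9}$ relative tolerance so edge harmonics are classified
deterministically.

## Reconstruction and read-outs

`backproject()` is plain time-domain delay-and-sum: each pixel averages
the A-scan amplitudes at delay $\sqrt{(x - x_p)^2 + z^2}/v_s$ over the
scan positions whose acceptance cone contains the pixel, with linear
interpolation between time samples and zero contribution outside the
recorded window.  A Fourier-domain implementation would be faster but
adds nothing for validation purposes; impulse-response deconvolution
and vesselness display filtering are out of scope, with per-column
analytic-signal envelopes (`envelope_image()`) standing in for display
processing.  Pixel indices are 0-based in the axes vectors' terms,
depth is one-way from the detector plane.

`ratio_series()` and `oer_series()` implement the oxygenation
read-outs: the wavelength-2 over wavelength-1 signal ratio $S_2/S_1$
tracks relative oxygen saturation (no absolute saturation is estimated
— only relative changes are claimed), and the oxygen extraction rate is
$(O_{ca} - O_{cv})/O_{ca}$ for artery/vein oxygenation.  The ratio
masks samples whose denominator falls below 5% of its series maximum —
a floor chosen once to keep noise-only frames from exploding the ratio.
`assign_channels()` is a pure relabelling of the four demultiplexed
channels to Hb / HbO2 / Evans Blue / ICG following the four-diode
convention.

## Problem sizes and defaults

The reference configuration (`reference_scheme()`) is the four-diode
operating point: 444.3/460.1/636.8/804.9 nm, pulse widths
6.7/6.7/10.2/10.2 ns, rates 200,000/200,125/200,250/200,375 Hz
($\delta f = 125$ Hz, inside the admissible 18.2–169.2 Hz), energies
189/137/142/153 nJ, pulse counts 100/101/101/101, sampled at 200 MS/s.
Simulation-based tests run this configuration directly (about $10^5$
samples per record); Monte-Carlo properties (the $\sqrt{N_p}$ SNR
scaling) use synthetic white-noise records of $10^2$–$10^4$ periods at
reduced sampling rates, sizes chosen to estimate the scaling exponent
to a few percent.  B-scan validation uses 21 positions at a 50 µm step
over a point target at 2 mm depth — small enough to run routinely,
large enough that a one-grid-cell localization error would be visible.

## Known limitations

* The $\delta f$ bounds use laser 1's harmonic index range for all
  lasers; for shifts comparable to $f_{rep}$ (far outside the intended
  $\delta f \ll f_{rep}$ regime) the closed form and the brute-force
  enumerator may diverge — the enumerator is authoritative there.
* Block coordinate descent converges slowly if combs are closer than
  $df$ (inadmissible $\delta f$); the warning path leaves the
  cross-talk in place rather than iterating further.
* Persistence uses R's native serialization with an explicit format
  version; records are therefore not portable to other languages
  without re-export (CSV paths are provided by the CLI).
* The oxygenation read-outs are ratios of raw signal intensities;
  wavelength-dependent fluence differences are not corrected, exactly
  as in the relative-change claim they implement.
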
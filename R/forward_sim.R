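# Forward simulation: excitation patterns and single-channel optoacoustic
# acquisition records (absorber wavelets, transducer band-limiting, EMI
# ringing, reflections, white noise, per-pulse energy/timing jitter).

#' Point/line absorber for the forward simulator
#'
#' @param depth Depth along the acoustic axis in metres.
#' @param lateral_position Lateral position in metres (used by B-scans).
#' @param per_wavelength_amplitude Dimensionless absorption weight per
#'   wavelength (recycled to the scheme's wavelength count when simulated).
#' @param reflection_delay Optional extra delay of an echo of the primary
#'   signal (seconds), e.g. a reverberation in the sample holder or the
#'   transducer lens; \code{NULL} for none.
#' @param reflection_gain Echo amplitude relative to the primary signal,
#'   in [0, 1).
#' @return An object of class \code{"absorber"}.
#' @examples
#' absorber(2e-3, per_wavelength_amplitude = c(1, 0, 0, 0))
#' @export
absorber <- function(depth, lateral_position = 0,
                     per_wavelength_amplitude = 1,
                     reflection_delay = NULL, reflection_gain = 0) {
  stopifnot(depth >= 0, all(per_wavelength_amplitude >= 0),
            reflection_gain >= 0, reflection_gain < 1)
  if (!is.null(reflection_delay)) stopifnot(reflection_delay > 0)
  structure(
    list(depth = depth, lateral_position = lateral_position,
         per_wavelength_amplitude = per_wavelength_amplitude,
         reflection_delay = reflection_delay,
         reflection_gain = reflection_gain),
    class = "absorber"
  )
}

#' Transducer model for the forward simulator and reconstruction
#'
#' @param band A \code{\link{transducer_band}}.  Default: 50 MHz centre,
#'   112\% fractional bandwidth.
#' @param focal_length Focal length in metres.
#' @param acceptance_half_angle Half-angle of the sensitivity cone in
#'   radians (must lie in (0, pi/2)).
#' @return An object of class \code{"transducer_model"}.
#' @export
transducer_model <- function(band = transducer_band(center = 50e6,
                                                    fractional_bandwidth = 1.12),
                             focal_length = 3e-3,
                             acceptance_half_angle = 0.5) {
  stopifnot(inherits(band, "transducer_band"), focal_length > 0,
            acceptance_half_angle > 0, acceptance_half_angle < pi / 2)
  structure(
    list(band = band, impulse_response_kind = "gaussian_bandpass",
         focal_length = focal_length,
         acceptance_half_angle = acceptance_half_angle),
    class = "transducer_model"
  )
}

#' Noise and artifact model for the forward simulator
#'
#' @param white_noise_std Standard deviation of additive white Gaussian
#'   noise (volts).
#' @param emi_amplitude Amplitude of the electromagnetic-interference
#'   ringing radiated by the laser-driver circuitry at each trigger
#'   (volts).
#' @param emi_ring_frequency Ring frequency of the EMI transient (Hz).
#' @param emi_decay Exponential decay time of the EMI transient (s).
#' @param energy_jitter_cv Coefficient of variation of the multiplicative
#'   (log-normal) pulse-to-pulse energy fluctuation.
#' @param timing_jitter_std Standard deviation of per-pulse timing jitter
#'   (s).
#' @param seed Integer seed fixing every stochastic draw of a simulation.
#' @return An object of class \code{"noise_model"}.
#' @export
noise_model <- function(white_noise_std = 0, emi_amplitude = 0,
                        emi_ring_frequency = 50e6, emi_decay = 50e-9,
                        energy_jitter_cv = 0, timing_jitter_std = 0,
                        seed = 1L) {
  stopifnot(white_noise_std >= 0, emi_amplitude >= 0,
            emi_ring_frequency > 0, emi_decay > 0,
            energy_jitter_cv >= 0, timing_jitter_std >= 0)
  structure(
    list(white_noise_std = white_noise_std, emi_amplitude = emi_amplitude,
         emi_ring_frequency = emi_ring_frequency, emi_decay = emi_decay,
         energy_jitter_cv = energy_jitter_cv,
         timing_jitter_std = timing_jitter_std, seed = as.integer(seed)),
    class = "noise_model"
  )
}

# trigger instants of one train: t_sh + k/f_rep, k = 0..N_p-1
.trigger_times <- function(train) {
  train$start_offset + (seq_len(train$n_pulses) - 1) / train$rep_rate
}

#' Sampled optical power series of every train in a scheme
#'
#' Rectangular pulses of width \code{pulse_width} at the train's trigger
#' instants, scaled so the energy of each pulse equals
#' \code{pulse_energy} (power = energy / width while the pulse is on).
#' The power spectrum of such a train is a comb at multiples of the
#' repetition rate under a sinc-squared envelope with first node at
#' \code{1/pulse_width}.
#'
#' @param scheme A \code{\link{multiplex_scheme}}.
#' @param sampling_rate Sampling rate in Hz; must place at least 4 samples
#'   across each pulse.
#' @param duration Series duration in seconds (default: longest train
#'   duration plus one period).
#' @return List with \code{time} (seconds) and \code{power}, a matrix with
#'   one column per wavelength (watts).
#' @export
build_excitation <- function(scheme, sampling_rate, duration = NULL) {
  stopifnot(inherits(scheme, "multiplex_scheme"), sampling_rate > 0)
  widths <- vapply(scheme$trains, `[[`, numeric(1), "pulse_width")
  if (any(sampling_rate * widths < 4))
    stop("sampling_rate must place at least 4 samples per pulse width",
         call. = FALSE)
  if (is.null(duration)) {
    duration <- max(vapply(scheme$trains, function(tr)
      tr$start_offset + tr$n_pulses / tr$rep_rate, numeric(1))) +
      1 / scheme$ref_rep_rate
  }
  n <- round(duration * sampling_rate)
  tt <- (seq_len(n) - 1) / sampling_rate
  power <- matrix(0, n, length(scheme$trains))
  for (j in seq_along(scheme$trains)) {
    tr <- scheme$trains[[j]]
    p_on <- if (tr$pulse_energy > 0) tr$pulse_energy / tr$pulse_width else 1
    for (t0 in .trigger_times(tr)) {
      # sample i is on iff t0 <= (i-1)/fs < t0 + t_p, evaluated in sample
      # units with a small tolerance so grid-aligned edges are exact
      n_lo <- ceiling(t0 * sampling_rate - 1e-6)
      n_hi <- ceiling((t0 + tr$pulse_width) * sampling_rate - 1e-6) - 1
      idx <- (max(0, n_lo):min(n - 1, n_hi)) + 1L
      power[idx, j] <- power[idx, j] + p_on
    }
  }
  list(time = tt, power = power)
}

# Band-limited bipolar wavelet modelling the transducer's gaussian
# bandpass response: a Gaussian-windowed cosine at the band centre whose
# magnitude spectrum exp(-(f - f_c)^2 / (2 sigma_f^2)) falls to one half
# at the band edges (sigma_f = half-bandwidth / sqrt(2 ln 2)).  The
# wavelet is evaluated analytically at the exact sample times of each
# arrival, never shifted on the grid, so a periodic pulse train produces
# an exactly periodic continuous-time signal whose sampled spectrum is a
# clean comb.
.wavelet_params <- function(transducer) {
  band <- transducer$band
  sigma_f <- (band$f_high - band$f_low) / 2 / sqrt(2 * log(2))
  list(fc = band$center, sigma_t = 1 / (2 * pi * sigma_f))
}

# accumulate wavelets arriving at times 'arrivals' (seconds) with
# amplitudes 'amps' into the record x sampled at fs; support +-5 sigma
.add_wavelets <- function(x, arrivals, amps, wp, fs) {
  half <- 5 * wp$sigma_t
  l <- ceiling(2 * half * fs) + 1L
  i0 <- floor((arrivals - half) * fs) + 1L
  idx <- outer(i0, 0:(l - 1L), `+`)
  tau <- (idx - 1) / fs - arrivals
  val <- amps * cos(2 * pi * wp$fc * tau) * exp(-tau^2 / (2 * wp$sigma_t^2))
  keep <- idx >= 1L & idx <= length(x)
  ii <- idx[keep]
  x[ii] <- x[ii] + val[keep]
  x
}

# anti-aliasing decimation: zero-pad to a highly composite length,
# brick-wall low-pass strictly below the output Nyquist rate, decimate
.decimate_antialias <- function(x, os, n_out) {
  n_int <- length(x)
  n_pad <- stats::nextn(n_int, c(2L, 3L, 5L))
  xp <- c(x, numeric(n_pad - n_int))
  X <- stats::fft(xp)
  freq_bin <- seq_len(n_pad) - 1L
  freq <- pmin(freq_bin, n_pad - freq_bin) / n_pad  # cycles per sample
  X[freq >= 0.5 / os] <- 0
  xf <- Re(stats::fft(X, inverse = TRUE)) / n_pad
  xf[seq.int(1L, by = os, length.out = n_out)]
}

# accumulate exponentially damped EMI sinusoids starting at 'starts'
.add_emi <- function(x, starts, noise, fs) {
  l <- ceiling(6 * noise$emi_decay * fs) + 1L
  i0 <- floor(starts * fs) + 1L
  idx <- outer(i0, 0:(l - 1L), `+`)
  tau <- (idx - 1) / fs - starts
  val <- noise$emi_amplitude * exp(-tau / noise$emi_decay) *
    sin(2 * pi * noise$emi_ring_frequency * tau)
  val[tau < 0] <- 0
  keep <- idx >= 1L & idx <= length(x)
  ii <- idx[keep]
  x[ii] <- x[ii] + val[keep]
  x
}

#' Simulate a single-channel optoacoustic acquisition record
#'
#' For every laser pulse and every absorber a band-limited bipolar wavelet
#' is added at \code{trigger + depth / v_s}, scaled by the absorber's
#' per-wavelength weight times the pulse energy (with optional
#' multiplicative log-normal energy jitter and additive Gaussian timing
#' jitter).  Each trigger also injects an exponentially damped EMI
#' sinusoid; absorbers may add delayed reflection echoes; white Gaussian
#' noise is added last.  Fully deterministic given the noise model's seed.
#'
#' @param scheme A \code{\link{multiplex_scheme}}.
#' @param phantom List of \code{\link{absorber}} objects (may be empty for
#'   a noise-only record).
#' @param transducer A \code{\link{transducer_model}}.
#' @param noise A \code{\link{noise_model}}.
#' @param medium A \code{\link{medium}}.
#' @param sampling_rate Sampling rate in Hz; must satisfy Nyquist for the
#'   transducer band (\code{>= 2 f_high}).
#' @param duration Record duration in seconds (default: longest train
#'   duration plus one reference period).
#' @param detector_position Lateral detector coordinate in metres; the
#'   acoustic delay of an absorber is its Euclidean distance to the
#'   detector over \code{v_s}, and absorbers outside the acceptance cone
#'   contribute nothing.  Default 0 with an unrestricted cone (plain
#'   depth-only delays) unless \code{use_cone = TRUE}.
#' @param use_cone Restrict sensitivity to the transducer's acceptance
#'   cone (used by \code{\link{make_bscan}}).
#' @param anti_alias Model the analog anti-aliasing front end: the
#'   deterministic signal is synthesized on a 2x oversampled grid,
#'   low-passed below the output Nyquist frequency and decimated, so
#'   wavelet energy above Nyquist does not fold back into the record
#'   (the real receive chain low-pass filters before digitization).
#' @return An object of class \code{"acquisition_record"}: list with
#'   \code{samples}, \code{sampling_rate}, \code{duration}, \code{scheme},
#'   \code{trigger_times} (per-laser list), and the per-pulse
#'   \code{energy_factors} / \code{timing_offsets} actually drawn (the
#'   simulated photodiode reference used by
#'   \code{\link{correct_pulse_variations}}).
#' @examples
#' sc <- fwm_scheme(200e3, 0, 1, n_pulses = 4)
#' rec <- simulate_record(sc, list(absorber(2e-3)), transducer_model(),
#'                        noise_model(seed = 7), medium(), 200e6)
#' @export
simulate_record <- function(scheme, phantom, transducer = transducer_model(),
                            noise = noise_model(), medium = fwmot::medium(),
                            sampling_rate = 200e6, duration = NULL,
                            detector_position = 0, use_cone = FALSE,
                            anti_alias = TRUE) {
  stopifnot(inherits(scheme, "multiplex_scheme"),
            inherits(transducer, "transducer_model"),
            inherits(noise, "noise_model"))
  if (sampling_rate < 2 * transducer$band$f_high)
    stop("sampling_rate violates Nyquist for the transducer band",
         call. = FALSE)
  vs <- medium$speed_of_sound
  if (is.null(duration)) {
    duration <- max(vapply(scheme$trains, function(tr)
      tr$start_offset + tr$n_pulses / tr$rep_rate, numeric(1))) +
      1 / scheme$ref_rep_rate
  }
  n <- round(duration * sampling_rate)
  os <- if (anti_alias) 2L else 1L
  fs_int <- os * sampling_rate
  x <- numeric(n * os)
  wp <- .wavelet_params(transducer)

  set.seed(noise$seed)
  trig <- lapply(scheme$trains, .trigger_times)
  energy_factors <- vector("list", length(trig))
  timing_offsets <- vector("list", length(trig))

  for (j in seq_along(scheme$trains)) {
    tr <- scheme$trains[[j]]
    tj <- trig[[j]]
    np <- length(tj)
    ef <- if (noise$energy_jitter_cv > 0) {
      sdl <- sqrt(log(1 + noise$energy_jitter_cv^2))
      exp(stats::rnorm(np, -sdl^2 / 2, sdl))
    } else rep(1, np)
    to <- if (noise$timing_jitter_std > 0)
      stats::rnorm(np, 0, noise$timing_jitter_std) else rep(0, np)
    energy_factors[[j]] <- ef
    timing_offsets[[j]] <- to
    tj_eff <- tj + to
    escale <- if (tr$pulse_energy > 0) tr$pulse_energy / 1e-7 else 1

    for (ab in phantom) {
      amp_w <- rep_len(ab$per_wavelength_amplitude, length(scheme$trains))[j]
      if (amp_w == 0) next
      dx <- ab$lateral_position - detector_position
      dist <- sqrt(dx^2 + ab$depth^2)
      if (use_cone) {
        # sensitivity cone about the axis, apex at the detector plane
        if (ab$depth <= 0 ||
            abs(dx) > ab$depth * tan(transducer$acceptance_half_angle))
          next
      }
      delay <- dist / vs
      amps <- amp_w * escale * ef
      x <- .add_wavelets(x, tj_eff + delay, amps, wp, fs_int)
      if (!is.null(ab$reflection_delay) && ab$reflection_gain > 0) {
        x <- .add_wavelets(x, tj_eff + delay + ab$reflection_delay,
                           amps * ab$reflection_gain, wp, fs_int)
      }
    }

    if (noise$emi_amplitude > 0) {
      x <- .add_emi(x, tj_eff, noise, fs_int)
    }
  }

  if (os > 1L) x <- .decimate_antialias(x, os, n)

  if (noise$white_noise_std > 0)
    x <- x + stats::rnorm(n, 0, noise$white_noise_std)

  structure(
    list(samples = x, sampling_rate = sampling_rate, duration = duration,
         scheme = scheme, trigger_times = trig,
         energy_factors = energy_factors, timing_offsets = timing_offsets,
         seed = noise$seed),
    class = "acquisition_record"
  )
}

#' @export
print.acquisition_record <- function(x, ...) {
  cat(sprintf(
    "Acquisition record: %d samples @ %.4g MS/s (%.4g ms), %d wavelength(s)\n",
    length(x$samples), x$sampling_rate / 1e6, x$duration * 1e3,
    length(x$trigger_times)))
  invisible(x)
}

#' @export
plot.acquisition_record <- function(x, ...) {
  tt <- (seq_along(x$samples) - 1) / x$sampling_rate
  graphics::plot(tt * 1e6, x$samples, type = "l", xlab = "time (us)",
                 ylab = "voltage (V)", ...)
  invisible(x)
}

#' Simulate a sinusoidally modulated (single-frequency) acquisition
#'
#' Classic frequency-domain excitation for comparison with pulse trains:
#' light modulated at one frequency with the mean optical power matched to
#' a reference pulse-train scheme.  The optoacoustic response is the
#' band-limited wavelet response at the modulation frequency, so the
#' record's spectrum carries a single signal line.
#'
#' @param modulation_freq Modulation frequency in Hz (must lie inside the
#'   transducer band).
#' @param mean_power_equivalent A \code{\link{multiplex_scheme}} whose mean
#'   optical power the sine drive should match.
#' @inheritParams simulate_record
#' @return An \code{acquisition_record} (with an empty trigger list).
#' @export
simulate_sine_record <- function(modulation_freq, mean_power_equivalent,
                                 phantom, transducer = transducer_model(),
                                 noise = noise_model(),
                                 medium = fwmot::medium(),
                                 sampling_rate = 200e6, duration = NULL) {
  stopifnot(inherits(mean_power_equivalent, "multiplex_scheme"))
  band <- transducer$band
  if (modulation_freq < band$f_low || modulation_freq > band$f_high)
    stop("modulation frequency outside the transducer band", call. = FALSE)
  if (sampling_rate < 2 * band$f_high)
    stop("sampling_rate violates Nyquist for the transducer band",
         call. = FALSE)
  sch <- mean_power_equivalent
  if (is.null(duration)) {
    duration <- max(vapply(sch$trains, function(tr)
      tr$start_offset + tr$n_pulses / tr$rep_rate, numeric(1))) +
      1 / sch$ref_rep_rate
  }
  # mean power of the pulsed scheme: sum over trains of E_p * f_rep; the
  # peak-to-peak modulated power is twice the mean (full-depth modulation)
  mean_power <- sum(vapply(sch$trains, function(tr)
    tr$pulse_energy * tr$rep_rate, numeric(1)))
  n <- round(duration * sampling_rate)
  tt <- (seq_len(n) - 1) / sampling_rate
  vs <- medium$speed_of_sound
  # per-sample optical energy of the AC part relative to the 1e-7 J pulse
  # reference used in simulate_record, so amplitudes are commensurate
  ac_energy_per_cycle <- mean_power / modulation_freq
  escale <- ac_energy_per_cycle / 1e-7
  x <- numeric(n)
  for (ab in phantom) {
    amp_w <- rep_len(ab$per_wavelength_amplitude, 1L)[1L]
    if (amp_w == 0) next
    delay <- ab$depth / vs
    ph <- 2 * pi * modulation_freq * (tt - delay)
    x <- x + amp_w * escale * sin(ph) * (tt >= delay)
  }
  set.seed(noise$seed)
  if (noise$white_noise_std > 0)
    x <- x + stats::rnorm(n, 0, noise$white_noise_std)
  structure(
    list(samples = x, sampling_rate = sampling_rate, duration = duration,
         scheme = sch, trigger_times = list(),
         modulation_freq = modulation_freq, seed = noise$seed),
    class = "acquisition_record"
  )
}

#' Simulate a lateral scan (one record per scan position)
#'
#' Moves the detector across \code{scan_positions} in a sweeping motion
#' and simulates one acquisition record per position.  Absorber delays use
#' the Euclidean distance from the detector, and only absorbers inside the
#' acceptance cone contribute, so a point absorber traces the usual
#' hyperbolic locus across the scan.
#'
#' @param scheme A \code{\link{multiplex_scheme}}.
#' @param phantom List of \code{\link{absorber}}s with lateral positions.
#' @param scan_positions Strictly increasing lateral detector positions in
#'   metres.
#' @inheritParams simulate_record
#' @return List of \code{acquisition_record}s, one per position, with the
#'   positions attached as attribute \code{"positions"}.
#' @export
make_bscan <- function(scheme, phantom, scan_positions,
                       transducer = transducer_model(),
                       noise = noise_model(), medium = fwmot::medium(),
                       sampling_rate = 200e6, duration = NULL) {
  if (length(scan_positions) == 0)
    stop("scan_positions must be non-empty", call. = FALSE)
  if (is.unsorted(scan_positions, strictly = TRUE))
    stop("scan_positions must be strictly increasing", call. = FALSE)
  recs <- lapply(seq_along(scan_positions), function(i) {
    ni <- noise
    ni$seed <- noise$seed + i - 1L  # independent noise per position
    simulate_record(scheme, phantom, transducer, ni, medium,
                    sampling_rate, duration,
                    detector_position = scan_positions[i], use_cone = TRUE)
  })
  attr(recs, "positions") <- scan_positions
  recs
}
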
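#' Pulse train description for one excitation wavelength
#'
#' A pulse train is the time-domain excitation pattern of one laser: a
#' sequence of \code{n_pulses} rectangular optical pulses of width
#' \code{pulse_width} fired at repetition rate \code{rep_rate}, starting at
#' \code{start_offset} within the multiplexing period.  Its power spectrum is
#' a frequency comb: discrete lines at integer multiples of \code{rep_rate}
#' under a sinc-squared envelope whose first node sits at
#' \code{1/pulse_width}.
#'
#' @param wavelength_id Integer label (>= 1) identifying the laser.
#' @param wavelength_nm Emission wavelength in nanometres.
#' @param pulse_width Optical pulse duration in seconds; must be shorter
#'   than one repetition period.
#' @param rep_rate Pulse repetition rate in Hz.
#' @param n_pulses Number of pulses in the train (>= 1).
#' @param pulse_energy Optical energy per pulse in joules.
#' @param start_offset Emission start time within one period, in seconds
#'   (\code{0 <= start_offset < 1/rep_rate}).
#' @return An object of class \code{"pulse_train"}.
#' @examples
#' pulse_train(1, 445, 6.7e-9, 200e3, 200, 189e-9)
#' @export
pulse_train <- function(wavelength_id, wavelength_nm, pulse_width, rep_rate,
                        n_pulses, pulse_energy = 0, start_offset = 0) {
  stopifnot(
    length(wavelength_id) == 1L, wavelength_id >= 1,
    wavelength_id == as.integer(wavelength_id),
    rep_rate > 0, pulse_width > 0, pulse_width < 1 / rep_rate,
    n_pulses >= 1, n_pulses == as.integer(n_pulses),
    pulse_energy >= 0,
    start_offset >= 0, start_offset < 1 / rep_rate
  )
  structure(
    list(
      wavelength_id = as.integer(wavelength_id),
      wavelength_nm = as.numeric(wavelength_nm),
      pulse_width = as.numeric(pulse_width),
      rep_rate = as.numeric(rep_rate),
      n_pulses = as.integer(n_pulses),
      pulse_energy = as.numeric(pulse_energy),
      start_offset = as.numeric(start_offset)
    ),
    class = "pulse_train"
  )
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf(
    "Pulse train (wavelength %d, %.1f nm): %d pulses @ %.6g Hz, t_p = %.3g ns, %.3g nJ/pulse\n",
    x$wavelength_id, x$wavelength_nm, x$n_pulses, x$rep_rate,
    x$pulse_width * 1e9, x$pulse_energy * 1e9
  ))
  invisible(x)
}

#' Multiplexing scheme: a set of pulse trains plus the scheme kind
#'
#' Binds the per-wavelength pulse trains together with the multiplexing
#' strategy.  Four strategies are supported:
#' \describe{
#'   \item{\code{"FWM"}}{frequency-wavelength multiplexing: all lasers fire
#'     concurrently, laser \eqn{j} at repetition rate
#'     \eqn{f_{rep,j} = f_{rep,1} + (j-1)\,\delta f}, so each wavelength
#'     occupies its own frequency comb.}
#'   \item{\code{"TD_INTERLEAVE"}}{time-domain interleaving: all lasers share
#'     one repetition rate, laser \eqn{j} shifted by \eqn{(j-1)\,T/N}; the
#'     per-wavelength depth of view shrinks by a factor \eqn{N}.}
#'   \item{\code{"TD_SLOW"}}{each laser pulsed at \eqn{f_{rep}/N} with
#'     \eqn{N_p/N} pulses: depth of view and acquisition time are kept but
#'     SNR drops by \eqn{\sqrt{N}}.}
#'   \item{\code{"TD_LONG"}}{each laser pulsed at \eqn{f_{rep}/N} with the
#'     full pulse count: SNR and depth of view kept, acquisition time grows
#'     by \eqn{N}.}
#' }
#'
#' @param trains List of \code{\link{pulse_train}} objects, ordered by
#'   wavelength id.
#' @param scheme_kind One of \code{"FWM"}, \code{"TD_INTERLEAVE"},
#'   \code{"TD_SLOW"}, \code{"TD_LONG"}.
#' @param delta_f Repetition-rate shift between consecutive wavelengths in
#'   Hz (FWM only; must reproduce the trains' rates exactly).
#' @return An object of class \code{"multiplex_scheme"}.
#' @seealso \code{\link{fwm_scheme}} for a convenience constructor.
#' @export
multiplex_scheme <- function(trains, scheme_kind = c("FWM", "TD_INTERLEAVE",
                                                     "TD_SLOW", "TD_LONG"),
                             delta_f = 0) {
  scheme_kind <- match.arg(scheme_kind)
  stopifnot(is.list(trains), length(trains) >= 1,
            all(vapply(trains, inherits, logical(1), "pulse_train")))
  f1 <- trains[[1L]]$rep_rate
  n <- length(trains)
  rates <- vapply(trains, `[[`, numeric(1), "rep_rate")
  if (scheme_kind == "FWM") {
    if (delta_f < 0 || delta_f >= f1)
      stop("delta_f must lie in [0, f_rep,1)", call. = FALSE)
    expected <- f1 + (seq_len(n) - 1) * delta_f
    if (any(abs(rates - expected) > 1e-9 * f1))
      stop("FWM trains must satisfy f_rep,j = f_rep,1 + (j-1)*delta_f",
           call. = FALSE)
  } else if (scheme_kind == "TD_INTERLEAVE") {
    if (any(rates != f1))
      stop("TD_INTERLEAVE trains must share one repetition rate",
           call. = FALSE)
  }
  structure(
    list(trains = trains, scheme_kind = scheme_kind,
         delta_f = as.numeric(delta_f), ref_rep_rate = f1),
    class = "multiplex_scheme"
  )
}

#' @export
print.multiplex_scheme <- function(x, ...) {
  cat(sprintf("Multiplex scheme [%s]: %d wavelength(s), f_rep,1 = %.6g Hz",
              x$scheme_kind, length(x$trains), x$ref_rep_rate))
  if (x$scheme_kind == "FWM") cat(sprintf(", delta_f = %.6g Hz", x$delta_f))
  cat("\n")
  for (tr in x$trains) print(tr)
  invisible(x)
}

#' @export
length.multiplex_scheme <- function(x) length(x$trains)

#' Convenience constructor for a frequency-multiplexed scheme
#'
#' Builds an FWM \code{\link{multiplex_scheme}} with laser \eqn{j} at
#' \eqn{f_{rep,1} + (j-1)\delta f}, all lasers starting at time zero.
#'
#' @param ref_rep_rate Repetition rate of laser 1 in Hz.
#' @param delta_f Repetition-rate shift in Hz.
#' @param n_wavelengths Number of lasers.
#' @param n_pulses Pulse count, recycled across lasers.
#' @param pulse_width Pulse width in seconds, recycled.
#' @param pulse_energy Energy per pulse in joules, recycled.
#' @param wavelengths_nm Optional emission wavelengths, recycled.
#' @return A \code{multiplex_scheme} of kind \code{"FWM"}.
#' @examples
#' fwm_scheme(200e3, 125, 4, n_pulses = c(100, 101, 101, 101))
#' @export
fwm_scheme <- function(ref_rep_rate, delta_f, n_wavelengths,
                       n_pulses = 100, pulse_width = 10e-9,
                       pulse_energy = 150e-9,
                       wavelengths_nm = seq(445, by = 100,
                                            length.out = n_wavelengths)) {
  n_pulses <- rep_len(n_pulses, n_wavelengths)
  pulse_width <- rep_len(pulse_width, n_wavelengths)
  pulse_energy <- rep_len(pulse_energy, n_wavelengths)
  wavelengths_nm <- rep_len(wavelengths_nm, n_wavelengths)
  trains <- lapply(seq_len(n_wavelengths), function(j) {
    pulse_train(j, wavelengths_nm[j], pulse_width[j],
                ref_rep_rate + (j - 1) * delta_f, n_pulses[j],
                pulse_energy[j])
  })
  multiplex_scheme(trains, "FWM", delta_f)
}

#' Convenience constructor for a time-interleaved scheme
#'
#' All lasers share \code{rep_rate}; laser \eqn{j} is shifted by
#' \eqn{(j-1)\,T/N} so the wavelengths time-share one period.
#'
#' @inheritParams fwm_scheme
#' @param rep_rate Shared repetition rate in Hz.
#' @return A \code{multiplex_scheme} of kind \code{"TD_INTERLEAVE"}.
#' @export
td_interleaved_scheme <- function(rep_rate, n_wavelengths, n_pulses = 100,
                                  pulse_width = 10e-9, pulse_energy = 150e-9,
                                  wavelengths_nm = seq(445, by = 100,
                                                       length.out = n_wavelengths)) {
  n_pulses <- rep_len(n_pulses, n_wavelengths)
  pulse_width <- rep_len(pulse_width, n_wavelengths)
  pulse_energy <- rep_len(pulse_energy, n_wavelengths)
  wavelengths_nm <- rep_len(wavelengths_nm, n_wavelengths)
  period <- 1 / rep_rate
  trains <- lapply(seq_len(n_wavelengths), function(j) {
    pulse_train(j, wavelengths_nm[j], pulse_width[j], rep_rate, n_pulses[j],
                pulse_energy[j], start_offset = (j - 1) * period / n_wavelengths)
  })
  multiplex_scheme(trains, "TD_INTERLEAVE")
}

#' Reference four-diode excitation configuration
#'
#' The default four-wavelength FWM configuration of the laser-diode
#' tomography system the package models: 444.3/460.1/636.8/804.9 nm diodes,
#' pulse widths 6.7/6.7/10.2/10.2 ns, repetition rates 200,000 / 200,125 /
#' 200,250 / 200,375 Hz (reference rate 200 kHz, shift 125 Hz), pulse
#' energies 189/137/142/153 nJ, and pulse counts 100/101/101/101.
#'
#' @param n_pulses Pulse counts per laser (length 4 or recycled).
#' @return A \code{multiplex_scheme} of kind \code{"FWM"}.
#' @examples
#' reference_scheme()
#' @export
reference_scheme <- function(n_pulses = c(100L, 101L, 101L, 101L)) {
  fwm_scheme(
    ref_rep_rate = 200e3, delta_f = 125, n_wavelengths = 4,
    n_pulses = rep_len(n_pulses, 4),
    pulse_width = c(6.7e-9, 6.7e-9, 10.2e-9, 10.2e-9),
    pulse_energy = c(189e-9, 137e-9, 142e-9, 153e-9),
    wavelengths_nm = c(444.3, 460.1, 636.8, 804.9)
  )
}

#' Ultrasound transducer detection band
#'
#' Either the band edges or a centre frequency plus fractional bandwidth can
#' be given; the other pair is derived (\code{f_low = center*(1 - fb/2)},
#' \code{f_high = center*(1 + fb/2)}).
#'
#' @param f_low,f_high Band edges in Hz.
#' @param center Centre frequency in Hz.
#' @param fractional_bandwidth Relative bandwidth (e.g. 1.12 for 112\%).
#' @return An object of class \code{"transducer_band"} with fields
#'   \code{f_low}, \code{f_high}, \code{center}, \code{fractional_bandwidth}.
#' @examples
#' transducer_band(22e6, 78e6)
#' transducer_band(center = 50e6, fractional_bandwidth = 1.12)
#' @export
transducer_band <- function(f_low = NULL, f_high = NULL, center = NULL,
                            fractional_bandwidth = NULL) {
  if (is.null(f_low) || is.null(f_high)) {
    if (is.null(center) || is.null(fractional_bandwidth))
      stop("give either (f_low, f_high) or (center, fractional_bandwidth)",
           call. = FALSE)
    f_low <- center * (1 - fractional_bandwidth / 2)
    f_high <- center * (1 + fractional_bandwidth / 2)
  } else {
    center <- (f_low + f_high) / 2
    fractional_bandwidth <- (f_high - f_low) / center
  }
  if (!(f_low > 0 && f_high > f_low))
    stop("require 0 < f_low < f_high", call. = FALSE)
  structure(
    list(f_low = f_low, f_high = f_high, center = center,
         fractional_bandwidth = fractional_bandwidth),
    class = "transducer_band"
  )
}

#' @export
print.transducer_band <- function(x, ...) {
  cat(sprintf("Transducer band: %.4g-%.4g MHz (center %.4g MHz, %.0f%% fractional)\n",
              x$f_low / 1e6, x$f_high / 1e6, x$center / 1e6,
              100 * x$fractional_bandwidth))
  invisible(x)
}

#' Acoustic propagation medium
#'
#' @param speed_of_sound Speed of sound in m/s.  The default 1500 m/s is
#'   the usual soft-tissue / water value.
#' @return An object of class \code{"medium"}.
#' @export
medium <- function(speed_of_sound = 1500) {
  stopifnot(speed_of_sound > 0)
  structure(list(speed_of_sound = as.numeric(speed_of_sound)),
            class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("Medium: speed of sound %.4g m/s\n", x$speed_of_sound))
  invisible(x)
}
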
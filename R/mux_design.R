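# Multiplexing design calculator: depth of view, harmonic index ranges,
# admissible repetition-rate shifts, wavelength capacity, pulse-count
# minima, exposure and SNR arithmetic.

# relative tolerance used when an integer harmonic index is derived from a
# frequency ratio, so that band-edge harmonics (k*f_rep == f_low or f_high)
# are counted as in-band regardless of floating-point representation
.k_eps <- 1e-9

.check_positive <- function(...) {
  vals <- list(...)
  nm <- names(vals)
  for (i in seq_along(vals)) {
    if (!is.numeric(vals[[i]]) || length(vals[[i]]) != 1L ||
        !is.finite(vals[[i]]) || vals[[i]] <= 0)
      stop(sprintf("'%s' must be a positive finite scalar", nm[i]),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Maximum unambiguous imaging depth of a pulse train
#'
#' The depth of view is the one-way distance ultrasound travels during one
#' repetition period, \eqn{DoV = v_s\,T} with \eqn{T = 1/f_{rep}}: echoes
#' from deeper structures alias into the next period.  When \code{n_shared}
#' wavelengths time-share one period (time-domain interleaving) each
#' wavelength keeps only \eqn{1/n} of it.
#'
#' @param rep_rate Pulse repetition rate in Hz.
#' @param medium A \code{\link{medium}} object (or speed of sound in m/s).
#' @param n_shared Number of wavelengths sharing the period (1 for a single
#'   wavelength or FWM operation).
#' @return Depth of view in metres.
#' @examples
#' depth_of_view(200e3, medium(1500))            # 7.5 mm
#' depth_of_view(200e3, medium(1500), n_shared = 4)  # 1.875 mm
#' @export
depth_of_view <- function(rep_rate, medium = fwmot::medium(), n_shared = 1) {
  vs <- if (inherits(medium, "medium")) medium$speed_of_sound else medium
  .check_positive(rep_rate = rep_rate, speed_of_sound = vs,
                  n_shared = n_shared)
  stopifnot(n_shared == as.integer(n_shared))
  vs / rep_rate / n_shared
}

#' Acquisition time of a pulse train
#'
#' @param n_pulses Number of pulses.
#' @param rep_rate Repetition rate in Hz.
#' @return \code{n_pulses / rep_rate} in seconds.
#' @examples
#' acquisition_time(200, 200e3)  # 1 ms
#' @export
acquisition_time <- function(n_pulses, rep_rate) {
  .check_positive(n_pulses = n_pulses, rep_rate = rep_rate)
  stopifnot(n_pulses == as.integer(n_pulses))
  n_pulses / rep_rate
}

#' Spectral resolution of an acquisition
#'
#' Frequencies closer than \code{df = 1/t_acq} cannot be resolved in the
#' record's spectrum; this sets the floor for the admissible comb spacing.
#'
#' @param t_acq Acquisition time in seconds.
#' @return Frequency resolution in Hz.
#' @export
frequency_resolution <- function(t_acq) {
  .check_positive(t_acq = t_acq)
  1 / t_acq
}

#' Harmonic indices of a repetition rate inside a detection band
#'
#' The excitation comb has lines at \eqn{k f_{rep}}, k a positive integer.
#' Returns the smallest and largest k whose line falls inside the
#' transducer band, band edges inclusive.
#'
#' @param rep_rate Repetition rate in Hz.
#' @param band A \code{\link{transducer_band}}.
#' @return List with \code{k_low}, \code{k_high} and \code{n_harmonics}
#'   (\code{= k_high - k_low + 1}, or 0 when no harmonic is in band, in
#'   which case \code{k_low > k_high}).
#' @examples
#' harmonic_indices(200e3, transducer_band(22e6, 78e6))  # k 110..390
#' @export
harmonic_indices <- function(rep_rate, band) {
  .check_positive(rep_rate = rep_rate)
  stopifnot(inherits(band, "transducer_band"))
  k_low <- max(1L, as.integer(ceiling(band$f_low / rep_rate - .k_eps)))
  k_high <- as.integer(floor(band$f_high / rep_rate + .k_eps))
  list(k_low = k_low, k_high = k_high,
       n_harmonics = max(0L, k_high - k_low + 1L))
}

#' Admissible repetition-rate shift range for frequency multiplexing
#'
#' With \eqn{N} wavelengths at rates \eqn{f_{rep,1} + (j-1)\delta f}, all
#' in-band comb lines of all lasers must be separated by at least the
#' spectral resolution \eqn{df = f_{rep,1}/N_p}.  Two constraints bound
#' \eqn{\delta f}:
#' \itemize{
#'   \item lower bound — adjacent lasers are closest at the lowest in-band
#'     harmonic: \eqn{k_{low}\,\delta f \ge df}, i.e.
#'     \eqn{\delta f_{min} = df/k_{low}};
#'   \item upper bound — laser \eqn{N}'s k-th harmonic must stay \eqn{df}
#'     clear of laser 1's (k+1)-th harmonic at the top of the band:
#'     \eqn{f_{rep,1} - k_{high}(N-1)\delta f \ge df}, i.e.
#'     \eqn{\delta f_{max} = (f_{rep,1} - df)/(k_{high}(N-1))}.
#' }
#' The configuration is feasible when
#' \eqn{\delta f_{min} \le \delta f_{max}} (ties allowed).
#'
#' @param ref_rep_rate Repetition rate of laser 1 in Hz.
#' @param n_pulses Pulse count of laser 1 (sets \eqn{df}).
#' @param n_wavelengths Number of lasers (>= 2).
#' @param band A \code{\link{transducer_band}}.
#' @return List with \code{delta_f_min}, \code{delta_f_max}, \code{df},
#'   \code{k_low}, \code{k_high} and logical \code{feasible}.
#' @examples
#' delta_f_bounds(200e3, 100, 4, transducer_band(22e6, 78e6))
#' @export
delta_f_bounds <- function(ref_rep_rate, n_pulses, n_wavelengths, band) {
  .check_positive(ref_rep_rate = ref_rep_rate, n_pulses = n_pulses)
  if (!(n_wavelengths >= 2 && n_wavelengths == as.integer(n_wavelengths)))
    stop("n_wavelengths must be an integer >= 2", call. = FALSE)
  ks <- harmonic_indices(ref_rep_rate, band)
  if (ks$n_harmonics == 0L)
    stop("no harmonic of ref_rep_rate falls inside the detection band",
         call. = FALSE)
  df <- ref_rep_rate / n_pulses
  dmin <- df / ks$k_low
  dmax <- (ref_rep_rate - df) / (ks$k_high * (n_wavelengths - 1))
  list(delta_f_min = dmin, delta_f_max = dmax, df = df,
       k_low = ks$k_low, k_high = ks$k_high,
       feasible = dmin <= dmax * (1 + .k_eps))
}

#' Brute-force comb-separation check
#'
#' Independent validator for \code{\link{delta_f_bounds}}: enumerates every
#' in-band comb line of every laser at its true repetition rate
#' \eqn{f_{rep,1} + (j-1)\delta f} and checks that lines belonging to
#' different lasers are pairwise separated by at least \code{df}.
#'
#' @inheritParams delta_f_bounds
#' @param delta_f Candidate repetition-rate shift in Hz.
#' @return \code{TRUE} when every cross-laser pair of in-band lines is
#'   separated by at least \eqn{df} (within a relative tolerance of 1e-9),
#'   else \code{FALSE}.
#' @export
comb_lines_separated <- function(ref_rep_rate, delta_f, n_pulses,
                                 n_wavelengths, band) {
  .check_positive(ref_rep_rate = ref_rep_rate, n_pulses = n_pulses)
  stopifnot(delta_f >= 0, n_wavelengths >= 1)
  df <- ref_rep_rate / n_pulses
  lines <- lapply(seq_len(n_wavelengths), function(j) {
    fj <- ref_rep_rate + (j - 1) * delta_f
    ks <- harmonic_indices(fj, band)
    if (ks$n_harmonics == 0L) return(numeric(0))
    seq(ks$k_low, ks$k_high) * fj
  })
  laser <- rep(seq_len(n_wavelengths), lengths(lines))
  freq <- unlist(lines)
  ord <- order(freq)
  freq <- freq[ord]; laser <- laser[ord]
  if (length(freq) < 2L) return(TRUE)
  gap <- diff(freq)
  cross <- diff(laser) != 0L
  all(gap[cross] >= df * (1 - .k_eps))
}

#' Maximum number of frequency-multiplexed wavelengths
#'
#' Largest \eqn{N} for which an admissible repetition-rate shift exists,
#' i.e. \code{\link{delta_f_bounds}} is feasible.  Found by linear scan
#' over \eqn{N}; feasibility is monotone decreasing in \eqn{N} because
#' \eqn{\delta f_{max} \propto 1/(N-1)} while \eqn{\delta f_{min}} is
#' fixed.
#'
#' @inheritParams delta_f_bounds
#' @return Integer number of wavelengths (>= 1; a single wavelength needs
#'   no separation and is always feasible).
#' @examples
#' max_wavelengths_fwm(200e3, 100, transducer_band(22e6, 78e6))  # 28
#' @export
max_wavelengths_fwm <- function(ref_rep_rate, n_pulses, band) {
  ks <- harmonic_indices(ref_rep_rate, band)
  if (ks$n_harmonics == 0L)
    stop("no harmonic of ref_rep_rate falls inside the detection band",
         call. = FALSE)
  n <- 1L
  repeat {
    b <- delta_f_bounds(ref_rep_rate, n_pulses, n + 1L, band)
    if (!b$feasible) break
    n <- n + 1L
  }
  n
}

#' Maximum number of time-interleaved wavelengths
#'
#' In time-domain interleaving each wavelength needs a time slot of
#' \code{dov_per_wavelength / v_s}; the capacity is the number of such
#' slots fitting in one repetition period.
#'
#' @param rep_rate Shared repetition rate in Hz.
#' @param medium A \code{\link{medium}} (or speed of sound in m/s).
#' @param dov_per_wavelength Depth of view each wavelength must retain, in
#'   metres.
#' @return Integer wavelength capacity.
#' @examples
#' max_wavelengths_td(200e3, medium(1500), 1.5e-3)  # 5
#' @export
max_wavelengths_td <- function(rep_rate, medium = fwmot::medium(),
                               dov_per_wavelength) {
  vs <- if (inherits(medium, "medium")) medium$speed_of_sound else medium
  .check_positive(rep_rate = rep_rate, speed_of_sound = vs,
                  dov_per_wavelength = dov_per_wavelength)
  as.integer(floor((vs / rep_rate) / dov_per_wavelength + .k_eps))
}

#' Minimum pulse count for feasible frequency multiplexing
#'
#' The spectral resolution \eqn{df = f_{rep,1}/N_p} tightens as the train
#' shortens; below some pulse count no admissible \eqn{\delta f} remains.
#' Returns the smallest \eqn{N_p} for which \code{\link{delta_f_bounds}}
#' is feasible, by linear scan from 1.
#'
#' @inheritParams delta_f_bounds
#' @return Integer minimum pulse count (1 when \code{n_wavelengths == 1}).
#' @examples
#' min_pulses(200e3, 4, transducer_band(22e6, 78e6))  # 12
#' @export
min_pulses <- function(ref_rep_rate, n_wavelengths, band) {
  if (n_wavelengths == 1) return(1L)
  ks <- harmonic_indices(ref_rep_rate, band)
  if (ks$n_harmonics == 0L)
    stop("no harmonic of ref_rep_rate falls inside the detection band",
         call. = FALSE)
  np <- 1L
  while (!delta_f_bounds(ref_rep_rate, np, n_wavelengths, band)$feasible) {
    np <- np + 1L
    if (np > 1e7) stop("no feasible pulse count below 1e7", call. = FALSE)
  }
  np
}

#' Signal-to-noise ratio in decibels
#'
#' \eqn{SNR = 10 \log_{10}(S/N)} with \eqn{S} the signal intensity and
#' \eqn{N} the standard deviation of the noise floor.
#'
#' @param signal_amplitude Signal intensity (volts).
#' @param noise_std Noise-floor standard deviation (volts).
#' @return SNR in dB.
#' @examples
#' snr_db(12e-3, 90.6e-6)  # 21.2 dB
#' @export
snr_db <- function(signal_amplitude, noise_std) {
  .check_positive(signal_amplitude = signal_amplitude, noise_std = noise_std)
  10 * log10(signal_amplitude / noise_std)
}

#' SNR gain from coherent averaging
#'
#' Averaging \eqn{N_p} repeats improves SNR by \eqn{\sqrt{N_p}}; the gain
#' from changing the number of averages is
#' \eqn{10\log_{10}\sqrt{n_{after}/n_{before}}} dB.
#'
#' @param n_after,n_before Pulse (average) counts.
#' @return Gain in dB.
#' @examples
#' averaging_gain_db(200, 50)  # 3.0 dB
#' @export
averaging_gain_db <- function(n_after, n_before) {
  .check_positive(n_after = n_after, n_before = n_before)
  10 * log10(sqrt(n_after / n_before))
}

#' Optical exposure of the sample and safety-limit compliance
#'
#' Per-pulse fluence is the summed per-shot energy of the simultaneously
#' firing lasers over the illuminated area; mean irradiance is fluence
#' times the combined repetition rate.  Both are compared against the skin
#' maximum-permissible-exposure limits of 20 mJ/cm2 per pulse and
#' 18 W/cm2 average.
#'
#' @param pulse_energies Energies per pulse in joules (one per laser).
#' @param spot_area Illuminated area in cm2.
#' @param combined_rep_rate Effective pulse repetition rate in Hz.
#' @param mpe_pulse_limit,mpe_mean_limit Safety limits (J/cm2, W/cm2).
#' @return An object of class \code{"exposure_report"}: list with
#'   \code{fluence_per_pulse} (J/cm2), \code{mean_irradiance} (W/cm2), the
#'   two limits and logical \code{compliant}.
#' @examples
#' # fluence 19.8 uJ/cm2 at 200 kHz -> 3.96 W/cm2 mean
#' rep <- exposure(19.8e-6 * 0.0314, spot_area = 0.0314,
#'                 combined_rep_rate = 200e3)
#' rep$mean_irradiance
#' @export
exposure <- function(pulse_energies, spot_area, combined_rep_rate,
                     mpe_pulse_limit = 20e-3, mpe_mean_limit = 18) {
  stopifnot(all(pulse_energies >= 0))
  .check_positive(spot_area = spot_area,
                  combined_rep_rate = combined_rep_rate)
  fluence <- sum(pulse_energies) / spot_area
  irradiance <- fluence * combined_rep_rate
  structure(
    list(fluence_per_pulse = fluence, mean_irradiance = irradiance,
         mpe_pulse_limit = mpe_pulse_limit, mpe_mean_limit = mpe_mean_limit,
         compliant = fluence < mpe_pulse_limit &&
           irradiance < mpe_mean_limit),
    class = "exposure_report"
  )
}

#' @export
print.exposure_report <- function(x, ...) {
  cat(sprintf("Exposure: %.4g uJ/cm2 per pulse, %.4g W/cm2 mean -- %s\n",
              x$fluence_per_pulse * 1e6, x$mean_irradiance,
              if (x$compliant) "within MPE limits" else "EXCEEDS MPE limits"))
  invisible(x)
}

#' Aggregate design limits for a multiplexing configuration
#'
#' One-call summary of every derived design quantity: depth of view,
#' acquisition time, spectral resolution, in-band harmonic index range,
#' admissible shift bounds, minimum pulse count and wavelength capacities.
#'
#' @inheritParams delta_f_bounds
#' @param medium A \code{\link{medium}}.
#' @param dov_per_wavelength Depth of view per wavelength used for the
#'   time-interleaved capacity (default 1.5 mm).
#' @return An object of class \code{"design_limits"}.
#' @examples
#' design_limits(200e3, 100, 4, transducer_band(22e6, 78e6))
#' @export
design_limits <- function(ref_rep_rate, n_pulses, n_wavelengths, band,
                          medium = fwmot::medium(),
                          dov_per_wavelength = 1.5e-3) {
  t_acq <- acquisition_time(n_pulses, ref_rep_rate)
  ks <- harmonic_indices(ref_rep_rate, band)
  b <- if (n_wavelengths >= 2 && ks$n_harmonics > 0L)
    delta_f_bounds(ref_rep_rate, n_pulses, n_wavelengths, band)
  else list(delta_f_min = NA_real_, delta_f_max = NA_real_,
            feasible = n_wavelengths == 1)
  structure(
    list(
      dov = depth_of_view(ref_rep_rate, medium),
      t_acq = t_acq,
      df = frequency_resolution(t_acq),
      k_low = ks$k_low, k_high = ks$k_high, n_harmonics = ks$n_harmonics,
      delta_f_min = b$delta_f_min, delta_f_max = b$delta_f_max,
      feasible = b$feasible,
      n_p_min = if (ks$n_harmonics > 0L)
        min_pulses(ref_rep_rate, n_wavelengths, band) else NA_integer_,
      n_max_fwm = if (ks$n_harmonics > 0L)
        max_wavelengths_fwm(ref_rep_rate, n_pulses, band) else NA_integer_,
      n_max_td = max_wavelengths_td(ref_rep_rate, medium,
                                    dov_per_wavelength),
      ref_rep_rate = ref_rep_rate, n_pulses = n_pulses,
      n_wavelengths = n_wavelengths, band = band
    ),
    class = "design_limits"
  )
}

#' @export
print.design_limits <- function(x, ...) {
  cat(sprintf("Design limits (f_rep,1 = %.6g Hz, N_p = %d, N = %d):\n",
              x$ref_rep_rate, as.integer(x$n_pulses),
              as.integer(x$n_wavelengths)))
  cat(sprintf("  DoV %.4g mm | t_acq %.4g ms | df %.4g Hz\n",
              x$dov * 1e3, x$t_acq * 1e3, x$df))
  cat(sprintf("  in-band harmonics k = %d..%d (%d lines)\n",
              x$k_low, x$k_high, x$n_harmonics))
  if (!is.na(x$delta_f_min))
    cat(sprintf("  delta_f in [%.4g, %.4g] Hz (%s)\n", x$delta_f_min,
                x$delta_f_max,
                if (isTRUE(x$feasible)) "feasible" else "INFEASIBLE"))
  cat(sprintf("  N_p,min %s | capacity: %s wavelengths (FWM), %d (TD)\n",
              format(x$n_p_min), format(x$n_max_fwm), x$n_max_td))
  invisible(x)
}

#' As-data-frame view of design limits
#'
#' @param x A \code{design_limits} object.
#' @param ... Unused.
#' @return A two-column data frame (quantity, value) suitable for a CSV
#'   design report.
#' @export
as.data.frame.design_limits <- function(x, ...) {
  data.frame(
    quantity = c("dov_m", "t_acq_s", "df_hz", "k_low", "k_high",
                 "n_harmonics", "delta_f_min_hz", "delta_f_max_hz",
                 "feasible", "n_p_min", "n_max_fwm", "n_max_td"),
    value = c(x$dov, x$t_acq, x$df, x$k_low, x$k_high, x$n_harmonics,
              x$delta_f_min, x$delta_f_max, as.numeric(x$feasible),
              x$n_p_min, x$n_max_fwm, x$n_max_td),
    stringsAsFactors = FALSE
  )
}

#' Trade-off table for the four multiplexing strategies
#'
#' For a given scheme, reports what each wavelength retains: depth of
#' view, pulse count, SNR factor relative to a single-wavelength train of
#' \eqn{N_p} pulses, and the total acquisition time.  Time interleaving
#' divides the depth of view by \eqn{N}; slow interleaving divides the
#' pulse count (SNR factor \eqn{1/\sqrt{N}}); long interleaving multiplies
#' the acquisition time by \eqn{N}; frequency multiplexing compromises
#' none of the three.
#'
#' @param scheme A \code{\link{multiplex_scheme}}.
#' @param band A \code{\link{transducer_band}} (recorded in the table
#'   attributes; the trade-offs themselves are band-independent).
#' @param medium A \code{\link{medium}}.
#' @return A data frame with one row per wavelength and columns
#'   \code{wavelength_id}, \code{dov}, \code{n_pulses}, \code{snr_factor},
#'   \code{t_acq_total}.
#' @export
scheme_tradeoffs <- function(scheme, band = NULL,
                             medium = fwmot::medium()) {
  stopifnot(inherits(scheme, "multiplex_scheme"))
  n <- length(scheme$trains)
  ids <- vapply(scheme$trains, `[[`, integer(1), "wavelength_id")
  np <- vapply(scheme$trains, `[[`, integer(1), "n_pulses")
  rates <- vapply(scheme$trains, `[[`, numeric(1), "rep_rate")
  dov_full <- vapply(rates, depth_of_view, numeric(1), medium = medium)
  t_acq <- max(np / rates)
  # in every time-sharing strategy the N trains interleave within one
  # repetition period, so each wavelength keeps 1/N of its train's DoV;
  # only frequency multiplexing keeps the full period per wavelength
  out <- switch(
    scheme$scheme_kind,
    TD_INTERLEAVE = data.frame(wavelength_id = ids, dov = dov_full / n,
                               n_pulses = np, snr_factor = 1,
                               t_acq_total = t_acq),
    TD_SLOW = data.frame(wavelength_id = ids, dov = dov_full / n,
                         n_pulses = np, snr_factor = 1 / sqrt(n),
                         t_acq_total = t_acq),
    TD_LONG = data.frame(wavelength_id = ids, dov = dov_full / n,
                         n_pulses = np, snr_factor = 1,
                         t_acq_total = t_acq),
    FWM = data.frame(wavelength_id = ids, dov = dov_full,
                     n_pulses = np, snr_factor = 1,
                     t_acq_total = t_acq),
    stop("unknown scheme kind", call. = FALSE)
  )
  attr(out, "scheme_kind") <- scheme$scheme_kind
  attr(out, "band") <- band
  out
}
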
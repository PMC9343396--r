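# Demultiplexing: recover per-wavelength one-period A-scans from a single
# interleaved record, either by time-domain period averaging or by
# projection onto the harmonic comb of each laser's repetition rate.

.new_ascan <- function(samples, sampling_rate, rep_rate, wavelength_id = 1L,
                       harmonics_used = integer(0),
                       spectrum = complex(0), t0 = 0) {
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         rep_rate = rep_rate, period = 1 / rep_rate,
         wavelength_id = as.integer(wavelength_id),
         harmonics_used = harmonics_used, spectrum = spectrum, t0 = t0),
    class = "averaged_ascan"
  )
}

#' @export
print.averaged_ascan <- function(x, ...) {
  cat(sprintf(
    "Averaged A-scan (wavelength %d): %d samples over T = %.4g us, %d harmonic(s)\n",
    x$wavelength_id, length(x$samples), x$period * 1e6,
    length(x$harmonics_used)))
  invisible(x)
}

#' @export
plot.averaged_ascan <- function(x, ...) {
  tt <- (seq_along(x$samples) - 1) / x$sampling_rate
  graphics::plot(tt * 1e6, x$samples, type = "l", xlab = "time in period (us)",
                 ylab = "voltage (V)", ...)
  invisible(x)
}

#' Time-domain period averaging of an acquisition record
#'
#' Splits the record into \code{n_pulses} consecutive sections of one
#' repetition period and averages them point by point; on white noise the
#' output standard deviation shrinks by \eqn{\sqrt{N_p}}.  When the period
#' is a non-integer number of samples, each section is resampled onto a
#' common one-period grid by linear interpolation.
#'
#' @param record An \code{\link{simulate_record} acquisition_record}
#'   (or any list with \code{samples} and \code{sampling_rate}).
#' @param rep_rate Repetition rate defining the period, in Hz.
#' @param n_pulses Number of periods to average.
#' @param t0 Start time of the first period within the record (seconds),
#'   e.g. the laser's first trigger.
#' @param wavelength_id Label carried into the output.
#' @return An \code{averaged_ascan}.
#' @export
td_average <- function(record, rep_rate, n_pulses, t0 = 0,
                       wavelength_id = 1L) {
  fs <- record$sampling_rate
  x <- record$samples
  period <- 1 / rep_rate
  if (t0 + n_pulses * period > length(x) / fs + 1e-12)
    stop("record shorter than n_pulses periods", call. = FALSE)
  p_len <- round(period * fs)
  grid <- (seq_len(p_len) - 1) / fs
  q <- rep(t0 + (seq_len(n_pulses) - 1) * period, each = p_len) + grid
  tt <- (seq_along(x) - 1) / fs
  vals <- stats::approx(tt, x, xout = q, rule = 2)$y
  avg <- colMeans(matrix(vals, nrow = n_pulses, byrow = TRUE))
  .new_ascan(avg, fs, rep_rate, wavelength_id, t0 = t0)
}

# Exact-frequency least-squares projection of a real record onto
# cos/sin pairs at k * rep_rate for each requested harmonic k.
# Returns complex coefficients c_k = a_k - i b_k such that the fitted
# component is Re(c_k exp(i 2 pi k f t)) = a_k cos + b_k sin.
.project_harmonics <- function(x, fs, rep_rate, harmonics, t_offset = 0) {
  m <- length(x)
  tt <- (seq_len(m) - 1) / fs + t_offset
  ks <- sort(unique(as.integer(harmonics)))
  z1 <- exp(-2i * pi * rep_rate * tt)
  z2 <- z1 * z1
  coef <- complex(length(ks))
  # walk the harmonic ladder: w = z1^k, w2 = z1^(2k), stepping by the gap
  # between consecutive requested k to avoid recomputing exponentials
  w <- exp(-2i * pi * rep_rate * ks[1] * tt)
  w2 <- w * w
  for (i in seq_along(ks)) {
    if (i > 1L) {
      dk <- ks[i] - ks[i - 1L]
      step <- if (dk == 1L) z1 else exp(-2i * pi * rep_rate * dk * tt)
      w <- w * step
      w2 <- w2 * step * step
    }
    A <- sum(x * w)          # sum s (cos - i sin)
    B <- sum(w2)             # sum (cos2wt - i sin2wt)
    scc <- (m + Re(B)) / 2
    sss <- (m - Re(B)) / 2
    scs <- -Im(B) / 2
    sc <- Re(A)
    ss <- -Im(A)
    det <- scc * sss - scs * scs
    if (abs(det) < 1e-9 * m * m) {
      a <- sc / scc; b <- 0
    } else {
      a <- (sss * sc - scs * ss) / det
      b <- (scc * ss - scs * sc) / det
    }
    coef[i] <- complex(real = a, imaginary = -b)
  }
  list(harmonics = ks, coef = coef)
}

# synthesize sum_k Re(c_k exp(i 2 pi k f t)) on arbitrary times
.synthesize_comb <- function(harmonics, coef, rep_rate, times) {
  if (length(harmonics) == 0L) return(numeric(length(times)))
  ang <- outer(times, 2 * pi * rep_rate * harmonics)
  # c = a - i b  =>  a cos + b sin = Re(c) cos - Im(c) sin
  drop(cos(ang) %*% Re(coef) - sin(ang) %*% Im(coef))
}

# ladder variant for long time vectors: walks the harmonics sequentially
# so memory stays O(length(times))
.synthesize_comb_long <- function(harmonics, coef, rep_rate, times) {
  out <- numeric(length(times))
  if (length(harmonics) == 0L) return(out)
  z1 <- exp(2i * pi * rep_rate * times)
  w <- exp(2i * pi * rep_rate * harmonics[1L] * times)
  for (i in seq_along(harmonics)) {
    if (i > 1L) {
      dk <- harmonics[i] - harmonics[i - 1L]
      w <- w * (if (dk == 1L) z1 else exp(2i * pi * rep_rate * dk * times))
    }
    out <- out + Re(coef[i]) * Re(w) - Im(coef[i]) * Im(w)
  }
  out
}

#' Harmonic-comb filtering of an acquisition record
#'
#' The frequency-domain equivalent of period averaging: the record's
#' spectrum is sampled only at the harmonics \eqn{k f_{rep}} of the
#' excitation comb — all other frequencies carry no signal, only noise —
#' and one period is synthesized from those components alone.  The
#' projection is an exact-frequency least-squares fit of \{cos, sin\}
#' pairs at each \eqn{k f_{rep}} over the full record, so harmonics need
#' not fall on FFT bins; an FFT-bin nearest-neighbour mode is available
#' for speed.  On a record containing an integer number of periods with
#' every sub-Nyquist harmonic retained the result equals
#' \code{\link{td_average}} with the DC term removed, to numerical
#' precision.
#'
#' @inheritParams td_average
#' @param harmonics Integer harmonic orders \eqn{k \ge 1} to retain; all
#'   must lie strictly below Nyquist (\code{k * rep_rate < fs/2}).
#' @param method \code{"projection"} (exact-frequency least squares,
#'   default) or \code{"fft_bin"} (nearest FFT bin).
#' @param t0 Time within the record to which the synthesized period is
#'   aligned (seconds); the output's sample \code{i} corresponds to record
#'   time \code{t0 + (i-1)/fs}.
#' @return An \code{averaged_ascan} with the complex comb
#'   \code{spectrum} attached.
#' @export
comb_filter <- function(record, rep_rate, harmonics,
                        method = c("projection", "fft_bin"),
                        t0 = 0, wavelength_id = 1L) {
  method <- match.arg(method)
  fs <- record$sampling_rate
  x <- record$samples
  if (length(harmonics) == 0L)
    stop("harmonics must be non-empty", call. = FALSE)
  harmonics <- sort(unique(as.integer(harmonics)))
  if (any(harmonics < 1L))
    stop("harmonics must be >= 1", call. = FALSE)
  if (max(harmonics) * rep_rate >= fs / 2)
    stop("harmonic above Nyquist", call. = FALSE)
  if (method == "projection") {
    pr <- .project_harmonics(x, fs, rep_rate, harmonics)
  } else {
    m <- length(x)
    X <- stats::fft(x)
    bins <- round(harmonics * rep_rate / fs * m) + 1L
    coef <- 2 * X[bins] / m
    # fft gives sum s exp(-i w t): coefficient of a cos + b sin fit is
    # a = 2 Re(X)/m, b = -2 Im(X)/m, matching c = a - i b = 2 X / m
    pr <- list(harmonics = harmonics, coef = coef)
  }
  p_len <- round(fs / rep_rate)
  times <- t0 + (seq_len(p_len) - 1) / fs
  samples <- .synthesize_comb(pr$harmonics, pr$coef, rep_rate, times)
  .new_ascan(samples, fs, rep_rate, wavelength_id,
             harmonics_used = pr$harmonics, spectrum = pr$coef, t0 = t0)
}

#' Demultiplex every wavelength of a frequency-multiplexed record
#'
#' Applies \code{\link{comb_filter}} once per laser at that laser's own
#' repetition rate \eqn{f_{rep,j}}, using the harmonics falling inside the
#' analysis band (or every sub-Nyquist harmonic when no band is given).
#' Each A-scan is aligned to its laser's first trigger.  For FWM schemes
#' the repetition-rate shift is checked against
#' \code{\link{delta_f_bounds}}; an inadmissible shift triggers a warning
#' (cross-talk is then expected) but processing proceeds.
#'
#' Separating the combs exactly amounts to one joint least-squares fit of
#' every laser's \{cos, sin\} pairs to the record.  Solving that system
#' directly is expensive, so it is solved by block coordinate descent:
#' after the initial per-laser projection, each refinement sweep
#' re-projects every laser onto the record minus the synthesized
#' contributions of all other lasers.  The cross-comb coupling is weak
#' (admissible \eqn{\delta f} guarantees comb-line spacing of at least
#' the spectral resolution), so a couple of sweeps suppress the residual
#' finite-record leakage between lasers far below the noise floor.
#'
#' @param record An \code{acquisition_record}.
#' @param scheme The \code{\link{multiplex_scheme}} used for the record
#'   (default: the one stored in the record).
#' @param band Optional \code{\link{transducer_band}} restricting the
#'   harmonic set to the detection band.
#' @param method Passed to \code{\link{comb_filter}}.
#' @param refine Number of block-coordinate-descent sweeps towards the
#'   joint least-squares solution (0 = independent per-laser projection;
#'   ignored for single-wavelength schemes and for \code{"fft_bin"}).
#' @return List of \code{averaged_ascan}s, one per wavelength.
#' @export
demux_all <- function(record, scheme = record$scheme, band = NULL,
                      method = c("projection", "fft_bin"), refine = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(scheme, "multiplex_scheme"))
  fs <- record$sampling_rate
  if (scheme$scheme_kind == "FWM" && length(scheme$trains) >= 2 &&
      !is.null(band)) {
    b <- delta_f_bounds(scheme$ref_rep_rate, scheme$trains[[1L]]$n_pulses,
                        length(scheme$trains), band)
    if (scheme$delta_f < b$delta_f_min * (1 - 1e-9) ||
        scheme$delta_f > b$delta_f_max * (1 + 1e-9))
      warning(sprintf(
        "delta_f = %g Hz outside the admissible range [%g, %g] Hz; cross-talk expected",
        scheme$delta_f, b$delta_f_min, b$delta_f_max), call. = FALSE)
  }
  harm_sets <- lapply(seq_along(scheme$trains), function(j) {
    tr <- scheme$trains[[j]]
    if (is.null(band)) {
      k_max <- floor((fs / 2) / tr$rep_rate)
      if (k_max * tr$rep_rate >= fs / 2) k_max <- k_max - 1L
      seq_len(max(1L, k_max))
    } else {
      h <- harmonic_indices(tr$rep_rate, band)
      if (h$n_harmonics == 0L)
        stop("no in-band harmonic for wavelength ", j, call. = FALSE)
      seq(h$k_low, h$k_high)
    }
  })
  n_l <- length(scheme$trains)
  if (method == "fft_bin") {
    return(lapply(seq_len(n_l), function(j) {
      tr <- scheme$trains[[j]]
      comb_filter(record, tr$rep_rate, harm_sets[[j]], method = method,
                  t0 = tr$start_offset, wavelength_id = tr$wavelength_id)
    }))
  }
  # analysis window: the common overlap of all trains, inside which every
  # laser's contribution is exactly periodic (train edges outside the
  # window would otherwise break the comb model and leak between lasers)
  starts <- vapply(scheme$trains, `[[`, numeric(1), "start_offset")
  ends <- vapply(scheme$trains, function(tr)
    tr$start_offset + tr$n_pulses / tr$rep_rate, numeric(1))
  win <- c(max(starts), min(ends))
  i0 <- max(1L, floor(win[1] * fs) + 1L)
  i1 <- min(length(record$samples), floor(win[2] * fs + 1e-9))
  if (i1 <= i0) stop("trains do not overlap in time", call. = FALSE)
  x <- record$samples[i0:i1]
  toff <- (i0 - 1L) / fs
  tt <- (seq.int(i0, i1) - 1L) / fs
  rates <- vapply(scheme$trains, `[[`, numeric(1), "rep_rate")
  proj <- vector("list", n_l)
  contrib <- vector("list", n_l)
  resid <- x
  for (j in seq_len(n_l)) {
    proj[[j]] <- .project_harmonics(resid, fs, rates[j], harm_sets[[j]],
                                    t_offset = toff)
    contrib[[j]] <- .synthesize_comb_long(proj[[j]]$harmonics,
                                          proj[[j]]$coef, rates[j], tt)
    resid <- resid - contrib[[j]]
  }
  for (sweep in seq_len(refine)) {
    for (j in seq_len(n_l)) {
      target <- resid + contrib[[j]]
      proj[[j]] <- .project_harmonics(target, fs, rates[j], harm_sets[[j]],
                                      t_offset = toff)
      new_contrib <- .synthesize_comb_long(proj[[j]]$harmonics,
                                           proj[[j]]$coef, rates[j], tt)
      resid <- target - new_contrib
      contrib[[j]] <- new_contrib
    }
  }
  lapply(seq_len(n_l), function(j) {
    tr <- scheme$trains[[j]]
    p_len <- round(fs / tr$rep_rate)
    times <- tr$start_offset + (seq_len(p_len) - 1) / fs
    samples <- .synthesize_comb(proj[[j]]$harmonics, proj[[j]]$coef,
                                tr$rep_rate, times)
    .new_ascan(samples, fs, tr$rep_rate, tr$wavelength_id,
               harmonics_used = proj[[j]]$harmonics,
               spectrum = proj[[j]]$coef, t0 = tr$start_offset)
  })
}

#' Correct per-pulse energy and timing fluctuations
#'
#' Divides each repetition period by its relative pulse energy and shifts
#' it by its timing offset (linear-interpolation resampling), using a
#' per-pulse reference such as a photodiode pick-off.  With a perfect
#' reference the demultiplexed SNR of a jittered record is restored to
#' within about 1 dB of the jitter-free case.
#'
#' @param record An \code{acquisition_record}.
#' @param wavelength_id Which laser's period structure to correct on
#'   (periods are taken relative to that laser's triggers).
#' @param energy_factors Relative per-pulse energies (default: the
#'   record's stored simulated reference).
#' @param timing_offsets Per-pulse timing offsets in seconds (default: the
#'   record's stored simulated reference).
#' @return A corrected \code{acquisition_record}.
#' @export
correct_pulse_variations <- function(record, wavelength_id = 1L,
                                     energy_factors = NULL,
                                     timing_offsets = NULL) {
  j <- wavelength_id
  trig <- record$trigger_times[[j]]
  if (is.null(energy_factors)) energy_factors <- record$energy_factors[[j]]
  if (is.null(timing_offsets)) timing_offsets <- record$timing_offsets[[j]]
  np <- length(trig)
  if (length(energy_factors) != np || length(timing_offsets) != np)
    stop("reference must cover every pulse", call. = FALSE)
  fs <- record$sampling_rate
  x <- record$samples
  tt <- (seq_along(x) - 1) / fs
  period <- trig[2L] - trig[1L]
  if (np < 2L) period <- record$duration
  out <- x
  for (k in seq_len(np)) {
    lo <- trig[k]
    hi <- if (k < np) trig[k + 1L] else lo + period
    idx <- which(tt >= lo & tt < hi)
    if (length(idx) == 0L) next
    shifted <- stats::approx(tt, x, xout = tt[idx] + timing_offsets[k],
                             rule = 2)$y
    out[idx] <- shifted / energy_factors[k]
  }
  rec <- record
  rec$samples <- out
  rec$energy_factors[[j]] <- rep(1, np)
  rec$timing_offsets[[j]] <- rep(0, np)
  rec
}

#' Signal-to-noise ratio of an averaged A-scan
#'
#' Signal intensity is the peak absolute amplitude inside the signal
#' window; the noise floor is the standard deviation inside a disjoint
#' noise window; SNR is \eqn{10\log_{10}(S/N)}.
#'
#' @param ascan An \code{averaged_ascan}.
#' @param signal_window,noise_window Two-element numeric vectors
#'   \code{c(t_start, t_end)} in seconds within the period; the windows
#'   must be disjoint and non-empty.
#' @return An object of class \code{"snr_report"}: list with
#'   \code{signal_amplitude}, \code{noise_std}, \code{snr_db} and logical
#'   \code{has_signal} (\code{FALSE} when the peak does not rise 3x above
#'   the noise floor, flagging a likely no-signal window).
#' @export
measure_snr <- function(ascan, signal_window, noise_window) {
  stopifnot(length(signal_window) == 2L, length(noise_window) == 2L)
  if (max(signal_window[1], noise_window[1]) <
      min(signal_window[2], noise_window[2]))
    stop("signal and noise windows must be disjoint", call. = FALSE)
  tt <- ascan$t0 + (seq_along(ascan$samples) - 1) / ascan$sampling_rate
  rel <- tt - ascan$t0
  sig <- ascan$samples[rel >= signal_window[1] & rel < signal_window[2]]
  noi <- ascan$samples[rel >= noise_window[1] & rel < noise_window[2]]
  if (length(sig) == 0L || length(noi) < 2L)
    stop("empty signal or noise window", call. = FALSE)
  s <- max(abs(sig))
  n <- stats::sd(noi)
  structure(
    list(signal_amplitude = s, noise_std = n, snr_db = snr_db(s, n),
         has_signal = s > 3 * n),
    class = "snr_report"
  )
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("SNR: S = %.4g V, N = %.4g V -> %.1f dB%s\n",
              x$signal_amplitude, x$noise_std, x$snr_db,
              if (x$has_signal) "" else " (no clear signal)"))
  invisible(x)
}

#' Cross-talk matrix between demultiplexed wavelengths
#'
#' Entry (i, j) is the peak amplitude of wavelength i's A-scan inside
#' wavelength j's signal window, relative to the peak in its own window,
#' in dB (diagonal 0 by construction).  Off-diagonal entries near 0 dB
#' mean total cross-talk; strongly negative entries mean clean
#' separation.
#'
#' @param ascans List of \code{averaged_ascan}s.
#' @param windows List (one per wavelength) of two-element time windows in
#'   seconds, relative to each A-scan's period start, marking where that
#'   wavelength's true signal lies.
#' @return Square matrix of dB values.
#' @export
crosstalk_db <- function(ascans, windows) {
  n <- length(ascans)
  if (length(windows) != n)
    stop("one window per wavelength required", call. = FALSE)
  peak_in <- function(a, w) {
    rel <- (seq_along(a$samples) - 1) / a$sampling_rate
    v <- a$samples[rel >= w[1] & rel < w[2]]
    if (length(v) == 0L) stop("window outside period", call. = FALSE)
    max(abs(v))
  }
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    own <- peak_in(ascans[[i]], windows[[i]])
    for (j in seq_len(n)) {
      m[i, j] <- 10 * log10(peak_in(ascans[[i]], windows[[j]]) / own)
    }
  }
  m
}
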
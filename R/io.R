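# Persistence, configuration and the canonical synthetic fixture suite.

.record_format_version <- "1"

#' Save / load an acquisition record
#'
#' Records are stored with R's native serialization together with a
#' format-version attribute; loading checks the version and the presence
#' of every dataset, and the round-trip is bitwise exact.
#'
#' @param record An \code{acquisition_record}.
#' @param path File path.
#' @return \code{save_record} returns \code{path} invisibly;
#'   \code{load_record} returns the \code{acquisition_record}.
#' @export
save_record <- function(record, path) {
  stopifnot(inherits(record, "acquisition_record"))
  obj <- list(version = .record_format_version, record = record)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_record
#' @export
load_record <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$version))
    stop("not a saved acquisition record", call. = FALSE)
  if (!identical(obj$version, .record_format_version))
    stop("unsupported record format version: ", obj$version, call. = FALSE)
  rec <- obj$record
  needed <- c("samples", "sampling_rate", "duration", "scheme",
              "trigger_times")
  missing <- setdiff(needed, names(rec))
  if (length(missing))
    stop("saved record is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rec
}

.config_keys <- c("ref_rep_rate", "delta_f", "n_wavelengths", "n_pulses",
                  "pulse_width", "pulse_energy", "scheme_kind",
                  "f_low", "f_high", "speed_of_sound", "sampling_rate",
                  "white_noise_std", "emi_amplitude", "seed",
                  "absorber_depths", "absorber_amplitudes")

#' Read / write a run configuration
#'
#' Plain-text key-value configuration (YAML) describing one simulation /
#' demultiplexing run: scheme parameters, transducer band, medium, noise
#' and phantom.  The schema is closed — unknown keys are an error — and a
#' configuration round-trips losslessly.
#'
#' @param path File path.
#' @param config Named list of configuration values (see
#'   \code{\link{default_run_config}} for the keys).
#' @return \code{read_run_config} returns the validated named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(ref_rep_rate = 200e3, delta_f = 125, n_wavelengths = 4L,
       n_pulses = c(100L, 101L, 101L, 101L),
       pulse_width = c(6.7e-9, 6.7e-9, 10.2e-9, 10.2e-9),
       pulse_energy = c(189e-9, 137e-9, 142e-9, 153e-9),
       scheme_kind = "FWM", f_low = 22e6, f_high = 78e6,
       speed_of_sound = 1500, sampling_rate = 200e6,
       white_noise_std = 1e-3, emi_amplitude = 0, seed = 1L,
       absorber_depths = c(1e-3, 2e-3, 3e-3, 4e-3),
       absorber_amplitudes = diag(4))
}

#' Build a multiplex scheme from a run configuration
#'
#' @param config Named list as returned by \code{\link{read_run_config}}.
#' @return A \code{\link{multiplex_scheme}}.
#' @export
scheme_from_config <- function(config) {
  n <- config$n_wavelengths
  if (identical(config$scheme_kind, "FWM")) {
    fwm_scheme(config$ref_rep_rate, config$delta_f, n,
               n_pulses = config$n_pulses,
               pulse_width = config$pulse_width,
               pulse_energy = config$pulse_energy)
  } else {
    td_interleaved_scheme(config$ref_rep_rate, n,
                          n_pulses = config$n_pulses,
                          pulse_width = config$pulse_width,
                          pulse_energy = config$pulse_energy)
  }
}

#' Canonical synthetic fixture suite
#'
#' Deterministic set of small acquisition records covering the scenarios
#' the pipeline must handle: a single-wavelength absorber-layer record, a
#' four-wavelength time-interleaved record, slow and long time-sharing
#' variants, the four-wavelength frequency-multiplexed record with the
#' reference diode parameters, and a noise-only record.  All records share
#' a disjoint one-absorber-per-wavelength phantom so that cross-talk is
#' directly measurable.
#'
#' In addition, \code{oxygen_challenge} holds a two-frame, two-wavelength
#' series in which the wavelength-2 absorption doubles between frames —
#' the stepped input for the oxygenation-ratio read-out.
#'
#' @param seed Integer seed fixing every stochastic draw.
#' @param sampling_rate Sampling rate in Hz.
#' @param noise_std White-noise standard deviation (volts).
#' @return Named list with \code{acquisition_record} elements
#'   \code{single_wavelength}, \code{td_interleaved}, \code{td_slow},
#'   \code{td_long}, \code{fwm}, \code{noise_only}, plus
#'   \code{oxygen_challenge}, a list of two records.
#' @export
fixture_suite <- function(seed = 1L, sampling_rate = 200e6,
                          noise_std = 2e-3) {
  tx <- transducer_model()
  med <- medium()
  phantom <- lapply(1:4, function(j)
    absorber(j * 1e-3, per_wavelength_amplitude = as.numeric(1:4 == j)))
  nm <- function(s) noise_model(white_noise_std = noise_std,
                                emi_amplitude = 0.5 * noise_std,
                                seed = seed + s)
  ref <- reference_scheme()
  single <- fwm_scheme(200e3, 0, 1, n_pulses = 50,
                       pulse_width = 6.7e-9, pulse_energy = 189e-9)
  tdi <- td_interleaved_scheme(200e3, 4, n_pulses = 50,
                               pulse_width = c(6.7e-9, 6.7e-9, 10.2e-9, 10.2e-9),
                               pulse_energy = c(189e-9, 137e-9, 142e-9, 153e-9))
  slow <- td_interleaved_scheme(50e3, 4, n_pulses = 13,
                                pulse_width = c(6.7e-9, 6.7e-9, 10.2e-9, 10.2e-9),
                                pulse_energy = c(189e-9, 137e-9, 142e-9, 153e-9))
  long <- td_interleaved_scheme(50e3, 4, n_pulses = 50,
                                pulse_width = c(6.7e-9, 6.7e-9, 10.2e-9, 10.2e-9),
                                pulse_energy = c(189e-9, 137e-9, 142e-9, 153e-9))
  list(
    single_wavelength = simulate_record(single, phantom[1L], tx, nm(1L),
                                        med, sampling_rate),
    td_interleaved = simulate_record(tdi, phantom, tx, nm(2L), med,
                                     sampling_rate),
    td_slow = simulate_record(slow, phantom, tx, nm(3L), med,
                              sampling_rate),
    td_long = simulate_record(long, phantom, tx, nm(4L), med,
                              sampling_rate),
    fwm = simulate_record(ref, phantom, tx, nm(5L), med, sampling_rate),
    noise_only = simulate_record(single, list(), tx, nm(6L), med,
                                 sampling_rate),
    oxygen_challenge = {
      duo <- fwm_scheme(200e3, 125, 2, n_pulses = c(20, 21),
                        pulse_width = 6.7e-9,
                        pulse_energy = c(189e-9, 137e-9))
      lapply(1:2, function(frame) {
        ph <- list(absorber(2e-3,
                            per_wavelength_amplitude = c(1, 0.8 * frame)))
        simulate_record(duo, ph, tx, nm(6L + frame), med, sampling_rate)
      })
    }
  )
}
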
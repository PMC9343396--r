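test_that("depth of view follows v_s * T / n_shared", {
  expect_equal(depth_of_view(200e3, soft_tissue()), 7.5e-3)
  expect_equal(depth_of_view(200e3, soft_tissue(), n_shared = 4), 1.875e-3)
  expect_equal(depth_of_view(50e3, soft_tissue()), 30e-3)
  # sharing the period never changes the total depth budget
  for (n in 1:6)
    expect_equal(depth_of_view(200e3, soft_tissue(), n) * n, 7.5e-3)
  expect_error(depth_of_view(-1, soft_tissue()), "positive")
  expect_error(depth_of_view(200e3, soft_tissue(), 0), "positive")
})

test_that("acquisition time and spectral resolution are reciprocal pairs", {
  expect_equal(acquisition_time(200, 200e3), 1e-3)
  expect_equal(acquisition_time(200, 50e3), 4e-3)
  expect_equal(acquisition_time(100, 200e3), 0.5e-3)
  expect_equal(frequency_resolution(1e-3), 1e3)
  expect_equal(frequency_resolution(0.5e-3), 2e3)
  expect_equal(frequency_resolution(4e-3), 250)
  expect_error(acquisition_time(0, 200e3), "positive")
  expect_error(frequency_resolution(0), "positive")
})

test_that("harmonic index range respects inclusive band edges", {
  ks <- harmonic_indices(200e3, ust_band())
  expect_equal(ks$k_low, 110L)
  expect_equal(ks$k_high, 390L)
  expect_equal(ks$n_harmonics, 281L)
  ks2 <- harmonic_indices(200e3, transducer_band(0.1e6, 0.45e6))
  expect_equal(c(ks2$k_low, ks2$k_high), c(1L, 2L))
  # band entirely below the fundamental: empty range signalled by k_low > k_high
  ks3 <- harmonic_indices(200e3, transducer_band(10e3, 90e3))
  expect_equal(ks3$n_harmonics, 0L)
  expect_gt(ks3$k_low, ks3$k_high)
  # a harmonic exactly on the band edge counts as in-band
  ks4 <- harmonic_indices(200e3, transducer_band(22e6, 78e6))
  expect_equal(ks4$k_low * 200e3, 22e6)
  expect_equal(ks4$k_high * 200e3, 78e6)
})

test_that("admissible delta_f range matches the closed-form bounds", {
  b <- delta_f_bounds(200e3, 100, 4, ust_band())
  expect_equal(b$df, 2000)
  expect_equal(b$delta_f_min, 2000 / 110)
  expect_equal(b$delta_f_max, (200e3 - 2000) / (390 * 3))
  expect_true(b$feasible)
  # the operating shift of the reference system is admissible
  expect_gt(125, b$delta_f_min)
  expect_lt(125, b$delta_f_max)
  # upper bound scales as 1/(N-1)
  b2 <- delta_f_bounds(200e3, 100, 2, ust_band())
  expect_equal(b2$delta_f_max, 3 * b$delta_f_max)
  expect_error(delta_f_bounds(200e3, 100, 1, ust_band()), "n_wavelengths")
  expect_error(delta_f_bounds(200e3, 100, 4, transducer_band(10e3, 90e3)),
               "no harmonic")
})

test_that("brute-force comb enumeration agrees with the closed-form verdict", {
  configs <- expand.grid(np = c(20, 50, 100, 400), n = c(2, 4, 8, 16))
  for (i in seq_len(nrow(configs))) {
    np <- configs$np[i]; n <- configs$n[i]
    b <- delta_f_bounds(200e3, np, n, ust_band())
    if (b$feasible) {
      # every admissible shift keeps all cross-laser line pairs >= df apart
      for (df_try in c(b$delta_f_min, (b$delta_f_min + b$delta_f_max) / 2,
                       b$delta_f_max))
        expect_true(comb_lines_separated(200e3, df_try, np, n, ust_band()),
                    label = sprintf("np=%d n=%d delta_f=%g", np, n, df_try))
      # shifts beyond the upper bound collide at the top of the band
      expect_false(comb_lines_separated(200e3, b$delta_f_max * 1.2, np, n,
                                        ust_band()))
    } else {
      # no shift can satisfy both ends: the candidates that fix one end
      # must violate the other
      expect_false(comb_lines_separated(200e3, b$delta_f_min, np, n,
                                        ust_band()))
    }
  }
  # shifts below the lower bound collide at the bottom of the band
  expect_false(comb_lines_separated(200e3, 5, 100, 4, ust_band()))
})

test_that("wavelength capacity searches reproduce the design-point values", {
  expect_equal(max_wavelengths_fwm(200e3, 100, ust_band()), 28L)
  expect_equal(max_wavelengths_td(200e3, soft_tissue(), 1.5e-3), 5L)
  expect_equal(max_wavelengths_td(200e3, soft_tissue(), 7.5e-3), 1L)
  expect_equal(max_wavelengths_td(200e3, soft_tissue(), 0.75e-3), 10L)
  # brute-force search over N agrees with the linear scan
  feasible_n <- function(n) delta_f_bounds(200e3, 100, n, ust_band())$feasible
  expect_true(all(vapply(2:28, feasible_n, logical(1))))
  expect_false(feasible_n(29))
  # monotone: more pulses (finer df) cannot fit fewer
  expect_gte(max_wavelengths_fwm(200e3, 400, ust_band()), 28L)
  # a band holding a single harmonic leaves only the spectral-resolution
  # constraint: capacity saturates at N_p combs packed df apart
  narrow <- transducer_band(22e6, 22.1e6)
  expect_equal(harmonic_indices(200e3, narrow)$n_harmonics, 1L)
  expect_identical(max_wavelengths_fwm(200e3, 100, narrow), 100L)
})

test_that("minimum pulse count is the least feasible train length", {
  expect_equal(min_pulses(200e3, 4, ust_band()), 12L)
  expect_equal(min_pulses(200e3, 1, ust_band()), 1L)
  # scan verification around the reported minimum
  expect_false(delta_f_bounds(200e3, 11, 4, ust_band())$feasible)
  expect_true(delta_f_bounds(200e3, 12, 4, ust_band())$feasible)
  # consistency with the capacity search at N_p = 100
  expect_lte(min_pulses(200e3, 28, ust_band()), 100L)
  expect_gt(min_pulses(200e3, 29, ust_band()), 100L)
})

test_that("SNR arithmetic follows 10 log10(S/N)", {
  expect_equal(round(snr_db(12e-3, 90.6e-6), 1), 21.2)
  expect_equal(snr_db(0.5, 0.5), 0)
  # the stated formula gives 18.7 dB for the 50-pulse noise floor
  expect_equal(round(snr_db(12e-3, 161.6e-6), 1), 18.7)
  expect_equal(round(averaging_gain_db(200, 50), 1), 3.0)
  expect_equal(averaging_gain_db(7, 7), 0)
  expect_equal(averaging_gain_db(100, 1), 10)
  expect_error(snr_db(0, 1), "positive")
})

test_that("exposure report multiplies fluence by the combined rate", {
  # reference operating point: 19.8 uJ/cm2 per pulse at 200 kHz combined
  area <- sum(c(189e-9, 137e-9, 142e-9, 153e-9)) / 19.8e-6
  rep <- exposure(c(189e-9, 137e-9, 142e-9, 153e-9), area, 200e3)
  expect_equal(rep$fluence_per_pulse, 19.8e-6)
  expect_equal(rep$mean_irradiance, 3.96)
  expect_true(rep$compliant)
  expect_equal(sum(c(189e-9, 137e-9, 142e-9, 153e-9)), 621e-9)
  # identity holds exactly for arbitrary inputs
  for (rate in c(1e3, 200e3, 5e6)) {
    r <- exposure(1e-7, 0.01, rate)
    expect_identical(r$mean_irradiance, r$fluence_per_pulse * rate)
  }
  z <- exposure(numeric(4), 0.01, 200e3)
  expect_equal(z$fluence_per_pulse, 0)
  expect_true(z$compliant)
  bad <- exposure(1, 0.01, 200e3)  # 100 J/cm2 per pulse
  expect_false(bad$compliant)
})

test_that("scheme trade-off table reports what each strategy sacrifices", {
  fwm <- fwm_scheme(200e3, 125, 4, n_pulses = 200)
  t_fwm <- scheme_tradeoffs(fwm)
  expect_equal(t_fwm$dov[1], 7.5e-3)
  expect_equal(unique(t_fwm$snr_factor), 1)
  expect_equal(t_fwm$t_acq_total[1], 1e-3)
  tdi <- td_interleaved_scheme(200e3, 4, n_pulses = 200)
  t_tdi <- scheme_tradeoffs(tdi)
  expect_equal(t_tdi$dov[1], 1.875e-3)
  slow <- td_interleaved_scheme(50e3, 4, n_pulses = 50)
  slow$scheme_kind <- "TD_SLOW"
  t_slow <- scheme_tradeoffs(slow)
  expect_equal(t_slow$dov[1], 7.5e-3)   # full depth retained
  expect_equal(t_slow$snr_factor[1], 0.5)  # quarter the pulses -> half SNR
  # single wavelength: every strategy coincides
  one <- fwm_scheme(200e3, 0, 1, n_pulses = 100)
  t_one <- scheme_tradeoffs(one)
  for (kind in c("TD_INTERLEAVE", "TD_SLOW", "TD_LONG")) {
    alt <- one
    alt$scheme_kind <- kind
    expect_equal(scheme_tradeoffs(alt)$dov, t_one$dov)
    expect_equal(scheme_tradeoffs(alt)$t_acq_total, t_one$t_acq_total)
  }
})

test_that("design aggregate collects every derived quantity coherently", {
  dl <- design_limits(200e3, 100, 4, ust_band())
  expect_equal(dl$dov, 7.5e-3)
  expect_equal(dl$df, 1 / dl$t_acq)
  expect_equal(dl$n_harmonics, dl$k_high - dl$k_low + 1L)
  expect_lte(dl$delta_f_min, dl$delta_f_max)
  expect_equal(dl$n_max_fwm, 28L)
  expect_equal(dl$n_max_td, 5L)
  df <- as.data.frame(dl)
  expect_equal(nrow(df), 12L)
  expect_true(all(c("quantity", "value") %in% names(df)))
})

test_that("scheme constructors enforce their invariants", {
  expect_error(pulse_train(1, 445, 6e-6, 200e3, 10), "pulse_width")
  expect_error(pulse_train(1, 445, 6.7e-9, 200e3, 0), "n_pulses")
  tr <- lapply(1:3, function(j)
    pulse_train(j, 445, 6.7e-9, 200e3 + (j - 1) * 100, 10))
  expect_error(multiplex_scheme(tr, "FWM", delta_f = 50), "delta_f")
  expect_silent(multiplex_scheme(tr, "FWM", delta_f = 100))
  expect_error(multiplex_scheme(tr, "TD_INTERLEAVE"), "share")
  sc <- reference_scheme()
  expect_equal(length(sc), 4L)
  expect_equal(vapply(sc$trains, `[[`, numeric(1), "rep_rate"),
               c(200000, 200125, 200250, 200375))
  expect_equal(vapply(sc$trains, `[[`, numeric(1), "pulse_energy"),
               c(189e-9, 137e-9, 142e-9, 153e-9))
  b <- transducer_band(center = 50e6, fractional_bandwidth = 1.12)
  expect_equal(b$f_low, 22e6)
  expect_equal(b$f_high, 78e6)
})
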
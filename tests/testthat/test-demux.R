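test_that("period averaging is exact on periodic input and reduces noise", {
  fs <- 10e6; f <- 100e3; P <- 100
  # constant record: average is the same constant
  rec_const <- list(samples = rep(2.5, 10 * P), sampling_rate = fs)
  expect_equal(td_average(rec_const, f, 10)$samples, rep(2.5, P))
  # periodic record: any period reproduced exactly
  one <- sin(2 * pi * 7 * (0:(P - 1)) / P) + 0.3
  rec_per <- list(samples = rep(one, 25), sampling_rate = fs)
  expect_equal(td_average(rec_per, f, 25)$samples, one, tolerance = 1e-12)
  # white noise shrinks by sqrt(N_p)
  set.seed(101)
  ratios <- replicate(6, {
    rec <- list(samples = rnorm(100 * P), sampling_rate = fs)
    1 / sd(td_average(rec, f, 100)$samples)
  })
  expect_equal(mean(ratios), 10, tolerance = 0.05 * 10)
  expect_error(td_average(rec_const, f, 100), "shorter")
})

test_that("comb filtering selects on-comb content and rejects off-comb", {
  fs <- 10e6; f <- 100e3
  tt <- (0:9999) / fs  # integer number of periods
  on <- list(samples = sin(2 * pi * 5 * f * tt), sampling_rate = fs)
  a_on <- comb_filter(on, f, 1:40)
  expect_equal(max(abs(a_on$samples)), 1, tolerance = 1e-9)
  off <- list(samples = sin(2 * pi * 5.5 * f * tt), sampling_rate = fs)
  a_off <- comb_filter(off, f, 1:40)
  expect_lt(max(abs(a_off$samples)), 0.01)
  expect_error(comb_filter(on, f, integer(0)), "non-empty")
  expect_error(comb_filter(on, f, 60), "Nyquist")
  expect_error(comb_filter(on, f, c(0, 3)), ">= 1")
})

test_that("comb filter with all harmonics equals DC-free period averaging", {
  fs <- 10e6; f <- 80e3; P <- 125  # odd samples per period: no Nyquist bin
  set.seed(7)
  # arbitrary record over an integer number of periods
  rec <- list(samples = rnorm(50 * P), sampling_rate = fs)
  ta <- td_average(rec, f, 50)
  cf <- comb_filter(rec, f, 1:62)  # all sub-Nyquist harmonics
  dev <- max(abs(cf$samples - (ta$samples - mean(ta$samples))))
  expect_lt(dev / diff(range(ta$samples)), 1e-9)
  # nearest-FFT-bin mode agrees when harmonics fall on bins
  cb <- comb_filter(rec, f, 1:62, method = "fft_bin")
  expect_equal(cb$samples, cf$samples, tolerance = 1e-9)
})

test_that("SNR gain of both averaging routes scales as sqrt(N_p)", {
  fs <- 10e6; f <- 100e3; P <- 100
  set.seed(11)
  nps <- c(8, 32, 128)
  gains <- sapply(nps, function(np) {
    mean(replicate(5, {
      x <- rnorm(np * P)
      rec <- list(samples = x, sampling_rate = fs)
      g_td <- sd(x) / sd(td_average(rec, f, np)$samples)
      g_cf <- sd(x) / sd(comb_filter(rec, f, 1:49)$samples)
      sqrt(g_td * g_cf)
    }))
  })
  slope <- coef(lm(log(gains) ~ log(nps)))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.1)
})

test_that("multi-wavelength demultiplexing separates disjoint absorbers", {
  # two-laser frequency-multiplexed record, each laser lighting one absorber
  sc <- fwm_scheme(200e3, 125, 2, n_pulses = c(40, 41),
                   pulse_width = 6.7e-9, pulse_energy = c(189e-9, 137e-9))
  tx <- transducer_model()
  ph <- disjoint_phantom(2)
  rec <- simulate_record(sc, ph, tx, noise_model(white_noise_std = 5e-4,
                                                 seed = 21),
                         soft_tissue(), 200e6)
  asc <- demux_all(rec)
  wins <- arrival_windows(2)
  # each wavelength sees its own absorber well above the noise floor ...
  for (j in 1:2) {
    r <- measure_snr(asc[[j]], wins[[j]], c(3.5e-6, 4.8e-6))
    expect_true(r$has_signal)
    expect_gt(r$snr_db, 10)
  }
  # ... and the other wavelength's absorber at most at 1% amplitude
  ct <- crosstalk_db(asc, wins)
  expect_lte(max(ct[row(ct) != col(ct)]), -20)
  # compare against independently simulated single-laser records
  for (j in 1:2) {
    solo_tr <- sc$trains[[j]]
    solo <- multiplex_scheme(list(pulse_train(1, solo_tr$wavelength_nm,
                                              solo_tr$pulse_width,
                                              solo_tr$rep_rate,
                                              solo_tr$n_pulses,
                                              solo_tr$pulse_energy)),
                             "FWM")
    rec_solo <- simulate_record(solo, list(absorber(j * 1e-3)), tx,
                                noise_model(seed = 1), soft_tissue(), 200e6)
    a_solo <- demux_all(rec_solo)[[1]]
    n <- min(length(a_solo$samples), length(asc[[j]]$samples))
    scale <- max(abs(a_solo$samples))
    expect_lt(max(abs(a_solo$samples[1:n] - asc[[j]]$samples[1:n])) / scale,
              0.05)
  }
})

test_that("demultiplexing is linear and immune to off-comb interference", {
  sc <- single_laser(30)
  tx <- transducer_model()
  ph <- list(absorber(2e-3))
  rec <- simulate_record(sc, ph, tx, noise_model(seed = 3), soft_tissue(),
                         200e6)
  base <- demux_all(rec)[[1]]$samples
  # linearity: scaling and adding records scales and adds A-scans
  rec2 <- rec
  rec2$samples <- 3 * rec$samples
  expect_equal(demux_all(rec2)[[1]]$samples, 3 * base, tolerance = 1e-9)
  # an interferer halfway between harmonics changes nothing material
  tt <- (seq_along(rec$samples) - 1) / rec$sampling_rate
  rec3 <- rec
  rec3$samples <- rec$samples +
    0.5 * max(abs(rec$samples)) * sin(2 * pi * 50.1e6 * tt)
  pert <- demux_all(rec3)[[1]]$samples
  expect_lt(max(abs(pert - base)) / max(abs(base)), 0.01)
  # zero record yields zero A-scans
  rec0 <- rec
  rec0$samples <- numeric(length(rec$samples))
  expect_equal(max(abs(demux_all(rec0)[[1]]$samples)), 0)
})

test_that("an inadmissible repetition-rate shift triggers a warning", {
  sc <- fwm_scheme(200e3, 5, 4, n_pulses = 100)  # below delta_f_min
  tx <- transducer_model()
  rec <- simulate_record(sc, disjoint_phantom(4), tx, noise_model(seed = 2),
                         soft_tissue(), 200e6, duration = 30e-6)
  expect_warning(demux_all(rec, band = ust_band(), refine = 0),
                 "cross-talk expected")
})

test_that("pulse variation correction restores jitter-degraded SNR", {
  sc <- single_laser(50)
  tx <- transducer_model()
  ph <- list(absorber(2e-3))
  clean <- simulate_record(sc, ph, tx,
                           noise_model(white_noise_std = 5e-3, seed = 9),
                           soft_tissue(), 200e6)
  jit <- simulate_record(sc, ph, tx,
                         noise_model(white_noise_std = 5e-3,
                                     energy_jitter_cv = 0.05,
                                     timing_jitter_std = 2e-9, seed = 9),
                         soft_tissue(), 200e6)
  fixed <- correct_pulse_variations(jit)
  sw <- c(1.2e-6, 1.5e-6); nw <- c(3e-6, 4.8e-6)
  snr_of <- function(r) measure_snr(td_average(r, 200e3, 50), sw, nw)$snr_db
  expect_lt(abs(snr_of(fixed) - snr_of(clean)), 1)
  # a zero-jitter reference is the identity
  same <- correct_pulse_variations(clean)
  expect_equal(same$samples, clean$samples, tolerance = 1e-12)
  expect_error(correct_pulse_variations(clean, energy_factors = 1,
                                        timing_offsets = 0),
               "every pulse")
})

test_that("SNR measurement matches injected amplitude and noise", {
  fs <- 10e6; f <- 100e3; P <- 100
  set.seed(31)
  sigma <- 0.01
  wavelet <- 0.8 * sin(2 * pi * (0:19) / 10) * exp(-((0:19) - 10)^2 / 30)
  reps <- replicate(10, {
    x <- rnorm(P, 0, sigma)
    x[31:50] <- x[31:50] + wavelet
    a <- structure(list(samples = x, sampling_rate = fs, rep_rate = f,
                        period = 1 / f, wavelength_id = 1L, t0 = 0),
                   class = "averaged_ascan")
    measure_snr(a, c(2.5e-6, 5.5e-6), c(6e-6, 10e-6))$snr_db
  })
  expect_equal(mean(reps), 10 * log10(max(abs(wavelet)) / sigma),
               tolerance = 0.5)
  # the worked design-point example
  x <- numeric(P)
  x[10] <- 12e-3
  set.seed(1)
  noise <- rnorm(50, 0, 90.6e-6)
  x[51:100] <- noise * (90.6e-6 / sd(noise)) # exact noise std by scaling
  a <- structure(list(samples = x, sampling_rate = fs, rep_rate = f,
                      period = 1 / f, wavelength_id = 1L, t0 = 0),
                 class = "averaged_ascan")
  r <- measure_snr(a, c(0, 2e-6), c(5e-6, 10e-6))
  expect_equal(round(r$snr_db, 1), 21.2)
  expect_error(measure_snr(a, c(0, 6e-6), c(5e-6, 10e-6)), "disjoint")
})

test_that("cross-talk metric is zero on identical channels", {
  fs <- 10e6
  x <- sin(2 * pi * (0:99) / 20)
  a <- structure(list(samples = x, sampling_rate = fs, rep_rate = 1e5,
                      period = 1e-5, wavelength_id = 1L, t0 = 0),
                 class = "averaged_ascan")
  wins <- list(c(0, 5e-6), c(5e-6, 1e-5))
  m <- crosstalk_db(list(a, a), wins)
  expect_equal(diag(m), c(0, 0))
  expect_equal(m[1, 2], m[2, 1])
  expect_error(crosstalk_db(list(a, a), wins[1]), "one window")
})
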
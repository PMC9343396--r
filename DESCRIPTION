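Package: fwmot
Title: Frequency-Wavelength-Multiplexed Optoacoustic Signal Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing, simulating and processing
    frequency-wavelength-multiplexed optoacoustic (photoacoustic)
    acquisitions.  A pulse train of short optical pulses excites discrete
    frequency combs in the recorded ultrasound trace; wavelengths pulsed at
    slightly shifted repetition rates occupy interleaved combs and are
    recovered by exact-frequency Fourier projection onto each comb.  The
    package provides the multiplexing design calculator (depth of view,
    harmonic index ranges, admissible repetition-rate shifts, wavelength
    capacity, exposure and SNR arithmetic), a forward simulator of
    single-channel acquisition records with transducer band-limiting, EMI
    artifacts, reflections and noise, time-domain and comb-filter
    demultiplexing with jitter correction and cross-talk metrics,
    delay-and-sum B-scan reconstruction with a conic sensitivity section,
    and dual-wavelength oxygenation read-outs (signal ratio and oxygen
    extraction rate).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
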
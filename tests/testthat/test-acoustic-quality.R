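# Band-pass design, 90% energy duration, SNR measurement, quality gate.

test_that("Butterworth band-pass coefficients match the reference design", {
  # frozen oracle: scipy.signal.butter(3, [450, 10000], 'band', fs=24000)
  d <- butter_bandpass(450, 10000, 24000, order = 3)
  b_ref <- c(0.520381051892, 0, -1.561143155677, 0,
             1.561143155677, 0, -0.520381051892)
  a_ref <- c(1, -0.808743412898, -1.453594771604, 0.697794477415,
             1.063642301194, -0.221500929435, -0.270432679431)
  expect_equal(d$b, b_ref, tolerance = 1e-9)
  expect_equal(d$a, a_ref, tolerance = 1e-9)
  expect_error(butter_bandpass(450, 12000, 24000),
               class = "orcaseq_bad_parameter")
})

test_that("bandpass passes in-band tones and rejects out-of-band ones", {
  fs <- 24000
  t <- seq(0, 1, by = 1 / fs)
  tone5k <- sin(2 * pi * 5000 * t)
  y <- bandpass(tone5k, fs)
  core <- seq(fs %/% 4, 3 * fs %/% 4)   # avoid edges
  expect_equal(mean(y[core]^2) / mean(tone5k[core]^2), 1, tolerance = 0.01)

  tone100 <- sin(2 * pi * 100 * t)
  y100 <- bandpass(tone100, fs)
  # zero-phase application doubles the single-pass 39.6 dB attenuation
  att_db <- 10 * log10(mean(tone100[core]^2) / mean(y100[core]^2))
  expect_gt(att_db, 20)

  expect_identical(bandpass(rep(0, 1000), fs), rep(0, 1000))
})

test_that("energy_duration_90 matches closed forms and a cumsum oracle", {
  fs <- 1000
  # uniform energy over 1 s -> 90% duration 0.9 s
  ed <- energy_duration_90(rep(1, fs), fs)
  expect_equal(ed$duration_s, 0.9, tolerance = 2 / fs)

  # point mass: all energy in one sample
  x <- rep(0, 100); x[37] <- 1
  ed <- energy_duration_90(x, fs)
  expect_equal(ed$t5, ed$t95)
  expect_identical(ed$duration_s, 0)
  expect_equal(ed$t5, 36 / fs)

  # linear amplitude ramp vs independent brute-force crossing search
  x <- seq(0, 1, length.out = 500)
  ed <- energy_duration_90(x, fs)
  cs <- 0; i5 <- NA; i95 <- NA
  total <- sum(x^2)
  for (i in seq_along(x)) {
    cs <- cs + x[i]^2
    if (is.na(i5) && cs >= 0.05 * total) i5 <- i
    if (is.na(i95) && cs >= 0.95 * total) i95 <- i
  }
  expect_equal(ed$duration_s, (i95 - i5) / fs)

  expect_error(energy_duration_90(rep(0, 10), fs),
               class = "orcaseq_degenerate_input")
})

test_that("SNR round-trips through the waveform synthesizer", {
  tag <- list(calls = make_calls(c(2, 5), c(3, 5.8), c("A", "B")))
  class(tag) <- "synthetic_tag"
  w <- synthesize_waveform(tag, sample_rate = 24000, call_snr_db = 20,
                           seed = 5)
  m <- measure_snr(w, call = w$annotations[1, ])
  expect_equal(m$snr_db, 20, tolerance = 1)
  expect_equal(diff(m$noise_window), 0.2, tolerance = 1e-9)
  # energy window inside the annotated call
  expect_gte(m$energy_window[1], 2)
  expect_lte(m$energy_window[2], 3)

  w0 <- synthesize_waveform(tag, sample_rate = 24000, call_snr_db = 0,
                            seed = 5)
  m0 <- measure_snr(w0, call = w0$annotations[1, ])
  expect_equal(m0$snr_db, 0, tolerance = 1)
})

test_that("measure_snr is invariant to overall scaling", {
  tag <- list(calls = make_calls(2, 3, "A"))
  class(tag) <- "synthetic_tag"
  w <- synthesize_waveform(tag, sample_rate = 24000, call_snr_db = 15,
                           seed = 9)
  m1 <- measure_snr(w$wave, w$sample_rate, w$annotations[1, ],
                    w$annotations)
  m2 <- measure_snr(w$wave * 10^(7 / 20), w$sample_rate, w$annotations[1, ],
                    w$annotations)
  expect_equal(m1$snr_db, m2$snr_db, tolerance = 1e-9)
  expect_equal(m2$spl_call_db - m1$spl_call_db, 7, tolerance = 1e-9)
})

test_that("a blocked look-back raises the no-noise-window error", {
  # a second call occupies the entire 5 s look-back
  calls <- make_calls(c(1, 6), c(5.95, 7), c("X", "A"))
  tag <- list(calls = calls)
  class(tag) <- "synthetic_tag"
  w <- synthesize_waveform(tag, sample_rate = 24000, seed = 2)
  expect_error(measure_snr(w, call = calls[2, ]),
               class = "orcaseq_no_noise_window")
  all_m <- measure_snr_all(w)
  expect_false(all_m$measured[2])
  expect_true(is.na(all_m$snr_db[2]))
  expect_true(all_m$measured[1])   # first call has open water before it
})

test_that("quality gate applies threshold, override, and audit partition", {
  calls <- make_calls(c(1, 4, 7), c(2, 5, 8), c("A", "B", "C"),
                      snr_db = c(12, 9, 15))
  gr <- quality_gate(calls)
  expect_identical(nrow(gr$retained), 2L)
  expect_identical(gr$audit$reason[2], "excluded_low_snr")

  calls$low_snr_override <- c(FALSE, TRUE, FALSE)
  gr2 <- quality_gate(calls)
  expect_identical(nrow(gr2$retained), 3L)
  expect_identical(gr2$audit$reason[2], "retained_low_snr_override")

  # low perceived quality excluded regardless of SNR
  calls$quality <- c("high", "high", "low")
  gr3 <- quality_gate(calls)
  expect_identical(gr3$audit$reason[3], "excluded_low_quality")

  # gate output is a subset; audit covers every input call
  expect_true(all(gr3$retained$call_id %in% calls$call_id))
  expect_identical(gr3$audit$call_id, calls$call_id)
  expect_identical(gr3$audit$retained, gr3$audit$reason %in%
                     c("retained", "retained_low_snr_override",
                       "retained_snr_unmeasured"))

  empty <- quality_gate(calls[0, ])
  expect_identical(nrow(empty$retained), 0L)
})
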
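test_that("ERB bandwidth matches the closed form and is monotone", {
  expect_equal(erb_bandwidth(1000), 24.7 * 5.37, tolerance = 1e-10)
  expect_equal(erb_bandwidth(1e-6), 24.7, tolerance = 1e-3)
  f <- c(125, 250, 500, 1000, 2000, 4000, 8000)
  expect_true(all(diff(erb_bandwidth(f)) > 0))
  expect_error(erb_bandwidth(0), "positive")
})

test_that("warble tone carries the specified frequency modulation", {
  spec <- warble_tone_spec(fc = 1000, fr = 4, fe = 0.043, duration = 1)
  w <- synth_warble_tone(spec)
  fi <- instantaneous_frequency(w)
  n <- length(fi)
  core <- fi[round(0.15 * n):round(0.85 * n)]   # skip ramps/edges
  # peak excursion 4.3% of the carrier
  exc_pct <- max(abs(core - 1000)) / 1000 * 100
  expect_equal(exc_pct, 4.3, tolerance = 0.02)
  # instantaneous frequency confined to fc*(1 +/- fe)
  expect_true(all(core >= 1000 * (1 - 0.0432) & core <= 1000 * (1 + 0.0432)))
  # modulation rate 4 Hz: finely-gridded sinusoid projection of the
  # frequency track
  d <- core - mean(core)
  tt <- seq_along(d) / w$sample_rate
  cand <- seq(3, 5, by = 0.01)
  amp <- vapply(cand, function(fr)
    Mod(sum(d * exp(-2i * pi * fr * tt))), numeric(1))
  expect_equal(cand[which.max(amp)], 4, tolerance = 0.02)
  # requested level honoured
  expect_equal(wave_level(w), 80, tolerance = 0.1)
})

test_that("zero excursion gives a pure tone", {
  w <- synth_warble_tone(warble_tone_spec(fc = 1000, fe = 0, duration = 0.5))
  fi <- instantaneous_frequency(w)
  core <- fi[round(0.2 * length(fi)):round(0.8 * length(fi))]
  expect_lt(max(abs(core - 1000)), 1)
})

test_that("warble spec validation rejects bad parameters", {
  expect_error(warble_tone_spec(fc = -100), "positive")
  expect_error(warble_tone_spec(fc = 1000, fe = 1.2), "fe")
  expect_error(warble_tone_spec(fc = 1000, duration = 0.05, ramp = 0.05),
               "duration")
})

test_that("TEN band is flat per ERB and sits at the requested level", {
  spec <- masker_spec("TEN_flat", center = 1000, level_per_erb = 70,
                      duration = 6)
  w <- synth_ten_band(spec, seed = 42)
  expect_equal(erb_level_db(w, 1000), 70, tolerance = 0.5)
  # ERB-wide windows fully inside the band agree within 1 dB
  probes <- 1000 * 2^seq(-0.35, 0.35, by = 0.1)
  lev <- vapply(probes, function(f) erb_level_db(w, f), numeric(1))
  expect_lt(max(lev) - min(lev), 1)
  expect_error(synth_ten_band(masker_spec("TEN_flat", center = 1000,
                                          duration = 0)), "duration")
  expect_error(synth_ten_band(masker_spec("TEN_flat", center = 20000,
                                          duration = 1)), "Nyquist")
})

test_that("condition maskers derive correctly from the reference TEN", {
  base <- masker_spec("TEN_flat", center = 2000, duration = 2)
  expect_identical(derive_condition_masker(2000, "N", base), base)
  # idempotent for N
  expect_identical(derive_condition_masker(
    2000, "N", derive_condition_masker(2000, "N", base)), base)
  s <- derive_condition_masker(2000, "S", base)
  expect_equal(s$center, 2200)
  expect_equal(s$kind, "TEN_shifted")
  t <- derive_condition_masker(2000, "T", base)
  expect_equal(t$kind, "TEN_modulated")
  expect_equal(t$mod_rate, 4)
  expect_error(derive_condition_masker(2000, "X", base), "condition")
  # rendered modulated masker has a 4-Hz envelope periodicity
  wm <- synth_ten_band(t, seed = 3)
  env <- abs(drop(wm$samples))
  env <- stats::filter(env, rep(1 / 2400, 2400), sides = 2)
  env <- env[!is.na(env)] - mean(env, na.rm = TRUE)
  sp <- Mod(stats::fft(env))[seq_len(floor(length(env) / 2))]
  f_axis <- (seq_along(sp) - 1) * wm$sample_rate / length(env)
  expect_equal(f_axis[which.max(sp[-1]) + 1], 4, tolerance = 0.3)
})

test_that("STM ripple depth follows the modulation level", {
  expect_equal(10^(-3 / 20), 0.708, tolerance = 1e-3)
  contrast <- vapply(c(-Inf, -10, -3), function(ml) {
    sp <- stm_spec(modulation_level = ml, duration = 1)
    stm_ripple_contrast(synth_stm_noise(sp, seed = 5), sp)
  }, numeric(1))
  expect_lt(contrast[1], 0.05)           # unmodulated: noise floor only
  expect_true(all(diff(contrast) > 0))   # monotone in m
  # demodulated depth tracks the generating m = 10^(ML/20)
  expect_equal(contrast[3], 10^(-3 / 20), tolerance = 0.35)
  expect_error(stm_spec(modulation_level = 1), "<= 0")
})

test_that("STM spectral ripple density matches the spec", {
  sp <- stm_spec(band_center = 800, band_width_oct = 3, spectral_density = 2,
                 temporal_rate = 4, modulation_level = -1, duration = 0.6)
  w <- synth_stm_noise(sp, seed = 8)
  # magnitude profile across log-frequency in a short window, FFT along the
  # octave axis -> peak at the generating density (cycles/octave)
  x <- drop(w$samples)
  win <- round(w$sample_rate / sp$temporal_rate / 4)
  seg <- x[10000:(10000 + win - 1)]
  X <- Mod(stats::fft(seg))[seq_len(win %/% 2)]
  f <- (seq_len(win %/% 2) - 1) * w$sample_rate / win
  oct_axis <- seq(0.1, 2.9, by = 1 / 32)   # octaves above the lower edge
  prof <- vapply(oct_axis, function(o) {
    sel <- abs(f - 400 * 2^o) < 25
    mean(X[sel])
  }, numeric(1))
  prof <- prof - mean(prof)
  ps <- Mod(stats::fft(prof))[seq_len(length(prof) %/% 2)]
  dens_axis <- (seq_along(ps) - 1) / (length(prof) / 32)
  expect_equal(dens_axis[which.max(ps[-1]) + 1], 2, tolerance = 0.25)
})

test_that("dichotic noise carries the interaural phase only at contours", {
  spec <- dichotic_noise_spec(duration = 2,
                              contour_freqs = c(400, 600),
                              contour_kind = c("diotic", "dichotic"),
                              ipd_radians = pi)
  w <- synth_dichotic_noise(spec, seed = 9)
  expect_equal(abs(cross_spectral_phase(w, 600, half_bw = 15)), pi,
               tolerance = 0.2)
  # diotic contour and plain regions: in phase
  expect_lt(abs(cross_spectral_phase(w, 400, half_bw = 15)), 0.1)
  expect_lt(abs(cross_spectral_phase(w, 1500, half_bw = 50)), 0.1)
  # high coherence outside the transition bands
  expect_gt(interaural_coherence(w, 900, 1400), 0.95)
  # no contours -> channels bit-identical
  w0 <- synth_dichotic_noise(dichotic_noise_spec(duration = 1), seed = 9)
  expect_identical(w0$samples[, 1], w0$samples[, 2])
  expect_error(dichotic_noise_spec(contour_freqs = 5000,
                                   contour_kind = "dichotic"), "band")
})

test_that("interaural-phase tone sequences follow the ABAB pattern", {
  measure_tone_ipd <- function(w, spec, k) {
    fs <- spec$sample_rate
    nt <- round(spec$tone_duration * fs); ng <- round(spec$gap * fs)
    i0 <- (k - 1) * (nt + ng) + round(0.2 * nt)
    idx <- i0:(i0 + round(0.6 * nt))
    seg <- waveform(w$samples[idx, ], fs)
    cross_spectral_phase(seg, spec$tone_freq, half_bw = 10)
  }
  spec <- ipd_sequence_spec(tone_freq = 500, ipd = pi, pattern = "ABAB")
  w <- synth_ipd_sequence(spec)
  expect_equal(abs(measure_tone_ipd(w, spec, 2)), pi, tolerance = 0.1)
  expect_equal(abs(measure_tone_ipd(w, spec, 4)), pi, tolerance = 0.1)
  expect_lt(abs(measure_tone_ipd(w, spec, 1)), 0.05)
  spec_a <- ipd_sequence_spec(tone_freq = 500, pattern = "AAAA")
  wa <- synth_ipd_sequence(spec_a)
  for (k in 1:4) expect_lt(abs(measure_tone_ipd(wa, spec_a, k)), 0.05)
  # zero-IPD ABAB degenerates to AAAA
  w0 <- synth_ipd_sequence(ipd_sequence_spec(tone_freq = 500, ipd = 0,
                                             pattern = "ABAB"))
  expect_equal(w0$samples, wa$samples)
})

test_that("waveforms are finite, level-settable and WAV-exportable", {
  w <- synth_ten_band(masker_spec("TEN_flat", center = 1000, duration = 0.5),
                      seed = 1)
  expect_true(all(is.finite(w$samples)))
  expect_equal(wave_level(set_level(w, 65)), 65, tolerance = 0.1)
  path <- tempfile(fileext = ".wav")
  write_wav(set_level(w, 80), path)   # 80 dB -> RMS 0.1, no clipping
  info <- file.info(path)
  expect_equal(info$size, 44 + 2 * nrow(w$samples))
  con <- file(path, "rb")
  expect_identical(readChar(con, 4), "RIFF")
  close(con)
})

test_that("stimulus specs serialize to JSON and back", {
  spec <- warble_tone_spec(fc = 2000, level = 75)
  expect_equal(spec_from_json(spec_to_json(spec)), spec)
  m <- masker_spec("TEN_shifted", center = 2200)
  expect_equal(spec_from_json(spec_to_json(m)), m)
})
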
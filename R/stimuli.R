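## Stimulus parameter records and synthesis.
##
## Every stimulus class of the battery is a small validated spec object that
## can be rendered to a `waveform`.  Noise stimuli are synthesized by
## spectral-domain shaping of Gaussian noise with a seeded generator, so any
## waveform is reproducible from (spec, seed).

#' Warble-tone specification
#'
#' A sinusoidally frequency-modulated tone
#' `wt(t) = sin(2*pi*fc*t + (fc*fe/fr) * sin(2*pi*fr*t))`,
#' whose instantaneous frequency swings between `fc*(1-fe)` and `fc*(1+fe)`
#' at rate `fr`.  `fe` is the peak fractional excursion (0.043 = 4.3%).
#'
#' @param fc carrier frequency, Hz
#' @param fr modulation rate, Hz
#' @param fe fractional frequency excursion (peak), 0 <= fe < 1
#' @param level presentation level, dB (package convention; HL/SPL mapping is
#'   the battery config's concern)
#' @param duration,ramp duration and raised-cosine ramp length, s
#' @param sample_rate Hz
#' @export
warble_tone_spec <- function(fc, fr = 4, fe = 0.043, level = 80,
                             duration = 0.5, ramp = 0.05, sample_rate = 48000) {
  if (fc <= 0) stop("fc must be positive")
  if (fe < 0 || fe >= 1) stop("fe must be in [0, 1)")
  if (fr <= 0) stop("fr must be positive")
  if (duration <= 2 * ramp) stop("duration must exceed twice the ramp")
  structure(list(fc = fc, fr = fr, fe = fe, level = level,
                 duration = duration, ramp = ramp, sample_rate = sample_rate),
            class = c("warble_tone_spec", "stimulus_spec"))
}

#' Synthesize a warble tone
#' @param spec a [warble_tone_spec()]
#' @return a mono `waveform` at `spec$level`
#' @export
synth_warble_tone <- function(spec) {
  stopifnot(inherits(spec, "warble_tone_spec"))
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  ph <- 2 * pi * spec$fc * t +
    (spec$fc * spec$fe / spec$fr) * sin(2 * pi * spec$fr * t)
  x <- sin(ph) * raised_cosine_gate(n, round(spec$ramp * spec$sample_rate))
  set_level(waveform(x, spec$sample_rate), spec$level)
}

#' Masker (threshold-equalizing noise) specification
#'
#' A band of Gaussian noise spectrally shaped so that the power falling into
#' any ERB-wide window inside the band is constant and equal to
#' `level_per_erb` dB.  `kind` selects the reference band (`TEN_flat`), the
#' spectrally shifted variant (`TEN_shifted`, centre multiplied by
#' `shift_factor`) or the sinusoidally amplitude-modulated variant
#' (`TEN_modulated`).
#'
#' @param kind one of "TEN_flat", "TEN_shifted", "TEN_modulated"
#' @param center band centre frequency, Hz
#' @param bandwidth_oct total bandwidth in octaves
#' @param level_per_erb level per ERB, dB
#' @param shift_factor centre-frequency multiplier for the shifted condition
#' @param mod_rate,mod_depth AM rate (Hz) and depth (0-1) for the modulated
#'   condition
#' @param duration,sample_rate s, Hz
#' @export
masker_spec <- function(kind = c("TEN_flat", "TEN_shifted", "TEN_modulated"),
                        center, bandwidth_oct = 1, level_per_erb = 70,
                        shift_factor = 1.1, mod_rate = 4, mod_depth = 1,
                        duration = 1, sample_rate = 48000) {
  kind <- match.arg(kind)
  if (center <= 0) stop("center must be positive")
  if (bandwidth_oct <= 0) stop("bandwidth_oct must be positive")
  if (shift_factor < 1) stop("shift_factor must be >= 1")
  if (mod_depth < 0 || mod_depth > 1) stop("mod_depth must be in [0, 1]")
  structure(list(kind = kind, center = center, bandwidth_oct = bandwidth_oct,
                 level_per_erb = level_per_erb, shift_factor = shift_factor,
                 mod_rate = mod_rate, mod_depth = mod_depth,
                 duration = duration, sample_rate = sample_rate),
            class = c("masker_spec", "stimulus_spec"))
}

## shaped Gaussian noise: PSD proportional to 1/ERB(f) inside the band, so
## the power per ERB-wide window is flat across the band.
synth_shaped_noise <- function(flo, fhi, psd_fun, n, fs) {
  X <- complex(n)
  f <- (seq_len(n) - 1) * fs / n
  pos <- which(f > 0 & f <= fs / 2)
  sel <- pos[f[pos] >= flo & f[pos] <= fhi]
  amp <- sqrt(psd_fun(f[sel]))
  X[sel] <- complex(real = stats::rnorm(length(sel)),
                    imaginary = stats::rnorm(length(sel))) * amp
  # hermitian symmetry for a real signal
  X[n - sel + 2] <- Conj(X[sel])
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Synthesize a threshold-equalizing noise band
#'
#' @param spec a [masker_spec()]
#' @param seed integer; the waveform is reproducible from (spec, seed)
#' @return a mono `waveform` whose ERB-band level anywhere inside the band
#'   equals `spec$level_per_erb` (within ~0.5 dB for realizations of a few
#'   seconds)
#' @export
synth_ten_band <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "masker_spec"))
  n <- round(spec$duration * spec$sample_rate)
  if (n < 2) stop("zero-duration masker requested")
  flo <- spec$center * 2^(-spec$bandwidth_oct / 2)
  fhi <- spec$center * 2^(spec$bandwidth_oct / 2)
  if (fhi > spec$sample_rate / 2) stop("masker band exceeds Nyquist")
  x <- with_seed(seed,
                 synth_shaped_noise(flo, fhi, function(f) 1 / erb_bandwidth(f),
                                    n, spec$sample_rate))
  w <- waveform(x, spec$sample_rate)
  # scale so the ERB window at the band centre sits at level_per_erb
  gain_db <- spec$level_per_erb - erb_level_db(w, spec$center)
  w$samples <- w$samples * 10^(gain_db / 20)
  if (spec$kind == "TEN_modulated") {
    t <- (seq_len(n) - 1) / spec$sample_rate
    env <- 1 + spec$mod_depth * sin(2 * pi * spec$mod_rate * t)
    env <- env / sqrt(mean(env^2))      # keep long-term power unchanged
    w$samples <- w$samples * env
  }
  w
}

#' Derive the masker for an extended-audiometry condition
#'
#' Condition `N` leaves the reference flat TEN unchanged; `S` shifts the
#' centre frequency up by `base$shift_factor` (default 1.1); `T` switches to
#' the sinusoidally modulated TEN at `mod_rate` (default 4 Hz).
#'
#' @param tone_freq target tone frequency, Hz
#' @param condition "N", "S" or "T"
#' @param base a `TEN_flat` [masker_spec()] centred on `tone_freq`
#' @return a [masker_spec()]
#' @export
derive_condition_masker <- function(tone_freq, condition, base) {
  stopifnot(inherits(base, "masker_spec"), base$kind == "TEN_flat")
  if (!isTRUE(all.equal(base$center, tone_freq)))
    stop("base masker must be centred on the tone frequency")
  switch(condition,
         N = base,
         S = { base$center <- base$shift_factor * tone_freq
               base$kind <- "TEN_shifted"; base },
         T = { base$kind <- "TEN_modulated"; base },
         stop("unknown condition: ", condition))
}

#' Spectro-temporal modulation (ripple) noise specification
#'
#' A noise band whose log-frequency-by-time envelope carries a drifting
#' sinusoidal ripple `1 + m*sin(2*pi*(density*log2(f/f_lo) +/- rate*t) + phi)`
#' with depth `m = 10^(modulation_level/20)`.
#'
#' @param band_center centre frequency, Hz (battery uses 800 and 4000)
#' @param band_width_oct band width, octaves (3 for the LF band, 1 for HF)
#' @param spectral_density ripple density, cycles/octave
#' @param temporal_rate ripple drift rate, Hz
#' @param modulation_level 20*log10(m), dB (<= 0); -Inf gives an unmodulated
#'   carrier
#' @param level overall level, dB
#' @param duration s
#' @param direction ripple drift direction, "down" or "up"
#' @param sample_rate Hz
#' @export
stm_spec <- function(band_center = 800, band_width_oct = 3,
                     spectral_density = 2, temporal_rate = 4,
                     modulation_level = -3, level = 75, duration = 0.5,
                     direction = c("down", "up"), sample_rate = 48000) {
  direction <- match.arg(direction)
  if (is.finite(modulation_level) && modulation_level > 0)
    stop("modulation_level must be <= 0 dB")
  structure(list(band_center = band_center, band_width_oct = band_width_oct,
                 spectral_density = spectral_density,
                 temporal_rate = temporal_rate,
                 modulation_level = modulation_level, level = level,
                 duration = duration, direction = direction,
                 sample_rate = sample_rate),
            class = c("stm_spec", "stimulus_spec"))
}

#' Synthesize spectro-temporal ripple noise
#'
#' The carrier is a dense log-spaced random-phase tone complex (1/64 octave
#' spacing); the ripple is imposed as a per-component amplitude envelope.
#'
#' @param spec an [stm_spec()]
#' @param seed integer
#' @return mono `waveform`
#' @export
synth_stm_noise <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "stm_spec"))
  m <- if (is.finite(spec$modulation_level)) 10^(spec$modulation_level / 20) else 0
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  f_lo <- spec$band_center * 2^(-spec$band_width_oct / 2)
  oct <- seq(0, spec$band_width_oct, by = 1 / 64)
  freqs <- f_lo * 2^oct
  sgn <- if (spec$direction == "down") +1 else -1
  x <- with_seed(seed, {
    phases <- stats::runif(length(freqs), 0, 2 * pi)
    phi0 <- stats::runif(1, 0, 2 * pi)
    acc <- numeric(n)
    for (i in seq_along(freqs)) {
      env <- 1 + m * sin(2 * pi * (spec$spectral_density * oct[i] +
                                     sgn * spec$temporal_rate * t) + phi0)
      acc <- acc + env * sin(2 * pi * freqs[i] * t + phases[i])
    }
    acc
  })
  x <- x * raised_cosine_gate(n, round(0.05 * spec$sample_rate))
  set_level(waveform(x, spec$sample_rate), spec$level)
}

#' Ripple contrast of a rendered STM stimulus
#'
#' Coherent spectro-temporal demodulation at the spec's ripple parameters:
#' the signal is split into 1/8-octave bands, each band's Hilbert envelope is
#' projected onto the ripple's temporal rate, and the complex band amplitudes
#' are phase-aligned along the log-frequency axis at the spectral density.
#' The result estimates the generating depth `m` (0 for unmodulated noise up
#' to a small noise floor) and is monotone in `m`.
#'
#' @param w mono `waveform` from [synth_stm_noise()]
#' @param spec the generating [stm_spec()]
#' @export
stm_ripple_contrast <- function(w, spec) {
  x <- drop(w$samples)
  n <- length(x)
  fs <- w$sample_rate
  # drop onset/offset ramps
  core <- round(0.08 * n):round(0.92 * n)
  tt <- (core - 1) / fs
  f_lo <- spec$band_center * 2^(-spec$band_width_oct / 2)
  sgn <- if (spec$direction == "down") +1 else -1
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  oct_centers <- seq(0.15, spec$band_width_oct - 0.15, by = 1 / 8)
  z <- vapply(oct_centers, function(o) {
    sel <- f >= f_lo * 2^(o - 1 / 16) & f < f_lo * 2^(o + 1 / 16)
    H <- complex(n); H[sel] <- 2       # analytic band signal
    env <- Mod(stats::fft(X * H, inverse = TRUE) / n)[core]
    # complex amplitude of the envelope component at the ripple rate,
    # rotated back by the spatial ripple phase of this band
    a <- 2 * mean(env * exp(-2i * pi * sgn * spec$temporal_rate * tt)) /
      mean(env)
    a * exp(-2i * pi * spec$spectral_density * o)
  }, complex(1))
  Mod(mean(z))
}

#' Dichotic (binaural-pitch) noise specification
#'
#' Broadband noise presented identically to both ears except at contour
#' frequencies.  Dichotic contours carry an interaural phase difference of
#' `ipd_radians` inside a transition band around the contour frequency
#' (evoking a purely binaural pitch); diotic contours are rendered as a
#' narrowband level increment in both ears (monaurally detectable).
#'
#' @param duration s
#' @param contour_freqs numeric vector, Hz
#' @param contour_kind character vector, "diotic" or "dichotic", one per
#'   contour
#' @param ipd_radians interaural phase at dichotic contours (pi = 180 deg)
#' @param transition_bw transition-band width as a fraction of the contour
#'   frequency
#' @param noise_band noise band edges, Hz
#' @param level overall level, dB
#' @param diotic_boost_db level increment used to render diotic contours, dB
#' @param sample_rate Hz
#' @export
dichotic_noise_spec <- function(duration = 1, contour_freqs = numeric(),
                                contour_kind = character(),
                                ipd_radians = pi, transition_bw = 0.16,
                                noise_band = c(100, 3200), level = 70,
                                diotic_boost_db = 6, sample_rate = 48000) {
  if (length(contour_freqs) != length(contour_kind))
    stop("contour_freqs and contour_kind must have the same length")
  if (length(contour_freqs) &&
      (any(contour_freqs < noise_band[1]) || any(contour_freqs > noise_band[2])))
    stop("contour frequencies must lie within the noise band")
  if (!all(contour_kind %in% c("diotic", "dichotic")))
    stop("contour_kind entries must be 'diotic' or 'dichotic'")
  structure(list(duration = duration, contour_freqs = contour_freqs,
                 contour_kind = contour_kind, ipd_radians = ipd_radians,
                 transition_bw = transition_bw, noise_band = noise_band,
                 level = level, diotic_boost_db = diotic_boost_db,
                 sample_rate = sample_rate),
            class = c("dichotic_noise_spec", "stimulus_spec"))
}

#' Synthesize dichotic (binaural-pitch) noise
#' @param spec a [dichotic_noise_spec()]
#' @param seed integer
#' @return stereo `waveform`
#' @export
synth_dichotic_noise <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "dichotic_noise_spec"))
  n <- round(spec$duration * spec$sample_rate)
  fs <- spec$sample_rate
  x <- with_seed(seed, synth_shaped_noise(spec$noise_band[1], spec$noise_band[2],
                                          function(f) rep(1, length(f)), n, fs))
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  pos <- f <= fs / 2
  phase <- numeric(n)    # extra phase applied to the right ear
  boost <- rep(1, n)     # level boost applied to both ears
  for (i in seq_along(spec$contour_freqs)) {
    fc <- spec$contour_freqs[i]
    hw <- spec$transition_bw * fc / 2
    sel <- which(pos & f >= fc - hw & f <= fc + hw)
    # raised-cosine weighting across the transition band
    wgt <- 0.5 * (1 + cos(pi * (f[sel] - fc) / hw))
    if (spec$contour_kind[i] == "dichotic") {
      phase[sel] <- phase[sel] + spec$ipd_radians * wgt
    } else {
      boost[sel] <- boost[sel] * 10^((spec$diotic_boost_db / 20) * wgt)
    }
  }
  XL <- X * boost
  XR <- XL * exp(1i * phase)
  # mirror to negative frequencies
  mirror <- function(Z) { idx <- 2:(n %/% 2 + if (n %% 2) 1 else 0)
    Z[n - idx + 2] <- Conj(Z[idx]); Z }
  L <- Re(stats::fft(mirror(XL), inverse = TRUE)) / n
  R <- Re(stats::fft(mirror(XR), inverse = TRUE)) / n
  set_level(waveform(cbind(L, R), fs), spec$level)
}

#' Interaural-phase tone-sequence specification
#'
#' Four successive tones; in an `ABAB` sequence tones 2 and 4 carry an
#' interaural phase difference of `ipd` radians, in `AAAA` all four are
#' diotic.
#'
#' @param tone_freq Hz
#' @param ipd radians (pi = 180 deg)
#' @param pattern "ABAB" or "AAAA"
#' @param tone_duration,gap s
#' @param level dB
#' @param ramp s
#' @param sample_rate Hz
#' @export
ipd_sequence_spec <- function(tone_freq, ipd = pi, pattern = c("ABAB", "AAAA"),
                              tone_duration = 0.4, gap = 0.1, level = 70,
                              ramp = 0.05, sample_rate = 48000) {
  pattern <- match.arg(pattern)
  if (tone_freq <= 0) stop("tone_freq must be positive")
  structure(list(tone_freq = tone_freq, ipd = ipd, pattern = pattern,
                 tone_duration = tone_duration, gap = gap, level = level,
                 ramp = ramp, sample_rate = sample_rate),
            class = c("ipd_sequence_spec", "stimulus_spec"))
}

#' Synthesize an interaural-phase tone sequence
#' @param spec an [ipd_sequence_spec()]
#' @return stereo `waveform`
#' @export
synth_ipd_sequence <- function(spec) {
  stopifnot(inherits(spec, "ipd_sequence_spec"))
  fs <- spec$sample_rate
  nt <- round(spec$tone_duration * fs)
  ng <- round(spec$gap * fs)
  t <- (seq_len(nt) - 1) / fs
  gate <- raised_cosine_gate(nt, round(spec$ramp * fs))
  kinds <- if (spec$pattern == "ABAB") c("A", "B", "A", "B") else rep("A", 4)
  L <- R <- numeric(0)
  for (k in kinds) {
    tone_l <- sin(2 * pi * spec$tone_freq * t) * gate
    ph <- if (k == "B") spec$ipd else 0
    tone_r <- sin(2 * pi * spec$tone_freq * t + ph) * gate
    L <- c(L, tone_l, numeric(ng)); R <- c(R, tone_r, numeric(ng))
  }
  set_level(waveform(cbind(L, R), fs), spec$level)
}

## ---- spec serialization ---------------------------------------------------

#' Serialize a stimulus spec to JSON
#' @param spec any `stimulus_spec`
#' @export
spec_to_json <- function(spec) {
  jsonlite::toJSON(c(list(.class = class(spec)[1]), unclass(spec)),
                   auto_unbox = TRUE, digits = NA)
}

#' Restore a stimulus spec from JSON produced by [spec_to_json()]
#' @param json JSON string
#' @export
spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  cls <- x$.class; x$.class <- NULL
  structure(x, class = c(cls, "stimulus_spec"))
}
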
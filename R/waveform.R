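#' Digital waveform container
#'
#' Holds one- or two-channel sampled audio as a numeric matrix (one column
#' per channel).  Levels throughout the package are digital dB re a fixed
#' reference: a signal with RMS amplitude 1.0 sits at 100 dB, so
#' `level = 100 + 20*log10(rms)`.  Absolute SPL calibration against a
#' transducer is out of scope; a calibration table in the battery config can
#' offset dB HL vs dB SPL if needed.
#'
#' @param samples numeric vector (mono) or matrix with one column per channel
#' @param sample_rate sampling rate in Hz
#' @return an object of class `waveform`
#' @export
waveform <- function(samples, sample_rate) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  stopifnot(is.matrix(samples), ncol(samples) %in% c(1L, 2L))
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(samples = samples, sample_rate = sample_rate,
                 channels = ncol(samples)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d channel(s), %d samples @ %g Hz (%.3f s), level %.1f dB\n",
              x$channels, nrow(x$samples), x$sample_rate,
              nrow(x$samples) / x$sample_rate, wave_level(x)))
  invisible(x)
}

# dB convention: RMS 1.0 <-> 100 dB
.DB_REF <- 100

#' RMS amplitude of a waveform (all channels pooled)
#' @param w a `waveform`
#' @export
wave_rms <- function(w) sqrt(mean(w$samples^2))

#' Overall level of a waveform in package dB (RMS 1.0 = 100 dB)
#' @param w a `waveform`
#' @export
wave_level <- function(w) .DB_REF + 20 * log10(wave_rms(w))

#' Rescale a waveform to a target overall level
#' @param w a `waveform`
#' @param level target level, dB (package convention)
#' @export
set_level <- function(w, level) {
  g <- 10^((level - .DB_REF) / 20) / wave_rms(w)
  w$samples <- w$samples * g
  w
}

db_to_rms <- function(level) 10^((level - .DB_REF) / 20)

#' Raised-cosine onset/offset ramp
#' @param n total number of samples
#' @param n_ramp ramp length in samples
#' @return gating envelope of length `n`
#' @keywords internal
raised_cosine_gate <- function(n, n_ramp) {
  env <- rep(1, n)
  if (n_ramp > 0) {
    r <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = n_ramp)))
    env[seq_len(n_ramp)] <- r
    env[n - n_ramp + seq_len(n_ramp)] <- rev(r)
  }
  env
}

## ---- signal analysis utilities -------------------------------------------

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1], dp))
}

#' Analytic signal via frequency-domain Hilbert transform
#' @param x numeric vector
#' @return complex vector, same length
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous frequency track of a (near-)narrowband waveform
#'
#' Estimated as the derivative of the analytic-signal phase.  Edge samples
#' (and any onset/offset ramps) should be trimmed by the caller before
#' summarizing.
#'
#' @param w a mono `waveform`
#' @return numeric vector of instantaneous frequency, Hz (length n-1)
#' @export
instantaneous_frequency <- function(w) {
  stopifnot(inherits(w, "waveform"), w$channels == 1)
  z <- analytic_signal(drop(w$samples))
  ph <- unwrap_phase(Arg(z))
  diff(ph) * w$sample_rate / (2 * pi)
}

#' Band level of a waveform in package dB
#'
#' Power is integrated over FFT bins inside `[flo, fhi]`.
#'
#' @param w a `waveform` (first channel used)
#' @param flo,fhi band edges in Hz
#' @export
band_level_db <- function(w, flo, fhi) {
  x <- w$samples[, 1]
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * w$sample_rate / n
  half <- f <= w$sample_rate / 2
  pwr <- (Mod(X)^2) / n^2
  # fold negative frequencies onto positive (real signal)
  sel <- half & f >= flo & f <= fhi
  p <- 2 * sum(pwr[sel])
  .DB_REF + 10 * log10(p)
}

#' Equivalent rectangular bandwidth of the auditory filter
#'
#' `ERB(f) = 24.7 * (4.37 * f / 1000 + 1)` Hz.
#'
#' @param f centre frequency in Hz (vectorized)
#' @return bandwidth in Hz
#' @export
erb_bandwidth <- function(f) {
  if (any(f <= 0)) stop("frequency must be positive")
  24.7 * (4.37 * f / 1000 + 1)
}

#' Level within one ERB-wide band centred at `f`
#' @param w a `waveform`
#' @param f centre frequency, Hz
#' @export
erb_level_db <- function(w, f) {
  bw <- erb_bandwidth(f)
  band_level_db(w, f - bw / 2, f + bw / 2)
}

#' Interaural cross-spectral phase near a frequency
#'
#' Average phase of the cross-spectrum `L * Conj(R)` over FFT bins within
#' `half_bw` Hz of `f`; returns a value in (-pi, pi].
#'
#' @param w a stereo `waveform`
#' @param f frequency of interest, Hz
#' @param half_bw half-width of the analysis band, Hz
#' @export
cross_spectral_phase <- function(w, f, half_bw = 20) {
  stopifnot(w$channels == 2)
  n <- nrow(w$samples)
  L <- stats::fft(w$samples[, 1]); R <- stats::fft(w$samples[, 2])
  fr <- (seq_len(n) - 1) * w$sample_rate / n
  sel <- fr >= f - half_bw & fr <= f + half_bw & fr <= w$sample_rate / 2
  Arg(sum(L[sel] * Conj(R[sel])))
}

#' Magnitude-squared interaural coherence in a band
#'
#' Welch-style estimate: the waveform is cut into `n_seg` segments, cross-
#' and auto-spectra are averaged across segments, and the MSC is averaged
#' over bins inside the band.
#'
#' @param w stereo `waveform`
#' @param flo,fhi band edges, Hz
#' @param n_seg number of segments
#' @export
interaural_coherence <- function(w, flo, fhi, n_seg = 16) {
  stopifnot(w$channels == 2)
  n <- nrow(w$samples)
  len <- n %/% n_seg
  sxy <- sxx <- syy <- NULL
  for (k in seq_len(n_seg)) {
    idx <- (k - 1) * len + seq_len(len)
    L <- stats::fft(w$samples[idx, 1]); R <- stats::fft(w$samples[idx, 2])
    if (is.null(sxy)) { sxy <- L * Conj(R); sxx <- Mod(L)^2; syy <- Mod(R)^2 }
    else { sxy <- sxy + L * Conj(R); sxx <- sxx + Mod(L)^2; syy <- syy + Mod(R)^2 }
  }
  fr <- (seq_len(len) - 1) * w$sample_rate / len
  sel <- fr >= flo & fr <= fhi & fr <= w$sample_rate / 2
  mean((Mod(sxy[sel])^2) / (sxx[sel] * syy[sel]))
}

## ---- WAV export ----------------------------------------------------------

#' Write a waveform to a RIFF/WAVE file
#'
#' Minimal writer supporting 16-bit PCM and 32-bit IEEE float; channel order
#' is left, right.
#'
#' @param w a `waveform`
#' @param path output file path
#' @param format "pcm16" or "float32"
#' @export
write_wav <- function(w, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  x <- t(w$samples)                     # interleave channels
  con <- file(path, "wb"); on.exit(close(con))
  n <- length(x)
  bits <- if (format == "pcm16") 16L else 32L
  bytes_per <- bits / 8L
  data_size <- n * bytes_per
  block <- w$channels * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, size = 2, endian = "little")
  writeBin(as.integer(w$channels), con, size = 2, endian = "little")
  writeBin(as.integer(w$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$sample_rate * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    v <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
    writeBin(v, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

## seeded evaluation helper (restores global RNG state)
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv))
          rm(".Random.seed", envir = .GlobalEnv)
      } else assign(".Random.seed", old, envir = .GlobalEnv)
    })
    set.seed(seed)
  }
  code
}

#' Deterministic seed derivation
#'
#' Hashes a master seed together with any number of string/numeric labels
#' into a reproducible integer below 2^31, so every sub-experiment of a run
#' gets its own independent but reproducible stream.
#'
#' @param master integer master seed
#' @param ... labels (coerced to character)
#' @export
derive_seed <- function(master, ...) {
  s <- as.numeric(master) %% 2147483647
  for (lab in unlist(lapply(list(...), as.character))) {
    for (code in utf8ToInt(lab)) s <- (s * 31 + code) %% 2147483647
  }
  as.integer(s)
}
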
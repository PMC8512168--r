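## Simulated listeners.
##
## A ListenerProfile is the generative ground truth of one subject: an
## audiogram, per-band loudness functions, speech/modulation/binaural
## parameters, and response-noise settings (false-alarm and lapse rates).
## Response functions turn a profile into the yes/no, categorical and 2-AFC
## answers the adaptive procedures need.  `make_cohort()` generates
## populations whose supra-threshold deficits are linked to the audiogram
## while binaural abilities stay statistically independent of it.

#' Psychometric-function parameters
#'
#' Detection probability `gamma + (1 - gamma - lambda) * F((x - theta)/sigma)`
#' with logistic `F`; `gamma` is the guess/false-alarm floor, `lambda` the
#' lapse rate.
#'
#' @param theta threshold (test units, 50% point of F)
#' @param sigma spread (test units)
#' @param gamma lower asymptote
#' @param lambda lapse rate
#' @export
psychometric_params <- function(theta, sigma, gamma = 0, lambda = 0) {
  if (sigma <= 0) stop("sigma must be positive")
  if (gamma < 0 || lambda < 0 || gamma + lambda >= 1)
    stop("need 0 <= gamma, lambda and gamma + lambda < 1")
  structure(list(theta = theta, sigma = sigma, gamma = gamma,
                 lambda = lambda), class = "psychometric_params")
}

#' Psychometric detection probability
#' @param x stimulus value(s)
#' @param params a [psychometric_params()]
#' @param decreasing if TRUE the function falls with `x` (frequency-type
#'   tasks where higher values are harder)
#' @export
psychometric_prob <- function(x, params, decreasing = FALSE) {
  z <- (x - params$theta) / params$sigma
  if (decreasing) z <- -z
  params$gamma + (1 - params$gamma - params$lambda) * stats::plogis(z)
}

#' Stimulus value at a given response probability
#' @param params a [psychometric_params()]
#' @param p target probability
#' @param decreasing as in [psychometric_prob()]
#' @export
psychometric_quantile <- function(params, p, decreasing = FALSE) {
  q <- stats::qlogis((p - params$gamma) / (1 - params$gamma - params$lambda))
  params$theta + (if (decreasing) -1 else 1) * params$sigma * q
}

#' Loudness-function parameters of a simulated listener
#'
#' Broken-stick categorical loudness: CU rises from the threshold branch with
#' slope `m_lo` (CU/dB) up to CU 25 at `L_cut`, then with slope `m_hi`;
#' output clipped to [0, 50].
#'
#' @param L_cut level at CU 25 (the most comfortable level), dB
#' @param m_lo,m_hi lower/upper branch slopes, CU/dB
#' @param response_noise_sd response scatter, CU
#' @export
loudness_params <- function(L_cut, m_lo, m_hi, response_noise_sd = 3) {
  if (m_lo <= 0 || m_hi <= 0) stop("slopes must be positive")
  structure(list(L_cut = L_cut, m_lo = m_lo, m_hi = m_hi,
                 response_noise_sd = response_noise_sd),
            class = "loudness_params")
}

#' Noiseless categorical loudness for a level
#' @param level dB
#' @param lp a [loudness_params()]
#' @export
loudness_cu <- function(level, lp) {
  m <- ifelse(level <= lp$L_cut, lp$m_lo, lp$m_hi)
  pmin(pmax(25 + m * (level - lp$L_cut), 0), 50)
}

.CU_CATEGORIES <- seq(0, 50, by = 5)

#' Construct a simulated listener
#'
#' All arguments have normal-hearing defaults; [make_cohort()] fills them
#' from its generative model.  Thresholds are in the package's dB convention
#' (treated as dB HL).
#'
#' @param audiogram named numeric, dB HL per audiometric frequency
#' @param flft_true highest audible frequency for an 80-dB warble tone, Hz
#' @param loudness named list of [loudness_params()] per ACALOS band
#' @param speech_quiet [psychometric_params()] in dB (theta = 50% word level;
#'   1 - lambda = max discrimination)
#' @param speech_noise [psychometric_params()] in dB SNR
#' @param stm_threshold named numeric, modulation level (dB) at the 80% point
#'   per condition ("8", "4k")
#' @param stm_sigma psychometric spread for the modulation task, dB
#' @param tin_true named numeric tone-in-noise thresholds, names like
#'   "N.LF", "S.HF" (dB HL)
#' @param s0n0_true,spin0_true diotic/antiphasic tone-in-noise thresholds, dB
#' @param ipd_fmax_true upper frequency limit for 180-degree interaural phase
#'   detection, Hz
#' @param ipd_spread_oct spread of the interaural-phase psychometric
#'   function, octaves
#' @param bp_detect_prob per-contour dichotic-pitch detection probability
#' @param false_alarm_rate yes-rate on catch trials
#' @param lapse_rate inattention rate
#' @param tin_sigma,flft_sigma_oct psychometric spreads for level (dB) and
#'   frequency (octaves) tracking
#' @param deterministic if TRUE the listener answers as a noise-free step
#'   function (used for idealized test-retest studies)
#' @param id,group,seed bookkeeping
#' @export
listener_profile <- function(audiogram = c(`250` = 0, `500` = 0, `1000` = 0,
                                           `2000` = 5, `4000` = 10,
                                           `6000` = 10, `8000` = 15),
                             flft_true = 12000,
                             loudness = NULL,
                             speech_quiet = psychometric_params(18, 4, 0, 0.02),
                             speech_noise = psychometric_params(-1, 1.2, 0, 0.02),
                             stm_threshold = c(`8` = -8, `4k` = -6),
                             stm_sigma = 1.5,
                             tin_true = c(N.LF = 70, S.LF = 51, T.LF = 63,
                                          N.HF = 70.5, S.HF = 43, T.HF = 58),
                             s0n0_true = 70, spin0_true = 54,
                             ipd_fmax_true = 750, ipd_spread_oct = 0.1,
                             bp_detect_prob = 0.98,
                             false_alarm_rate = 0.05, lapse_rate = 0.02,
                             tin_sigma = 2, flft_sigma_oct = 0.1,
                             deterministic = FALSE,
                             id = "L1", group = "ONH", seed = 1) {
  if (is.null(loudness)) {
    loudness <- lapply(audiogram[as.character(c(250, 500, 1000, 2000, 4000, 6000))],
                       function(h) default_loudness_for_loss(h))
    names(loudness) <- as.character(c(250, 500, 1000, 2000, 4000, 6000))
  }
  stopifnot(all(bp_detect_prob >= 0 & bp_detect_prob <= 1),
            false_alarm_rate >= 0, false_alarm_rate <= 1)
  structure(list(audiogram = audiogram, flft_true = flft_true,
                 loudness = loudness, speech_quiet = speech_quiet,
                 speech_noise = speech_noise, stm_threshold = stm_threshold,
                 stm_sigma = stm_sigma, tin_true = tin_true,
                 s0n0_true = s0n0_true, spin0_true = spin0_true,
                 ipd_fmax_true = ipd_fmax_true,
                 ipd_spread_oct = ipd_spread_oct,
                 bp_detect_prob = bp_detect_prob,
                 false_alarm_rate = false_alarm_rate,
                 lapse_rate = lapse_rate, tin_sigma = tin_sigma,
                 flft_sigma_oct = flft_sigma_oct,
                 deterministic = deterministic,
                 id = id, group = group, seed = seed),
            class = "listener_profile")
}

#' @export
print.listener_profile <- function(x, ...) {
  cat(sprintf("<listener_profile> %s (%s): PTA %.1f dB HL, FLFT %.1f kHz, IPDfmax %.0f Hz\n",
              x$id, x$group,
              mean(x$audiogram[c("500", "1000", "2000")]),
              x$flft_true / 1000, x$ipd_fmax_true))
  invisible(x)
}

## loudness function implied by a hearing loss: threshold branch anchored
## near the audiometric threshold, UCL rising only slowly with loss
## (recruitment: the lower branch steepens as the dynamic range shrinks)
default_loudness_for_loss <- function(loss, ucl = NULL, cut_frac = 0.62,
                                      noise_sd = 3) {
  if (is.null(ucl)) ucl <- 105 + 0.10 * loss
  thr <- loss
  d <- max(ucl - thr, 15)
  L_cut <- thr + cut_frac * d
  loudness_params(L_cut = L_cut, m_lo = 24.5 / (L_cut - thr),
                  m_hi = 25 / (ucl - L_cut), response_noise_sd = noise_sd)
}

## internal: psychometric lookup for a yes/no test id
profile_yesno_params <- function(profile, test_id) {
  gam <- if (profile$deterministic) 0 else profile$false_alarm_rate
  lam <- if (profile$deterministic) 0 else profile$lapse_rate
  det_sigma <- 1e-6
  if (test_id == "eAUD-HF") {
    s <- if (profile$deterministic) det_sigma else profile$flft_sigma_oct
    return(list(params = psychometric_params(log2(profile$flft_true), s, gam, lam),
                decreasing = TRUE))
  }
  if (grepl("^fSTM\\.", test_id)) {
    cond <- sub("^fSTM\\.", "", test_id)
    s <- if (profile$deterministic) det_sigma else profile$stm_sigma
    # stored truth is the 80% point; recover the underlying 50% point
    p80 <- profile$stm_threshold[[cond]]
    par <- psychometric_params(0, s, gam, lam)
    par$theta <- p80 - s * stats::qlogis((0.8 - gam) / (1 - gam - lam))
    return(list(params = par, decreasing = FALSE))
  }
  if (grepl("^sSTM\\.", test_id)) {
    cond <- sub("^sSTM\\.", "", test_id)
    s <- if (profile$deterministic) det_sigma else profile$stm_sigma
    p80 <- profile$stm_threshold[[cond]]
    par <- psychometric_params(0, s, gam, lam)
    par$theta <- p80 - s * stats::qlogis((0.8 - gam) / (1 - gam - lam))
    return(list(params = par, decreasing = FALSE))
  }
  if (grepl("^eAUD-[NST]\\.", test_id)) {
    key <- sub("^eAUD-", "", test_id)   # e.g. "N.LF"
    s <- if (profile$deterministic) det_sigma else profile$tin_sigma
    # detection grows with tone level
    return(list(params = psychometric_params(profile$tin_true[[key]], s, gam, lam),
                decreasing = FALSE))
  }
  if (test_id == "S0N0" || test_id == "SpiN0") {
    s <- if (profile$deterministic) det_sigma else profile$tin_sigma
    th <- if (test_id == "S0N0") profile$s0n0_true else profile$spin0_true
    return(list(params = psychometric_params(th, s, gam, lam),
                decreasing = FALSE))
  }
  stop("unknown test_id: ", test_id)
}

#' Yes/no response of a simulated listener
#'
#' Catch trials are answered "yes" with the profile's false-alarm rate;
#' signal trials according to the psychometric function the `test_id` maps
#' to ("eAUD-HF", "eAUD-N.LF", ..., "fSTM.8", "S0N0", "SpiN0").
#'
#' @param profile a [listener_profile()]
#' @param test_id test identifier
#' @param stimulus_present FALSE on catch trials
#' @param value current tracked value (dB, dB ML, or log2 Hz for "eAUD-HF")
#' @export
respond_yesno <- function(profile, test_id, stimulus_present, value) {
  if (!stimulus_present) {
    fa <- if (profile$deterministic) 0 else profile$false_alarm_rate
    return(stats::runif(1) < fa)
  }
  m <- profile_yesno_params(profile, test_id)
  p <- psychometric_prob(value, m$params, decreasing = m$decreasing)
  if (profile$deterministic) p >= 0.5 else stats::runif(1) < p
}

#' Categorical loudness response
#'
#' Broken-stick loudness plus Gaussian response noise, snapped to the nearest
#' of the 11 categorical values (0, 5, ..., 50).
#'
#' @param profile a [listener_profile()]
#' @param band ACALOS band centre, Hz (must be in `profile$loudness`)
#' @param level presentation level, dB HL
#' @export
respond_loudness <- function(profile, band, level) {
  lp <- profile$loudness[[as.character(band)]]
  if (is.null(lp)) stop("no loudness parameters for band ", band)
  cu <- loudness_cu(level, lp)
  if (!profile$deterministic && lp$response_noise_sd > 0)
    cu <- cu + stats::rnorm(1, 0, lp$response_noise_sd)
  # below-threshold levels are reported "not heard"
  if (loudness_cu(level, lp) == 0) cu <- 0
  .CU_CATEGORIES[which.min(abs(.CU_CATEGORIES - min(max(cu, 0), 50)))]
}

#' 2-AFC interaural-phase response
#'
#' Probability correct `0.5 + 0.5 * (1 - lapse) * S(f)` where `S` falls
#' logistically (in log2 frequency, spread `ipd_spread_oct`) from 1 to 0
#' around the profile's upper IPD frequency limit.
#'
#' @param profile a [listener_profile()]
#' @param freq tone frequency, Hz
#' @export
respond_2afc_ipd <- function(profile, freq) {
  if (profile$deterministic) return(freq <= profile$ipd_fmax_true)
  S <- stats::plogis((log2(profile$ipd_fmax_true) - log2(freq)) /
                       profile$ipd_spread_oct)
  p <- 0.5 + 0.5 * (1 - profile$lapse_rate) * S
  stats::runif(1) < p
}

## ---- cohort generation -----------------------------------------------------

## IEC 60118-15 standard audiograms N1-N4 (flat/moderately sloping family),
## dB HL; 8 kHz extrapolated from the 4-6 kHz slope.
.STD_AUDIOGRAMS <- rbind(
  N1 = c(`250` = 10, `500` = 10, `1000` = 10, `2000` = 15, `4000` = 30,
         `6000` = 40, `8000` = 45),
  N2 = c(20, 20, 25, 35, 45, 50, 55),
  N3 = c(35, 35, 40, 50, 60, 65, 70),
  N4 = c(55, 55, 55, 65, 75, 80, 85))

#' Interpolated standard audiogram
#'
#' Piecewise-linear interpolation between the standard audiograms N1-N4
#' indexed by a severity scalar in [0, 1] (0 = N1, 1 = N4).
#'
#' @param severity scalar in [0, 1]
#' @export
standard_audiogram <- function(severity) {
  stopifnot(severity >= 0, severity <= 1)
  pos <- severity * 3
  k <- min(floor(pos) + 1, 3); u <- pos - (k - 1)
  out <- (1 - u) * .STD_AUDIOGRAMS[k, ] + u * .STD_AUDIOGRAMS[k + 1, ]
  names(out) <- colnames(.STD_AUDIOGRAMS)
  out
}

#' Cohort generator configuration
#'
#' The generative linkage model: high-frequency loss steepens the loudness
#' function (recruitment), raises speech-in-noise thresholds and
#' modulation-detection thresholds and shrinks the high-frequency masking
#' releases; low-frequency loss drives speech-in-quiet; binaural parameters
#' (IPD limit, dichotic-pitch detection, binaural masking release) are drawn
#' independently of the audiogram.  All coefficients live here.
#'
#' @param n_listeners cohort size
#' @param onh_prop proportion of (older) normal-hearing listeners
#' @param jitter_sd per-frequency audiogram jitter, dB
#' @param linkage named list of linkage coefficients and noise SDs; entries
#'   omitted from the list keep their defaults
#' @param fixed_severity optional `c(lf, hf)` severity pair in [0, 1]; when
#'   given, every listener uses this audiogram template instead of sampled
#'   severities (with zero `jitter_sd` and zero linkage SDs all profiles are
#'   then identical)
#' @param deterministic generate noise-free (step-function) responders
#' @param seed integer
#' @export
cohort_config <- function(n_listeners = 50, onh_prop = 0.1, jitter_sd = 5,
                          linkage = list(), fixed_severity = NULL,
                          deterministic = FALSE, seed = 1) {
  if (n_listeners < 1) stop("n_listeners must be >= 1")
  defaults <- list(
    srtq_int = 17, srtq_pta = 1.0, srtq_sd = 3,
    srtn_int = -1, srtn_hf = 0.09, srtn_sd = 1.2,
    stm8_int = -8, stm8_hf = 0.11, stm8_sd = 1.5,
    stm4k_int = -6, stm4k_hf = 0.09, stm4k_sd = 1.5,
    flft_int_khz = 15, flft_hf = 0.12, flft_sd_khz = 1,
    tin_lf_int = 70, tin_lf_coef = 0.035,
    tin_hf_int = 70.5, tin_hf_coef = 0.06, tin_sd = 1,
    tmr_lf_mean = 7, tmr_hf_int = 12.5,
    tmr_hf_coef = -0.08, tmr_sd = 2,
    smr_lf_mean = 19, smr_hf_int = 28,
    smr_hf_coef = -0.15, smr_sd = 2.5,
    bmr_mean = 15.5, bmr_sd = 3,
    s0n0_sd = 1, maxds_sd = 2,
    loud_thr_sd = 2, loud_ucl_sd = 3,
    ipd_logmean = log(700), ipd_logsd = 0.35,
    bp_base = 0.98, bp_sd = 0.02, bp_poor_prob = 0.15)
  bad <- setdiff(names(linkage), names(defaults))
  if (length(bad)) stop("unknown linkage coefficients: ",
                        paste(bad, collapse = ", "))
  defaults[names(linkage)] <- linkage
  structure(list(n_listeners = n_listeners, onh_prop = onh_prop,
                 jitter_sd = jitter_sd, linkage = defaults,
                 fixed_severity = fixed_severity,
                 deterministic = deterministic, seed = seed),
            class = "cohort_config")
}

#' Generate a simulated cohort
#'
#' @param config a [cohort_config()]
#' @return list of [listener_profile()]s with attribute `"truth"`: a
#'   data.frame of the ground-truth counterparts of the battery outcomes
#'   (see [cohort_truth()])
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  L <- config$linkage
  profiles <- with_seed(config$seed, {
    lapply(seq_len(config$n_listeners), function(i) {
      onh <- i <= round(config$onh_prop * config$n_listeners)
      # two latent severity dimensions: low- and high-frequency loss vary
      # partly independently (flat, sloping and mixed audiometric shapes)
      if (!is.null(config$fixed_severity)) {
        sev_lf <- config$fixed_severity[1]; sev_hf <- config$fixed_severity[2]
      } else {
        sev_lf <- if (onh) stats::runif(1, 0, 0.08) else stats::runif(1, 0.05, 0.75)
        sev_hf <- if (onh) stats::runif(1, 0, 0.12)
                  else max(stats::runif(1, 0.1, 1), sev_lf - 0.2)
      }
      aud <- c(standard_audiogram(sev_lf)[c("250", "500", "1000")],
               standard_audiogram(sev_hf)[c("2000", "4000", "6000", "8000")]) +
        stats::rnorm(7, 0, config$jitter_sd)
      aud <- pmax(round(aud / 5) * 5, -10)
      lf <- mean(aud[c("250", "500", "1000")])
      hf <- mean(aud[c("2000", "4000", "6000")])
      pta <- mean(aud[c("500", "1000", "2000")])
      loud <- lapply(as.character(c(250, 500, 1000, 2000, 4000, 6000)),
                     function(f) default_loudness_for_loss(
                       aud[[f]] + stats::rnorm(1, 0, L$loud_thr_sd),
                       ucl = 105 + 0.10 * aud[[f]] +
                         stats::rnorm(1, 0, L$loud_ucl_sd),
                       noise_sd = if (config$deterministic) 0 else 3))
      names(loud) <- as.character(c(250, 500, 1000, 2000, 4000, 6000))
      srtq <- L$srtq_int + L$srtq_pta * pta + stats::rnorm(1, 0, L$srtq_sd)
      maxds <- min(100 - max(0, 0.12 * (hf - 20)) -
                     abs(stats::rnorm(1, 0, L$maxds_sd)), 100)
      srtn <- L$srtn_int + L$srtn_hf * hf + stats::rnorm(1, 0, L$srtn_sd)
      stm8 <- min(L$stm8_int + L$stm8_hf * hf + stats::rnorm(1, 0, L$stm8_sd),
                  -0.5)
      stm4k <- min(L$stm4k_int + L$stm4k_hf * hf +
                     stats::rnorm(1, 0, L$stm4k_sd), -0.5)
      flft <- max(min((L$flft_int_khz - L$flft_hf * hf +
                         stats::rnorm(1, 0, L$flft_sd_khz)), 19), 4) * 1000
      tin_n_lf <- L$tin_lf_int + L$tin_lf_coef * lf + stats::rnorm(1, 0, L$tin_sd)
      tin_n_hf <- L$tin_hf_int + L$tin_hf_coef * hf + stats::rnorm(1, 0, L$tin_sd)
      tmr_lf <- max(L$tmr_lf_mean + stats::rnorm(1, 0, L$tmr_sd), 0.5)
      tmr_hf <- max(L$tmr_hf_int + L$tmr_hf_coef * hf +
                      stats::rnorm(1, 0, L$tmr_sd), 0.5)
      smr_lf <- max(L$smr_lf_mean + stats::rnorm(1, 0, L$smr_sd), 0.5)
      smr_hf <- max(L$smr_hf_int + L$smr_hf_coef * hf +
                      stats::rnorm(1, 0, L$smr_sd), 0.5)
      bmr <- min(max(stats::rnorm(1, L$bmr_mean, L$bmr_sd), 5), 25)
      s0n0 <- 70 + 0.03 * lf + stats::rnorm(1, 0, L$s0n0_sd)
      ipd <- min(max(stats::rlnorm(1, L$ipd_logmean, L$ipd_logsd), 200), 1600)
      bp <- if (stats::runif(1) < L$bp_poor_prob) stats::runif(1, 0.2, 0.9)
            else min(max(stats::rnorm(1, L$bp_base, L$bp_sd), 0), 1)
      if (config$deterministic) bp <- round(bp)
      listener_profile(
        audiogram = aud, flft_true = flft, loudness = loud,
        speech_quiet = psychometric_params(srtq, 4, 0, 1 - maxds / 100 + 1e-4),
        speech_noise = psychometric_params(srtn, 1.2, 0,
                                           if (config$deterministic) 1e-4 else 0.02),
        stm_threshold = c(`8` = stm8, `4k` = stm4k),
        tin_true = c(N.LF = tin_n_lf, S.LF = tin_n_lf - smr_lf,
                     T.LF = tin_n_lf - tmr_lf, N.HF = tin_n_hf,
                     S.HF = tin_n_hf - smr_hf, T.HF = tin_n_hf - tmr_hf),
        s0n0_true = s0n0, spin0_true = s0n0 - bmr,
        ipd_fmax_true = ipd, bp_detect_prob = bp,
        false_alarm_rate = if (config$deterministic) 0 else 0.05,
        lapse_rate = if (config$deterministic) 0 else 0.02,
        deterministic = config$deterministic,
        id = sprintf("L%03d", i), group = if (onh) "ONH" else "HI",
        seed = derive_seed(config$seed, "listener", i))
    })
  })
  attr(profiles, "truth") <- do.call(rbind, lapply(profiles, profile_truth_row))
  class(profiles) <- "listener_cohort"
  profiles
}

## one row of ground-truth counterparts of the reduced outcome variables
profile_truth_row <- function(p) {
  aud <- p$audiogram
  band_stat <- function(fun) {
    v <- vapply(p$loudness, fun, numeric(1))
    c(LF = mean(v[c("250", "500", "1000")]),
      HF = mean(v[c("2000", "4000", "6000")]))
  }
  htl <- band_stat(function(lp) lp$L_cut - 22.5 / lp$m_lo)
  mcl <- band_stat(function(lp) lp$L_cut)
  slope <- band_stat(function(lp) lp$m_lo)
  dynr <- band_stat(function(lp) 25 / lp$m_hi + 24.5 / lp$m_lo)
  data.frame(
    id = p$id, group = p$group,
    AUD_LF = mean(aud[c("250", "500", "1000")]),
    AUD_HF = mean(aud[c("2000", "4000", "6000")]),
    FLFT = p$flft_true / 1000,
    HTL_LF = htl[["LF"]], HTL_HF = htl[["HF"]],
    MCL_LF = mcl[["LF"]], MCL_HF = mcl[["HF"]],
    DynR_LF = dynr[["LF"]], DynR_HF = dynr[["HF"]],
    Slope_LF = slope[["LF"]], Slope_HF = slope[["HF"]],
    SRT_Q = p$speech_quiet$theta,
    maxDS = 100 * (1 - p$speech_quiet$lambda),
    SRT_N = p$speech_noise$theta,
    SScore_4dB = 100 * psychometric_prob(4, p$speech_noise),
    fSTM_8 = p$stm_threshold[["8"]], fSTM_4k = p$stm_threshold[["4k"]],
    TiN_LF = p$tin_true[["N.LF"]], TiN_HF = p$tin_true[["N.HF"]],
    SMR_LF = p$tin_true[["N.LF"]] - p$tin_true[["S.LF"]],
    SMR_HF = p$tin_true[["N.HF"]] - p$tin_true[["S.HF"]],
    TMR_LF = p$tin_true[["N.LF"]] - p$tin_true[["T.LF"]],
    TMR_HF = p$tin_true[["N.HF"]] - p$tin_true[["T.HF"]],
    IPD_fmax = p$ipd_fmax_true / 1000,
    BP_20 = 100 * p$bp_detect_prob,
    BMR = p$s0n0_true - p$spin0_true,
    row.names = NULL)
}

#' Ground-truth table of a cohort
#' @param cohort result of [make_cohort()]
#' @return data.frame, one row per listener, reduced-variable ground truths
#' @export
cohort_truth <- function(cohort) attr(cohort, "truth")

#' Serialize a listener profile to JSON (lossless)
#' @param profile a [listener_profile()]
#' @export
profile_to_json <- function(profile) {
  x <- unclass(profile)
  x$speech_quiet <- unclass(x$speech_quiet)
  x$speech_noise <- unclass(x$speech_noise)
  x$loudness <- lapply(x$loudness, unclass)
  # keep the names of atomic vectors (jsonlite would drop them)
  for (f in c("audiogram", "stm_threshold", "tin_true")) x[[f]] <- as.list(x[[f]])
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}

#' Restore a listener profile from JSON
#' @param json string from [profile_to_json()]
#' @export
profile_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$speech_quiet <- do.call(psychometric_params, x$speech_quiet)
  x$speech_noise <- do.call(psychometric_params, x$speech_noise)
  x$loudness <- lapply(x$loudness, function(l) do.call(loudness_params, l))
  x$audiogram <- unlist(x$audiogram)
  x$stm_threshold <- unlist(x$stm_threshold)
  x$tin_true <- unlist(x$tin_true)
  do.call(listener_profile, x)
}
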